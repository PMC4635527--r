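# smlmChromatin

Single-molecule localization microscopy (SMLM) analysis of nuclear
chromatin compaction, in R.

SMLM of DNA-dye stained nuclei localizes individual blinking fluorophores
over thousands of camera frames and accumulates them into a
super-resolved point map of chromatin. This package provides the complete
computational chain for that experiment — aimed at microscopists and
image analysts who want a tested, scriptable reference implementation:

* a **simulator** that renders acquisitions from analytic nuclear
  phantoms (DNA-dense hollow *atolls*, chromatin-free *voids*, a diffuse
  floor) with known emitter positions, Gaussian PSFs integrated over
  102 nm pixels, ~1500-photon bursts, 150-count uniform background,
  Poisson shot noise, and optional linear drift;
* **localization**: rolling 8-frame background with Poisson noise model
  (`STD = sqrt(background)`), detection of smoothed local maxima at the
  `(TF − 1)·STD` threshold, 7×7 centre-of-intensity refinement with
  radial overlap clipping (candidates losing > 30 % of signal to clipping
  are discarded), per-record precision

  σ²loc = (s² + p²/12)/N + 8π s⁴ b² / (p² N²),

  and joining of consecutive-frame bursts within 2.5·⟨σloc⟩;
* **drift correction** by Fourier cross-correlation of up to 100 temporal
  subset reconstructions with sub-pixel peak interpolation;
* **rendering** (per-record / mean / fixed Gaussian blur, 5 nm pixels),
  the quadrature resolution estimate σ²total = σ²loc + σ²sampling +
  σ²drift with σsampling = 2/√α, and **Fourier ring correlation** at the
  1/7 threshold;
* **compaction statistics**: localization density over the nuclear mask,
  grid-binned counts (bins with < 2 localizations discarded) with
  Fisher–Pearson skewness, exact k-nearest-neighbour mean distances
  within regions of interest (k up to 500), and the chromatin-free area
  fraction after 8-bit histogram stretching, thresholding at 50 and hole
  filling.

## Worked example

Simulate an ischemia-mimetic ("compacted") and an untreated ("open")
nucleus at the same seed and run the full pipeline on each:

```r
library(smlmChromatin)

open <- runPipeline(defaultPipelineConfig("open",      seed = 1))
comp <- runPipeline(defaultPipelineConfig("compacted", seed = 1))

round(c(open = open$densityPerUm2, comp = comp$densityPerUm2))
#> open comp
#>  503  365
round(100 * c(open = open$freeArea$freeFraction,
              comp = comp$freeArea$freeFraction), 1)
#> open comp
#>  8.0 20.4
round(c(open = open$binning$skewness, comp = comp$binning$skewness), 2)
#>  open  comp
#> -0.66  0.23
round(c(open = open$nn$median, comp = comp$nn$median))
#> open comp
#>  425  589
```

Compaction shows exactly the expected signature: ~27 % fewer
localizations per μm², a ~2.5-fold larger chromatin-free fraction, higher
bin-count skewness, and longer 500-nearest-neighbour distances. Each
report also carries the resolution decomposition
(`report$resolution`) and, for tables of ≥ 2000 records, the FRC
resolution.

Individual stages are plain functions over S4 objects
(`FrameStack`, `LocalizationTable`, `ChromatinPhantom`, ...):

```r
ph  <- nuclearPhantom("compacted", seed = 7)
em  <- makeBlinkSchedule(sampleEmitters(ph, 14000, seed = 8),
                         AcquisitionConfig(nFrames = 2500), seed = 9)
st  <- simulateStack(em, AcquisitionConfig(nFrames = 2500), seed = 10)
tab <- localizeStack(st, DetectionConfig(thresholdFactor = 3))
img <- renderLocalizations(tab, pixel = 5, blur = "mean")
```

A thin command-line wrapper with `simulate` / `localize` / `driftcorr` /
`render` / `frc` / `stats` / `run` subcommands is installed at
`inst/cli/smlm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/smlm.R", package = "smlmChromatin"))')" \
    localize --tf 3 --pixel-nm 102 --psf-sigma-nm 130 --gain 2 in.tif out.csv
```

Localization tables are ThunderSTORM-compatible CSV
(`frame,x [nm],y [nm],intensity [photon],sigma [nm],uncertainty_xy [nm],background [photon]`);
stacks and reconstructions are multi-page 16-bit TIFF.

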