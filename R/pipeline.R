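#' Preset nuclear phantoms for the two chromatin regimes
#'
#' Builds a \linkS4class{ChromatinPhantom} emulating either an untreated
#' ("open") nucleus -- mostly diffuse chromatin, a few small atolls, modest
#' chromatin-free voids -- or an ischemia-mimetic compacted nucleus -- many
#' 240-700 nm atolls with 120 nm rings at about 3x the diffuse emitter
#' density, and doubled void area.  The nucleus is a disk centred in the
#' field; structures are placed inside it by non-overlapping dart throwing,
#' so a given seed always yields the same geometry.
#'
#' @param regime \code{"open"} or \code{"compacted"}.
#' @param fieldSize field extent (x, y), nm.
#' @param nucleusDiameter diameter of the nuclear disk, nm.
#' @param seed integer seed for the geometry.
#' @return a \linkS4class{ChromatinPhantom}.
#' @export
nuclearPhantom <- function(regime = c("open", "compacted"),
        fieldSize = c(4900, 4900), nucleusDiameter = 0.86 * min(fieldSize),
        seed = NULL) {
    regime <- match.arg(regime)
    if (!is.null(seed)) set.seed(seed)
    diskR <- nucleusDiameter / 2
    diskCx <- fieldSize[1] / 2
    diskCy <- fieldSize[2] / 2
    cfg <- switch(regime,
        open = list(voidFraction = 0.125, nAtolls = 3,
            outerRange = c(240, 400), voidDiam = c(600, 1000),
            contrast = 2),
        compacted = list(voidFraction = 0.25, nAtolls = 10,
            outerRange = c(240, 700), voidDiam = c(800, 1400),
            contrast = 3))
    ## draw void diameters until the target fraction of the nuclear area
    target <- cfg$voidFraction * pi * diskR^2
    drawGeometry <- function() {
        vd <- numeric()
        acc <- 0
        while (acc < target) {
            d <- stats::runif(1, cfg$voidDiam[1], cfg$voidDiam[2])
            if (acc + pi * (d / 2)^2 > target)
                d <- 2 * sqrt((target - acc) / pi)
            if (d < 50) break
            vd <- c(vd, d)
            acc <- acc + pi * (d / 2)^2
        }
        ao <- stats::runif(cfg$nAtolls, cfg$outerRange[1], cfg$outerRange[2])
        list(vd = vd, ao = ao)
    }
    ## place all circles (atolls + voids) without overlap, larger first;
    ## a minimum chromatin wall separates voids from each other (250 nm)
    ## and from the nuclear rim (300 nm) -- chromatin-free compartments
    ## bounded by walls thinner than the sampling resolution neither occur
    ## in nuclei nor survive rendering.  Atolls are themselves chromatin
    ## and may sit close to anything.
    gap <- 250
    rimGap <- 300
    placeAll <- function(geom) {
        radii <- c(geom$ao / 2, geom$vd / 2)
        kind <- rep(c("atoll", "void"),
            c(length(geom$ao), length(geom$vd)))
        ord <- order(-radii)
        placed <- matrix(numeric(), 0, 3)
        placedKind <- character()
        for (i in ord) {
            r <- radii[i]
            isVoid <- kind[i] == "void"
            ok <- FALSE
            for (try in 1:2000) {
                ## uniform within the disk, kept fully inside it
                th <- stats::runif(1, 0, 2 * pi)
                rr <- (diskR - r - if (isVoid) rimGap else 50) *
                    sqrt(stats::runif(1))
                cx <- diskCx + rr * cos(th)
                cy <- diskCy + rr * sin(th)
                sep <- placed[, 3] + r +
                    ifelse(isVoid & placedKind == "void", gap, 50)
                if (!nrow(placed) || all(sqrt((placed[, 1] - cx)^2 +
                        (placed[, 2] - cy)^2) > sep)) {
                    ok <- TRUE
                    break
                }
            }
            if (!ok)
                return(NULL)
            placed <- rbind(placed, c(cx, cy, r))
            placedKind <- c(placedKind, kind[i])
        }
        list(placed = placed, kind = kind, ord = ord)
    }
    ## some size draws cannot be packed with the required walls; re-draw
    res <- NULL
    for (restart in 1:20) {
        res <- placeAll(drawGeometry())
        if (!is.null(res)) break
    }
    if (is.null(res))
        stop("could not place all phantom structures without overlap; ",
            "reduce their number or size")
    placed <- res$placed
    kind <- res$kind
    ord <- res$ord
    atolls <- NULL
    voids <- NULL
    aRows <- which(kind[ord] == "atoll")
    vRows <- which(kind[ord] == "void")
    if (length(aRows)) {
        outer <- 2 * placed[aRows, 3]
        atolls <- data.frame(x = placed[aRows, 1], y = placed[aRows, 2],
            outer = outer, thickness = pmin(120, 0.45 * outer))
    }
    if (length(vRows))
        voids <- data.frame(x = placed[vRows, 1], y = placed[vRows, 2],
            diameter = 2 * placed[vRows, 3])
    buildPhantom(fieldSize, atolls = atolls, voids = voids,
        densityContrast = cfg$contrast, nucleusDiameter = nucleusDiameter)
}

#' Default end-to-end pipeline configuration
#'
#' Returns the nested configuration list consumed by
#' \code{\link{runPipeline}}, with all units annotated: distances nm, light
#' photons, camera levels counts.  The simulated acquisition mirrors a
#' typical DNA-dye SMLM run scaled to a small nuclear patch: 102 nm pixels,
#' gain 2, 150-count background, 1500-photon bursts, TF 3.
#'
#' @param regime phantom regime, \code{"open"} or \code{"compacted"}.
#' @param seed top-level seed; stage seeds are derived deterministically.
#' @return configuration list.
#' @export
defaultPipelineConfig <- function(regime = "open", seed = 1L) {
    list(
        seed = as.integer(seed),
        simulate = list(
            regime = regime,
            fieldPixels = c(48L, 48L),   # x 102 nm = 4.9 um patch
            nFrames = 2500L,
            ## compaction reduces dye binding by ~30%
            nEmitters = if (regime == "compacted") 14000L else 20000L,
            pixelSize = 102, psfSigma = 130,
            backgroundCounts = 150, gain = 2,
            meanBurstPhotons = 1500, blinkProb = 2.5e-4,
            driftRate = c(0, 0)          # nm/h
        ),
        detection = list(tf = 3, psfSigma = 130, joinRadiusFactor = 2.5),
        drift = list(enabled = FALSE, nSubsets = NULL, renderPixel = 20),
        render = list(pixel = 5, blur = "mean"),
        stats = list(binSize = 400, nnK = 500L, roiUm = 2, nRois = 3L,
            threshold8bit = 50, freeAreaPixel = 50, farCutoff = 80,
            highThreshold = 25)
    )
}

## deterministic per-stage seeds below 2^31
.stageSeed <- function(seed, stage) {
    (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) an acquisition, localizes every frame, joins
#' consecutive-frame bursts, corrects drift, renders a reconstruction, and
#' computes the compaction report: localization density, binned counts with
#' skewness, k-nearest-neighbour summaries, chromatin-free-area fraction
#' and the resolution estimate.  Fully deterministic under the top-level
#' seed.  Optionally writes all artifacts (localization CSV, drift
#' trajectory CSV, reconstruction TIFF, report JSON) to \code{outDir}.
#'
#' @param config configuration list, see
#'   \code{\link{defaultPipelineConfig}}; alternatively a path to a YAML
#'   file readable by \code{\link{readPipelineConfig}}.
#' @param outDir optional output directory for artifacts.
#' @param verbose log per-stage progress and counts.
#' @return the compaction report (named list).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = NULL,
        verbose = FALSE) {
    if (is.character(config)) config <- readPipelineConfig(config)
    seed <- config$seed
    say <- function(...) if (verbose) message(sprintf(...))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                conditionMessage(e), call. = FALSE))
    }

    ## --- acquisition -----------------------------------------------------
    sim <- config$simulate
    if (!is.null(sim)) {
        stack <- stage("simulate", {
            phantom <- nuclearPhantom(sim$regime,
                fieldSize = sim$fieldPixels * sim$pixelSize,
                seed = .stageSeed(seed, 1))
            acq <- AcquisitionConfig(nFrames = sim$nFrames,
                fieldPixels = sim$fieldPixels, pixelSize = sim$pixelSize,
                psfSigma = sim$psfSigma,
                backgroundCounts = sim$backgroundCounts, gain = sim$gain,
                meanBurstPhotons = sim$meanBurstPhotons,
                blinkProb = sim$blinkProb)
            em <- sampleEmitters(phantom, sim$nEmitters,
                seed = .stageSeed(seed, 2))
            em <- makeBlinkSchedule(em, acq, seed = .stageSeed(seed, 3))
            drift <- if (any(sim$driftRate != 0))
                DriftModel(rate = sim$driftRate,
                    frameInterval = 0.05) else NULL
            simulateStack(em, acq, drift = drift,
                seed = .stageSeed(seed, 4))
        })
        say("simulate: %d frames, %d ground-truth bursts", nFrames(stack),
            nrow(groundTruth(stack)))
    } else {
        stack <- stage("read", readStack(config$input$stack,
            pixelSize = config$input$pixelSize, gain = config$input$gain))
    }

    ## --- localization ----------------------------------------------------
    det <- config$detection
    cfg <- DetectionConfig(thresholdFactor = det$tf,
        joinRadiusFactor = det$joinRadiusFactor)
    table <- stage("localize",
        localizeStack(stack, cfg, psfSigma = det$psfSigma,
            verbose = verbose))
    say("localize: %d records", nLocalizations(table))

    ## --- drift correction ------------------------------------------------
    traj <- NULL
    sigmaDrift <- 0
    if (isTRUE(config$drift$enabled)) {
        traj <- stage("driftcorr", estimateDrift(table,
            nSubsets = config$drift$nSubsets,
            renderPixel = config$drift$renderPixel))
        table <- applyDrift(table, traj)
        sigmaDrift <- traj@residualStd
        say("driftcorr: residual subset-shift SD %.2f nm", sigmaDrift)
    }

    ## --- reconstruction --------------------------------------------------
    recon <- stage("render", renderLocalizations(table,
        pixel = config$render$pixel, blur = config$render$blur))

    ## --- compaction statistics -------------------------------------------
    st <- config$stats
    rec <- locData(table)
    fieldNm <- if (!is.null(sim)) sim$fieldPixels * sim$pixelSize else
        c(max(rec$x), max(rec$y))
    report <- stage("stats", {
        ## provisional density over the data extent sets the kernel width
        approxDensity <- nLocalizations(table) /
            (diff(range(rec$x)) * diff(range(rec$y)) / 1e6)
        ## free-area reconstruction smoothed at the sampling-resolution
        ## scale 2/sqrt(alpha): below that scale a reconstruction carries
        ## no information, and coarser data need a wider kernel to yield
        ## the continuous image the thresholding step assumes
        blurSigma <- max(samplingSigma(approxDensity),
            mean(rec$uncertainty))
        faRecon <- renderLocalizations(table, pixel = st$freeAreaPixel,
            blur = "fixed", blurSigma = blurSigma,
            bounds = list(xlim = c(0, fieldNm[1]), ylim = c(0, fieldNm[2])))
        fa <- freeAreaFraction(faRecon, pixel = st$freeAreaPixel,
            threshold = st$threshold8bit)
        ## density over the whole detected nucleus
        mask <- nuclearMask(faRecon, threshold = st$threshold8bit)
        density <- localizationDensity(table, mask, st$freeAreaPixel)
        bins <- binHistogram(table, st$binSize,
            highThreshold = st$highThreshold)
        rois <- .centralRois(fieldNm, st$roiUm * 1000, st$nRois)
        nn <- nnMeanDistances(table, rois, k = st$nnK,
            farCutoff = st$farCutoff)
        resEst <- totalResolution(mean(rec$uncertainty),
            samplingSigma(density),
            if (is.finite(sigmaDrift)) sigmaDrift else 0, alpha = density)
        frc <- if (nLocalizations(table) >= 2000) {
            set.seed(.stageSeed(seed, 5))
            as.numeric(frcResolution(table, pixel = 20))
        } else NA_real_
        list(
            nLocalizations = nLocalizations(table),
            densityPerUm2 = density,
            binning = list(binSize = st$binSize,
                nBins = length(bins@counts), median = bins@median,
                q1 = bins@q1, q3 = bins@q3, skewness = bins@skewness,
                propHigh = bins@propHigh),
            nn = list(k = nn@k, median = nn@median, q1 = nn@q1,
                q3 = nn@q3, propFar = nn@propFar),
            freeArea = list(nuclearAreaUm2 = fa@nuclearArea,
                chromatinAreaUm2 = fa@chromatinArea,
                freeFraction = fa@freeFraction),
            resolution = list(sigmaLoc = resEst@sigmaLoc,
                sigmaSampling = resEst@sigmaSampling,
                sigmaDrift = resEst@sigmaDrift,
                sigmaTotal = resEst@sigmaTotal,
                structuralFWHM = resEst@structuralFWHM),
            frcResolutionNm = frc,
            counters = as.list(locMetadata(table)$counters))
    })

    ## --- artifacts -------------------------------------------------------
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeLocalizations(table, file.path(outDir, "localizations.csv"))
        if (!is.null(traj))
            utils::write.csv(data.frame(frame = traj@frames,
                dx = traj@dx, dy = traj@dy),
                file.path(outDir, "drift_trajectory.csv"),
                row.names = FALSE)
        reconScaled <- recon / max(recon)
        tiff::writeTIFF(reconScaled, file.path(outDir, "reconstruction.tif"),
            bits.per.sample = 16, compression = "none")
        jsonlite::write_json(report, file.path(outDir, "report.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    report
}

## n square ROIs along the central part of the field diagonal
.centralRois <- function(fieldNm, roiNm, n) {
    roiNm <- min(roiNm, 0.45 * min(fieldNm))
    cx <- fieldNm[1] * seq(0.4, 0.6, length.out = n)
    cy <- fieldNm[2] * seq(0.4, 0.6, length.out = n)
    data.frame(xmin = cx - roiNm / 2, xmax = cx + roiNm / 2,
        ymin = cy - roiNm / 2, ymax = cy + roiNm / 2)
}
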