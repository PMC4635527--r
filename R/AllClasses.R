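#' @import methods
NULL

#' FrameStack: a time-ordered camera acquisition
#'
#' Container for a multi-frame grayscale camera stack in raw counts, together
#' with the two pieces of calibration metadata every downstream stage needs:
#' the effective pixel pitch in the sample plane (nm) and the camera gain
#' (photons per count).
#'
#' Frames are stored as a 3-D numeric array \code{[row, col, frame]} where the
#' row index runs along y and the column index along x.  Pixel \code{(i, j)}
#' (0-based) covers the half-open square
#' \code{[j*p, (j+1)*p) x [i*p, (i+1)*p)} nm, so the centre of that pixel is
#' at \code{((j + 0.5)*p, (i + 0.5)*p)}.
#'
#' @slot frames numeric 3-D array of pixel counts, \code{[y, x, frame]}.
#' @slot pixelSize effective pixel size in the sample plane, nm.
#' @slot gain camera gain, photons per count.
#' @slot groundTruth optional data.frame of true emitter bursts
#'   (\code{emitter_id, frame, x_nm, y_nm, photons}) carried along by the
#'   simulator; empty for real acquisitions.
#'
#' @export
setClass("FrameStack",
    representation(
        frames = "array",
        pixelSize = "numeric",
        gain = "numeric",
        groundTruth = "data.frame"
    ),
    prototype(
        frames = array(0, c(0, 0, 0)),
        pixelSize = 102,
        gain = 2,
        groundTruth = data.frame()
    )
)

setValidity("FrameStack", function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 3L)
        msg <- c(msg, "'frames' must be a 3-D array [y, x, frame]")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be a single positive number (nm)")
    if (length(object@gain) != 1L || object@gain <= 0)
        msg <- c(msg, "'gain' must be a single positive number (photons/count)")
    if (any(object@frames < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' LocalizationTable: fitted single-molecule positions
#'
#' One row per localized emitter burst.  Canonical columns (all distances nm,
#' light in photons):
#' \describe{
#'   \item{frame}{1-based acquisition frame index.}
#'   \item{x, y}{position in the sample plane, nm.}
#'   \item{photons}{collected photon count N.}
#'   \item{sigma}{PSF standard deviation s assumed during fitting, nm.}
#'   \item{uncertainty}{predicted localization precision sigma_loc, nm.}
#'   \item{background}{background noise b at the fit, photons/pixel.}
#' }
#'
#' @slot records data.frame with the canonical columns above; frame indices
#'   are non-decreasing.
#' @slot metadata named list of acquisition/analysis parameters (pixel size,
#'   threshold factor, gain, ...).
#'
#' @export
setClass("LocalizationTable",
    representation(records = "data.frame", metadata = "list"),
    prototype(records = data.frame(
        frame = integer(), x = numeric(), y = numeric(),
        photons = numeric(), sigma = numeric(), uncertainty = numeric(),
        background = numeric()), metadata = list())
)

.LOC_COLUMNS <- c("frame", "x", "y", "photons", "sigma", "uncertainty",
    "background")

setValidity("LocalizationTable", function(object) {
    msg <- character()
    rec <- object@records
    missing <- setdiff(.LOC_COLUMNS, names(rec))
    if (length(missing))
        msg <- c(msg, paste0("records lack mandatory column(s): ",
            paste(missing, collapse = ", ")))
    if (!length(missing) && nrow(rec)) {
        if (is.unsorted(rec$frame))
            msg <- c(msg, "frame indices must be non-decreasing")
        if (any(rec$photons <= 0, na.rm = TRUE))
            msg <- c(msg, "photon counts must be positive")
        if (any(rec$uncertainty <= 0, na.rm = TRUE))
            msg <- c(msg, "localization precision must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' ChromatinPhantom: ground-truth nuclear chromatin density model
#'
#' An analytic spatial density over a rectangular field, mimicking the three
#' regimes seen in nuclei: DNA-dense hollow \emph{atolls} (annuli of high
#' emitter density), chromatin-sparse \emph{voids} (zero density), and a
#' uniform \emph{diffuse} floor everywhere else.  The total probability mass
#' splits as \code{1 - diffuseWeight} inside atoll rings and
#' \code{diffuseWeight} over the remaining (non-void, non-ring) area; the
#' implied ratio of per-area emitter densities is stored as
#' \code{densityContrast}.
#'
#' @slot fieldSize numeric length-2, field extent (x, y) in nm.
#' @slot nucleusDiameter diameter of the nuclear disk centred in the field,
#'   nm; \code{NA} means the whole field is nuclear interior.  Emitter
#'   density is zero outside the nucleus.
#' @slot atolls data.frame with columns \code{x, y, outer, thickness} (nm):
#'   annulus centres, outer diameters and ring thicknesses.
#' @slot voids data.frame with columns \code{x, y, diameter} (nm).
#' @slot diffuseWeight fraction of emitters placed on the diffuse floor.
#' @slot densityContrast derived in-ring to diffuse density ratio.
#'
#' @export
setClass("ChromatinPhantom",
    representation(
        fieldSize = "numeric",
        nucleusDiameter = "numeric",
        atolls = "data.frame",
        voids = "data.frame",
        diffuseWeight = "numeric",
        densityContrast = "numeric"
    ),
    prototype(nucleusDiameter = NA_real_)
)

setValidity("ChromatinPhantom", function(object) {
    msg <- character()
    if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0))
        msg <- c(msg, "'fieldSize' must be two positive extents (nm)")
    nd <- object@nucleusDiameter
    if (length(nd) == 1L && is.finite(nd)) {
        if (nd <= 0 || nd > min(object@fieldSize))
            msg <- c(msg, "'nucleusDiameter' must fit inside the field")
    }
    cx <- object@fieldSize[1] / 2
    cy <- object@fieldSize[2] / 2
    inBounds <- function(x, y, r) {
        ok <- x - r >= 0 & x + r <= object@fieldSize[1] &
            y - r >= 0 & y + r <= object@fieldSize[2]
        if (is.finite(nd))
            ok <- ok & sqrt((x - cx)^2 + (y - cy)^2) + r <= nd / 2
        ok
    }
    a <- object@atolls
    if (nrow(a)) {
        if (any(a$thickness <= 0) || any(a$thickness >= a$outer / 2))
            msg <- c(msg, "ring thickness must lie in (0, outer/2)")
        if (!all(inBounds(a$x, a$y, a$outer / 2)))
            msg <- c(msg, "atoll extends outside the field or nucleus")
    }
    v <- object@voids
    if (nrow(v)) {
        if (!all(inBounds(v$x, v$y, v$diameter / 2)))
            msg <- c(msg, "void extends outside the field or nucleus")
    }
    if (object@diffuseWeight < 0 || object@diffuseWeight > 1)
        msg <- c(msg, "'diffuseWeight' must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' EmitterSet: ground-truth emitter positions and blink schedule
#'
#' @slot positions numeric matrix, n x 2, emitter (x, y) in nm.
#' @slot blinks data.frame with columns \code{emitter, frame, photons}: one
#'   row per blink event (burst); photons emitted during that frame.
#'
#' @export
setClass("EmitterSet",
    representation(positions = "matrix", blinks = "data.frame"),
    prototype(positions = matrix(numeric(), ncol = 2),
        blinks = data.frame(emitter = integer(), frame = integer(),
            photons = numeric()))
)

setValidity("EmitterSet", function(object) {
    msg <- character()
    if (ncol(object@positions) != 2L)
        msg <- c(msg, "'positions' must have two columns (x, y) in nm")
    b <- object@blinks
    if (nrow(b)) {
        if (any(b$photons <= 0))
            msg <- c(msg, "blink photon counts must be positive")
        if (any(b$emitter < 1 | b$emitter > nrow(object@positions)))
            msg <- c(msg, "blink emitter index out of range")
    }
    if (length(msg)) msg else TRUE
})

#' AcquisitionConfig: camera and illumination parameters for simulation
#'
#' Defaults reflect a typical widefield SMLM acquisition of DNA-dye stained
#' nuclei: 102 nm effective pixel size, gain 2 photons/count, uniform
#' background of 150 counts (300 photons) per pixel, bursts averaging 1500
#' photons, 50 ms exposures.
#'
#' @slot nFrames number of frames to simulate.
#' @slot fieldPixels integer length-2, frame size (nx, ny) in pixels.
#' @slot pixelSize nm per pixel.
#' @slot psfSigma Gaussian PSF standard deviation, nm.
#' @slot backgroundCounts uniform background level, counts/pixel.
#' @slot gain photons per count.
#' @slot meanBurstPhotons mean photons emitted per blink event.
#' @slot minBurstPhotons lower truncation of the burst-photon distribution.
#' @slot blinkProb per-frame probability that an emitter is active.
#' @slot exposureMs exposure time label, ms (metadata only).
#'
#' @export
setClass("AcquisitionConfig",
    representation(
        nFrames = "integer", fieldPixels = "integer",
        pixelSize = "numeric", psfSigma = "numeric",
        backgroundCounts = "numeric", gain = "numeric",
        meanBurstPhotons = "numeric", minBurstPhotons = "numeric",
        blinkProb = "numeric", exposureMs = "numeric"
    ),
    prototype(
        nFrames = 1000L, fieldPixels = c(64L, 64L),
        pixelSize = 102, psfSigma = 130,
        backgroundCounts = 150, gain = 2,
        meanBurstPhotons = 1500, minBurstPhotons = 100,
        blinkProb = 1e-3, exposureMs = 50
    )
)

setValidity("AcquisitionConfig", function(object) {
    msg <- character()
    if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
    if (object@psfSigma <= 0) msg <- c(msg, "'psfSigma' must be > 0")
    if (object@gain <= 0) msg <- c(msg, "'gain' must be > 0")
    if (object@backgroundCounts < 0)
        msg <- c(msg, "'backgroundCounts' must be >= 0")
    if (object@nFrames < 1L) msg <- c(msg, "'nFrames' must be >= 1")
    if (length(object@fieldPixels) != 2L || any(object@fieldPixels < 1L))
        msg <- c(msg, "'fieldPixels' must be two positive pixel counts")
    if (object@blinkProb <= 0 || object@blinkProb > 1)
        msg <- c(msg, "'blinkProb' must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' DriftModel: linear sample drift
#'
#' Drift is zero at frame 1 and grows linearly with acquisition time.
#'
#' @slot rate numeric length-2, drift velocity (x, y) in nm/h.
#' @slot frameInterval time between frame starts, seconds.
#'
#' @export
setClass("DriftModel",
    representation(rate = "numeric", frameInterval = "numeric"),
    prototype(rate = c(150, 0), frameInterval = 0.05)
)

setValidity("DriftModel", function(object) {
    if (length(object@rate) != 2L)
        return("'rate' must be a length-2 (x, y) vector in nm/h")
    if (object@frameInterval <= 0)
        return("'frameInterval' must be positive (seconds)")
    TRUE
})

#' DriftTrajectory: estimated per-frame sample drift
#'
#' @slot frames integer vector of frame indices covered.
#' @slot dx,dy estimated drift per frame, nm (zero at the reference subset).
#' @slot subsetShifts data.frame \code{subset, centerFrame, dx, dy}: the raw
#'   cross-correlation shifts of each temporal subset against the first.
#' @slot residualStd pooled standard deviation of subset shifts re-estimated
#'   after correction, nm (the sigma_drift diagnostic).
#'
#' @export
setClass("DriftTrajectory",
    representation(frames = "integer", dx = "numeric", dy = "numeric",
        subsetShifts = "data.frame", residualStd = "numeric")
)

setValidity("DriftTrajectory", function(object) {
    msg <- character()
    n <- length(object@frames)
    if (length(object@dx) != n || length(object@dy) != n)
        msg <- c(msg, "'dx'/'dy' must match 'frames' in length")
    if (n && (abs(object@dx[1]) > 1e-9 || abs(object@dy[1]) > 1e-9))
        msg <- c(msg, "trajectory must be (0, 0) at the reference subset")
    if (length(msg)) msg else TRUE
})

#' ResolutionEstimate: decomposition of the achievable image resolution
#'
#' Combines the mean localization precision, the Nyquist-type sampling term
#' \code{sigma_sampling = 2/sqrt(alpha)} set by the localization density
#' alpha, and the residual drift, in quadrature:
#' \code{sigma_total^2 = sigma_loc^2 + sigma_sampling^2 + sigma_drift^2}.
#' The structural resolution is the Gaussian FWHM
#' \code{2*sqrt(2*ln 2) * sigma_total}.
#'
#' @slot sigmaLoc mean localization precision, nm.
#' @slot alpha localization density, localizations/um^2 (NA if not supplied).
#' @slot sigmaSampling sampling term, nm.
#' @slot sigmaDrift residual drift, nm.
#' @slot sigmaTotal quadrature total, nm.
#' @slot structuralFWHM \code{2*sqrt(2*ln 2)*sigmaTotal}, nm.
#' @slot structuralFWHM10 the FWHM rounded to the nearest 10 nm.
#'
#' @export
setClass("ResolutionEstimate",
    representation(sigmaLoc = "numeric", alpha = "numeric",
        sigmaSampling = "numeric", sigmaDrift = "numeric",
        sigmaTotal = "numeric", structuralFWHM = "numeric",
        structuralFWHM10 = "numeric")
)

#' BinningResult: grid-binned localization counts and their skewness
#'
#' @slot binSize grid width, nm.
#' @slot counts integer vector of localizations per retained bin (bins with
#'   fewer than 2 localizations are discarded).
#' @slot bins data.frame \code{ix, iy, n} of retained grid squares.
#' @slot median,q1,q3 summary of retained counts (type-7 quantiles).
#' @slot skewness Fisher-Pearson g1 of retained counts.
#' @slot propHigh fraction of retained bins with >= \code{highThreshold}.
#' @slot highThreshold count threshold for \code{propHigh} (default 25).
#'
#' @export
setClass("BinningResult",
    representation(binSize = "numeric", counts = "integer",
        bins = "data.frame", median = "numeric", q1 = "numeric",
        q3 = "numeric", skewness = "numeric", propHigh = "numeric",
        highThreshold = "numeric")
)

setValidity("BinningResult", function(object) {
    msg <- character()
    if (length(object@counts) && any(object@counts < 2L))
        msg <- c(msg, "retained bins must hold >= 2 localizations")
    if (!(object@q1 <= object@median && object@median <= object@q3))
        msg <- c(msg, "quartiles must be ordered q1 <= median <= q3")
    if (object@propHigh < 0 || object@propHigh > 1)
        msg <- c(msg, "'propHigh' must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' NNResult: k-nearest-neighbour distance summaries
#'
#' @slot k number of neighbours averaged per localization.
#' @slot meanDistances per-localization mean distance to its k nearest
#'   neighbours (nm), pooled over ROIs.
#' @slot median,q1,q3 summary of \code{meanDistances} (type-7 quantiles).
#' @slot propFar fraction of localizations whose mean distance to their 100
#'   nearest neighbours is >= 80 nm (NA when any ROI holds <= 100 points).
#' @slot rois data.frame \code{xmin, xmax, ymin, ymax} (nm) of the regions
#'   analysed.
#'
#' @export
setClass("NNResult",
    representation(k = "integer", meanDistances = "numeric",
        median = "numeric", q1 = "numeric", q3 = "numeric",
        propFar = "numeric", rois = "data.frame")
)

setValidity("NNResult", function(object) {
    if (length(object@meanDistances) && any(object@meanDistances < 0))
        return("distances must be non-negative")
    TRUE
})

#' FreeAreaResult: chromatin-free nuclear area
#'
#' @slot nuclearArea hole-filled nuclear area, um^2.
#' @slot chromatinArea above-threshold (chromatin) area inside the nucleus,
#'   um^2.
#' @slot freeFraction \code{(nuclearArea - chromatinArea)/nuclearArea}.
#' @slot threshold 8-bit intensity threshold separating chromatin from free
#'   area after histogram stretching (default 50).
#'
#' @export
setClass("FreeAreaResult",
    representation(nuclearArea = "numeric", chromatinArea = "numeric",
        freeFraction = "numeric", threshold = "numeric")
)

setValidity("FreeAreaResult", function(object) {
    msg <- character()
    if (object@chromatinArea > object@nuclearArea + 1e-9)
        msg <- c(msg, "chromatin area cannot exceed nuclear area")
    f <- (object@nuclearArea - object@chromatinArea) / object@nuclearArea
    if (abs(f - object@freeFraction) > 1e-9)
        msg <- c(msg, "'freeFraction' inconsistent with the areas")
    if (length(msg)) msg else TRUE
})
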