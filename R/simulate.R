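#' Acquisition configuration constructor
#'
#' @param nFrames frames to simulate.
#' @param fieldPixels frame size (nx, ny), pixels.
#' @param pixelSize nm per pixel in the sample plane.
#' @param psfSigma Gaussian PSF standard deviation, nm.
#' @param backgroundCounts uniform background, counts/pixel.
#' @param gain photons per count.
#' @param meanBurstPhotons mean photons per blink event.
#' @param minBurstPhotons lower truncation of burst photons.
#' @param blinkProb per-frame on-probability of an emitter.
#' @param exposureMs exposure time, ms (metadata only).
#' @return an \linkS4class{AcquisitionConfig}.
#' @export
AcquisitionConfig <- function(nFrames = 1000, fieldPixels = c(64, 64),
        pixelSize = 102, psfSigma = 130, backgroundCounts = 150, gain = 2,
        meanBurstPhotons = 1500, minBurstPhotons = 100, blinkProb = 1e-3,
        exposureMs = 50) {
    new("AcquisitionConfig", nFrames = as.integer(nFrames),
        fieldPixels = as.integer(fieldPixels), pixelSize = pixelSize,
        psfSigma = psfSigma, backgroundCounts = backgroundCounts,
        gain = gain, meanBurstPhotons = meanBurstPhotons,
        minBurstPhotons = minBurstPhotons, blinkProb = blinkProb,
        exposureMs = exposureMs)
}

#' Linear drift model constructor
#'
#' @param rate drift velocity (x, y), nm/h.
#' @param frameInterval seconds between frame starts.
#' @return a \linkS4class{DriftModel}.
#' @export
DriftModel <- function(rate = c(150, 0), frameInterval = 0.05) {
    new("DriftModel", rate = as.numeric(rate), frameInterval = frameInterval)
}

#' Drift displacement at given frames
#'
#' Zero at frame 1, linear in elapsed time thereafter.
#'
#' @param drift a \linkS4class{DriftModel}.
#' @param frames frame indices (1-based).
#' @return matrix with columns dx, dy in nm.
#' @export
driftAt <- function(drift, frames) {
    tHours <- (frames - 1) * drift@frameInterval / 3600
    cbind(dx = drift@rate[1] * tHours, dy = drift@rate[2] * tHours)
}

#' Assign a blink schedule to an emitter set
#'
#' Blinking is modelled as a memoryless two-state process: each emitter is
#' independently active in any frame with probability \code{blinkProb}, and
#' an active frame emits a photon count drawn from a shifted exponential
#' (minimum \code{minBurstPhotons}, mean \code{meanBurstPhotons}).
#'
#' @param emitters an \linkS4class{EmitterSet} (positions only).
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param seed optional integer seed.
#' @return the emitter set with its \code{blinks} slot filled.
#' @export
makeBlinkSchedule <- function(emitters, acq, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    nE <- nrow(emitters@positions)
    if (nE == 0)
        return(emitters)
    nOn <- stats::rbinom(nE, acq@nFrames, acq@blinkProb)
    emitter <- rep(seq_len(nE), nOn)
    frame <- unlist(lapply(seq_len(nE), function(i) {
        if (nOn[i] > 0) sample.int(acq@nFrames, nOn[i]) else integer()
    }), use.names = FALSE)
    nBlink <- length(emitter)
    photons <- acq@minBurstPhotons +
        stats::rexp(nBlink, 1 / (acq@meanBurstPhotons - acq@minBurstPhotons))
    blinks <- data.frame(emitter = emitter, frame = as.integer(frame),
        photons = photons)
    blinks <- blinks[order(blinks$frame, blinks$emitter), , drop = FALSE]
    rownames(blinks) <- NULL
    emitters@blinks <- blinks
    validObject(emitters)
    emitters
}

## expected photons an emitter at (x, y) nm deposits in each pixel of a
## window; integrated (error-function) Gaussian PSF over the pixel grid
.psfWindow <- function(x, y, photons, s, p, nx, ny, truncSigmas = 5) {
    half <- ceiling(truncSigmas * s / p)
    cx <- floor(x / p)                  # 0-based pixel containing the emitter
    cy <- floor(y / p)
    jx <- max(0, cx - half):min(nx - 1, cx + half)
    jy <- max(0, cy - half):min(ny - 1, cy + half)
    if (!length(jx) || !length(jy))
        return(NULL)
    fx <- stats::pnorm((jx + 1) * p, x, s) - stats::pnorm(jx * p, x, s)
    fy <- stats::pnorm((jy + 1) * p, y, s) - stats::pnorm(jy * p, y, s)
    list(rows = jy + 1, cols = jx + 1, photons = photons * outer(fy, fx))
}

#' Simulate an SMLM acquisition
#'
#' Renders each frame as background photons plus integrated-Gaussian PSFs of
#' the emitters blinking in that frame (optionally displaced by linear
#' drift), applies Poisson shot noise to the expected photon image, and
#' converts photons to camera counts by dividing by the gain.  Ground-truth
#' burst positions are retained in the returned stack.
#'
#' @param emitters an \linkS4class{EmitterSet} with a blink schedule.
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param drift optional \linkS4class{DriftModel}.
#' @param seed optional integer seed for the shot noise.
#' @param noise logical; \code{FALSE} yields the noise-free expectation
#'   (useful for validating photon bookkeeping).
#' @return a \linkS4class{FrameStack} whose \code{groundTruth} holds one row
#'   per burst: \code{emitter_id, frame, x_nm, y_nm, photons} (positions
#'   include any drift).
#' @export
simulateStack <- function(emitters, acq, drift = NULL, seed = NULL,
        noise = TRUE) {
    if (!is.null(seed)) set.seed(seed)
    nx <- acq@fieldPixels[1]
    ny <- acq@fieldPixels[2]
    nF <- acq@nFrames
    blinks <- emitters@blinks
    if (nrow(blinks) && max(blinks$frame) > nF)
        stop("blink schedule extends past frame ", nF)
    dxy <- if (is.null(drift)) matrix(0, nF, 2) else driftAt(drift, seq_len(nF))
    bgPhotons <- acq@backgroundCounts * acq@gain

    frames <- array(0, c(ny, nx, nF))
    gt <- vector("list", nrow(blinks))
    bi <- 0L
    byFrame <- if (nrow(blinks)) split(blinks, blinks$frame) else list()
    for (f in seq_len(nF)) {
        expected <- matrix(bgPhotons, ny, nx)
        fb <- byFrame[[as.character(f)]]
        if (!is.null(fb)) {
            for (r in seq_len(nrow(fb))) {
                e <- fb$emitter[r]
                xs <- emitters@positions[e, 1] + dxy[f, 1]
                ys <- emitters@positions[e, 2] + dxy[f, 2]
                w <- .psfWindow(xs, ys, fb$photons[r], acq@psfSigma,
                    acq@pixelSize, nx, ny)
                if (!is.null(w))
                    expected[w$rows, w$cols] <-
                        expected[w$rows, w$cols] + w$photons
                bi <- bi + 1L
                gt[[bi]] <- data.frame(emitter_id = e, frame = f,
                    x_nm = xs, y_nm = ys, photons = fb$photons[r])
            }
        }
        counts <- if (noise) {
            matrix(stats::rpois(ny * nx, expected), ny, nx) / acq@gain
        } else expected / acq@gain
        frames[, , f] <- counts
    }
    gtd <- if (bi > 0) do.call(rbind, gt[seq_len(bi)]) else
        data.frame(emitter_id = integer(), frame = integer(),
            x_nm = numeric(), y_nm = numeric(), photons = numeric())
    new("FrameStack", frames = frames, pixelSize = acq@pixelSize,
        gain = acq@gain, groundTruth = gtd)
}
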