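#' Localization precision of a point emitter
#'
#' The predicted standard deviation of a centre-of-intensity position
#' estimate for a Gaussian spot of width s (nm) sampled on pixels of pitch
#' p (nm) with N collected photons over background noise b (photons/pixel):
#' \deqn{\sigma_{loc}^2 = \frac{s^2 + p^2/12}{N} +
#'       \frac{8 \pi s^4 b^2}{p^2 N^2}}
#'
#' @param N photon count(s), must be positive.
#' @param s PSF standard deviation, nm.
#' @param p pixel size, nm.
#' @param b background noise, photons/pixel.
#' @return sigma_loc in nm (vectorized over \code{N} and \code{b}).
#' @examples
#' estimatePrecision(1500, s = 130, p = 102, b = sqrt(300))
#' @export
estimatePrecision <- function(N, s, p, b) {
    if (any(N <= 0)) stop("photon count N must be positive")
    stopifnot(s > 0, p > 0, all(b >= 0))
    sqrt((s^2 + p^2 / 12) / N + 8 * pi * s^4 * b^2 / (p^2 * N^2))
}

## the 8 radial directions of the overlap-clipping rule
.RADIAL_DIRS <- rbind(
    c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))

## zero, along each of 8 rays from the ROI centre, every pixel beyond the
## first radius at which intensity increases moving outward (radius 0 =
## centre included in the comparison); returns the clipped ROI
.clipOverlap <- function(roi, halfWidth) {
    cr <- halfWidth + 1L
    for (d in seq_len(nrow(.RADIAL_DIRS))) {
        dr <- .RADIAL_DIRS[d, 1]
        dc <- .RADIAL_DIRS[d, 2]
        prev <- roi[cr, cr]
        clipping <- FALSE
        for (k in seq_len(halfWidth)) {
            v <- roi[cr + k * dr, cr + k * dc]
            if (!clipping && v > prev)
                clipping <- TRUE
            if (clipping)
                roi[cr + k * dr, cr + k * dc] <- 0
            prev <- v
        }
    }
    roi
}

#' Refine a candidate to subpixel accuracy
#'
#' Extracts a (2h+1) x (2h+1) ROI of the (smoothed) difference image around
#' the candidate pixel, clips overlapping neighbour signals (detected as
#' radially increasing intensity away from the centre), and computes the
#' intensity-weighted centre of intensity.  Candidates are rejected when the
#' ROI does not fit inside the frame, when clipping removes more than
#' \code{clipLossLimit} of the accumulated signal, or when the ROI sum is
#' not positive.
#'
#' The full pipeline passes the 3x3-mean-smoothed difference image here (the
#' same image detection thresholds): averaging suppresses the centroid noise
#' and spurious clip triggers that single-pixel shot noise causes, while the
#' box average leaves the centre of intensity of a smooth spot unchanged.
#'
#' @param diff difference image (raw or smoothed), counts.
#' @param candidate integer (row, col) pixel position.
#' @param cfg a \code{\link{DetectionConfig}}.
#' @param gain photons per count.
#' @param s assumed PSF standard deviation, nm.
#' @param p pixel size, nm.
#' @param bg background state (for the local noise estimate b).
#' @return a list \code{list(loc, reason)}: \code{loc} is a one-row
#'   data.frame (x, y, photons, sigma, uncertainty, background) on success
#'   and \code{NULL} on rejection; \code{reason} is one of \code{"ok"},
#'   \code{"border"}, \code{"clip_loss"}, \code{"nonpositive"}.
#' @export
refineCandidate <- function(diff, candidate, cfg, gain, s, p, bg) {
    h <- cfg$roiHalfWidth
    r <- candidate[1]
    cc <- candidate[2]
    nr <- nrow(diff)
    nc <- ncol(diff)
    if (r <= h || r > nr - h || cc <= h || cc > nc - h)
        return(list(loc = NULL, reason = "border"))
    roi <- diff[(r - h):(r + h), (cc - h):(cc + h)]
    roi[roi < 0] <- 0
    sumPre <- sum(roi)
    if (sumPre <= 0)
        return(list(loc = NULL, reason = "nonpositive"))
    roi <- .clipOverlap(roi, h)
    sumPost <- sum(roi)
    if (sumPost <= 0)
        return(list(loc = NULL, reason = "nonpositive"))
    if ((sumPre - sumPost) / sumPre > cfg$clipLossLimit)
        return(list(loc = NULL, reason = "clip_loss"))
    ## centre of intensity in nm; pixel (i, j) 1-based has centre
    ## ((j - 0.5) p, (i - 0.5) p)
    rows <- (r - h):(r + h)
    cols <- (cc - h):(cc + h)
    wRow <- rowSums(roi)
    wCol <- colSums(roi)
    yc <- sum(wRow * (rows - 0.5)) / sumPost * p
    xc <- sum(wCol * (cols - 0.5)) / sumPost * p
    N <- sumPost * gain
    b <- mean(bg$std[rows, cols]) * gain
    list(loc = data.frame(x = xc, y = yc, photons = N, sigma = s,
        uncertainty = estimatePrecision(N, s, p, b), background = b),
        reason = "ok")
}
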