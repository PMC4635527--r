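#' Detection configuration
#'
#' @param thresholdFactor TF; the detection cutoff is \code{(TF - 1) * STD}
#'   on the smoothed difference image.  Use 3 for DNA dyes and 3.5 for
#'   AlexaFluor 647.
#' @param roiHalfWidth half-width of the refinement ROI in pixels (3 gives
#'   the 7x7 ROI).
#' @param clipLossLimit fraction of accumulated ROI signal that overlap
#'   clipping may remove before the candidate is discarded.
#' @param joinRadiusFactor multiple of the mean localization precision used
#'   as the consecutive-frame joining search radius.
#' @return a list used by the detection and refinement steps.
#' @export
DetectionConfig <- function(thresholdFactor = 3, roiHalfWidth = 3L,
        clipLossLimit = 0.30, joinRadiusFactor = 2.5) {
    stopifnot(thresholdFactor > 1, clipLossLimit > 0, clipLossLimit < 1,
        roiHalfWidth >= 1)
    list(thresholdFactor = thresholdFactor,
        roiHalfWidth = as.integer(roiHalfWidth),
        clipLossLimit = clipLossLimit,
        joinRadiusFactor = joinRadiusFactor)
}

## 3x3 mean filter with replicated edges
.meanFilter3 <- function(m) {
    nr <- nrow(m)
    nc <- ncol(m)
    pad <- matrix(0, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- m
    pad[1, ] <- pad[2, ]
    pad[nr + 2, ] <- pad[nr + 1, ]
    pad[, 1] <- pad[, 2]
    pad[, nc + 2] <- pad[, nc + 1]
    acc <- matrix(0, nr, nc)
    for (dr in 0:2)
        for (dc in 0:2)
            acc <- acc + pad[dr + 1:nr, dc + 1:nc]
    acc / 9
}

#' Detect candidate single-molecule signals
#'
#' Smooths the difference image with a 3x3 mean filter, then keeps
#' 8-connected local maxima whose smoothed peak intensity is at least
#' \code{(TF - 1) * STD} at that pixel.  Plateau ties are broken in favour
#' of the smaller row-major index.
#'
#' @param diff difference image, counts.
#' @param bg background state (per-pixel STD is taken from here).
#' @param cfg a \code{\link{DetectionConfig}}.
#' @return integer matrix with columns \code{row, col} (1-based pixel
#'   indices); zero rows when nothing exceeds the threshold.
#' @export
detectCandidates <- function(diff, bg, cfg = DetectionConfig()) {
    sm <- .meanFilter3(diff)
    nr <- nrow(sm)
    nc <- ncol(sm)
    ## row-major index used for deterministic plateau tie-breaks
    idx <- matrix(seq_len(nr * nc), nr, nc, byrow = TRUE)
    isMax <- matrix(TRUE, nr, nc)
    for (dr in -1:1) {
        for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            nv <- matrix(-Inf, nr, nc)
            ni <- matrix(Inf, nr, nc)
            rs <- max(1, 1 + dr):min(nr, nr + dr)
            cs <- max(1, 1 + dc):min(nc, nc + dc)
            nv[rs - dr, cs - dc] <- sm[rs, cs]
            ni[rs - dr, cs - dc] <- idx[rs, cs]
            isMax <- isMax & (sm > nv | (sm == nv & idx < ni))
        }
    }
    keep <- isMax & (sm >= (cfg$thresholdFactor - 1) * bg$std)
    which(keep, arr.ind = TRUE, useNames = TRUE)
}
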