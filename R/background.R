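#' Initial background estimate
#'
#' Averages the first eight frames of the stack; under the Poisson noise
#' model the per-pixel noise standard deviation is the square root of the
#' background, \code{STD = sqrt(background)}.
#'
#' @param stack a \linkS4class{FrameStack} with at least 8 frames.
#' @return a list with elements \code{background} and \code{std}
#'   (matrices, counts/pixel).
#' @export
initialBackground <- function(stack) {
    if (nFrames(stack) < 8)
        stop("initial background needs at least 8 frames, got ",
            nFrames(stack))
    bg <- apply(stack@frames[, , 1:8, drop = FALSE], c(1, 2), mean)
    list(background = bg, std = sqrt(bg))
}

#' Background-subtracted difference image
#'
#' @param frame a raw frame, counts.
#' @param bg a background state from \code{\link{initialBackground}} or
#'   \code{\link{updateBackground}}.
#' @return signed difference image, counts.
#' @export
differenceImage <- function(frame, bg) {
    stopifnot(all(dim(frame) == dim(bg$background)))
    frame - bg$background
}

#' Update the rolling background
#'
#' The difference image is clipped from above at STD (so bright single-
#' molecule signals do not leak into the background), scaled by 1/8 and
#' added to the previous background; the result is clipped below at zero
#' and STD recomputed.
#'
#' @param bg current background state.
#' @param diff difference image for the frame just processed, counts.
#' @return updated background state.
#' @export
updateBackground <- function(bg, diff) {
    stopifnot(all(dim(diff) == dim(bg$background)))
    newBg <- pmax(bg$background + pmin(diff, bg$std) / 8, 0)
    list(background = newBg, std = sqrt(newBg))
}
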