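## 2D histogram render used by drift estimation and FRC; fixed bounds so all
## subsets share a grid
.histRender <- function(x, y, pixel, xlim, ylim) {
    nx <- max(1L, ceiling((xlim[2] - xlim[1]) / pixel))
    ny <- max(1L, ceiling((ylim[2] - ylim[1]) / pixel))
    ix <- floor((x - xlim[1]) / pixel) + 1L
    iy <- floor((y - ylim[1]) / pixel) + 1L
    keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    m <- matrix(tabulate((ix[keep] - 1L) * ny + iy[keep], nbins = nx * ny),
        ny, nx)
    m
}

## shift of img relative to ref by FFT cross-correlation with 3-point
## parabolic subpixel peak interpolation; returns c(dx, dy) in pixels,
## positive = img displaced toward +x/+y
.xcorrShift <- function(ref, img) {
    nr <- nrow(ref)
    nc <- ncol(ref)
    F1 <- stats::fft(ref)
    F2 <- stats::fft(img)
    cc <- Re(stats::fft(Conj(F1) * F2, inverse = TRUE)) / (nr * nc)
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    ## parabolic interpolation per axis with circular neighbours
    wrap <- function(i, n) ((i - 1) %% n) + 1
    sub <- function(cm1, c0, cp1) {
        den <- cm1 - 2 * c0 + cp1
        if (den == 0) 0 else 0.5 * (cm1 - cp1) / den
    }
    dyF <- sub(cc[wrap(pk[1] - 1, nr), pk[2]], cc[pk[1], pk[2]],
        cc[wrap(pk[1] + 1, nr), pk[2]])
    dxF <- sub(cc[pk[1], wrap(pk[2] - 1, nc)], cc[pk[1], pk[2]],
        cc[pk[1], wrap(pk[2] + 1, nc)])
    ## unwrap: peak index i corresponds to shift i-1, large values negative
    sy <- pk[1] - 1 + dyF
    sx <- pk[2] - 1 + dxF
    if (sy > nr / 2) sy <- sy - nr
    if (sx > nc / 2) sx <- sx - nc
    c(dx = sx, dy = sy)
}

#' Estimate sample drift from a localization table
#'
#' Splits the table into up to 100 contiguous temporal subsets, renders each
#' subset as a 2D histogram, finds the shift of every subset against the
#' first by Fourier cross-correlation with parabolic subpixel peak
#' interpolation, and interpolates linearly between subset centres to give a
#' per-frame drift trajectory.  The residual subset-shift standard deviation
#' after correction (the sigma_drift diagnostic) is computed by one
#' re-estimation pass on the corrected table.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param nSubsets number of temporal subsets; default
#'   \code{min(100, floor(nFrames/300))}, at least 2.
#' @param renderPixel histogram pixel size for the subset reconstructions,
#'   nm.
#' @param minPerSubset minimum localizations a subset must hold.
#' @param .residual internal; skip the residual re-estimation pass.
#' @return a \linkS4class{DriftTrajectory}.
#' @export
estimateDrift <- function(table, nSubsets = NULL, renderPixel = 20,
        minPerSubset = 100L, .residual = TRUE) {
    rec <- locData(table)
    if (!nrow(rec)) stop("empty localization table")
    fmin <- min(rec$frame)
    fmax <- max(rec$frame)
    nF <- fmax - fmin + 1L
    if (is.null(nSubsets))
        nSubsets <- max(2L, min(100L, nF %/% 300L))
    nSubsets <- min(nSubsets, 100L)
    breaks <- round(seq(fmin, fmax + 1, length.out = nSubsets + 1))
    grp <- findInterval(rec$frame, breaks, rightmost.closed = TRUE)
    grp[grp > nSubsets] <- nSubsets
    cnt <- tabulate(grp, nSubsets)
    if (any(cnt < minPerSubset))
        stop("subset(s) with fewer than ", minPerSubset,
            " localizations; use fewer subsets")
    xlim <- range(rec$x)
    ylim <- range(rec$y)
    ## pad so cyclic correlation wrap-around cannot alias real shifts
    pad <- 20 * renderPixel
    xlim <- xlim + c(-pad, pad)
    ylim <- ylim + c(-pad, pad)
    ref <- .histRender(rec$x[grp == 1], rec$y[grp == 1], renderPixel,
        xlim, ylim)
    centers <- (breaks[-length(breaks)] + breaks[-1] - 1) / 2
    shifts <- matrix(0, nSubsets, 2)
    for (g in 2:nSubsets) {
        img <- .histRender(rec$x[grp == g], rec$y[grp == g], renderPixel,
            xlim, ylim)
        shifts[g, ] <- .xcorrShift(ref, img) * renderPixel
    }
    frames <- seq.int(fmin, fmax)
    dx <- stats::approx(centers, shifts[, 1], xout = frames, rule = 2)$y
    dy <- stats::approx(centers, shifts[, 2], xout = frames, rule = 2)$y
    ## anchor the trajectory at zero displacement for the reference subset
    traj <- new("DriftTrajectory", frames = as.integer(frames),
        dx = dx - dx[1], dy = dy - dy[1],
        subsetShifts = data.frame(subset = seq_len(nSubsets),
            centerFrame = centers, dx = shifts[, 1], dy = shifts[, 2]),
        residualStd = NA_real_)
    if (.residual) {
        corrected <- applyDrift(table, traj)
        t2 <- estimateDrift(corrected, nSubsets = nSubsets,
            renderPixel = renderPixel, minPerSubset = minPerSubset,
            .residual = FALSE)
        res <- c(t2@subsetShifts$dx, t2@subsetShifts$dy)
        traj@residualStd <- stats::sd(res)
    }
    traj
}

#' Remove an estimated drift trajectory from a localization table
#'
#' Subtracts the per-frame drift from every record's position; record count,
#' photon counts and all other fields are untouched.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param traj a \linkS4class{DriftTrajectory} covering the table's frames.
#' @return the corrected \linkS4class{LocalizationTable}.
#' @export
applyDrift <- function(table, traj) {
    rec <- locData(table)
    if (!nrow(rec)) return(table)
    i <- match(rec$frame, traj@frames)
    if (anyNA(i))
        stop("drift trajectory does not cover all frames in the table")
    rec$x <- rec$x - traj@dx[i]
    rec$y <- rec$y - traj@dy[i]
    LocalizationTable(rec, metadata = table@metadata)
}
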