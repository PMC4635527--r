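#' Nuclear mask from a reconstruction
#'
#' Mirrors the classic ImageJ workflow: histogram stretching to the full
#' 8-bit range (with a small saturated fraction at the top, as ImageJ's
#' contrast enhancement applies, so single hot pixels cannot compress the
#' whole histogram), a fixed intensity threshold (chromatin = intensity
#' above 50), hole filling, and retention of the largest connected
#' component as the nucleus.
#'
#' @param recon numeric matrix (a reconstruction; any intensity scale).
#' @param threshold 8-bit threshold after stretching (default 50).
#' @param saturate fraction of pixels allowed to saturate at 255 during
#'   stretching (default 0.0035, the ImageJ convention); 0 gives a pure
#'   min-max stretch.
#' @return logical matrix: the hole-filled nuclear mask.  The stretched
#'   8-bit image is attached as attribute \code{"stretched"}.
#' @export
nuclearMask <- function(recon, threshold = 50, saturate = 0.0035) {
    rng <- range(recon)
    if (rng[1] == rng[2])
        stop("blank image: cannot stretch a constant reconstruction")
    hi <- if (saturate > 0)
        stats::quantile(recon, 1 - saturate, names = FALSE) else rng[2]
    if (hi <= rng[1]) hi <- rng[2]
    stretched <- pmin((recon - rng[1]) / (hi - rng[1]) * 255, 255)
    chromatin <- stretched > threshold
    lab <- EBImage::bwlabel(EBImage::Image(chromatin * 1))
    filled <- EBImage::fillHull(lab)
    fm <- EBImage::imageData(filled)
    if (!any(fm > 0))
        stop("no chromatin pixels above the threshold")
    sizes <- tabulate(fm[fm > 0])
    mask <- matrix(fm == which.max(sizes), nrow(recon), ncol(recon))
    attr(mask, "stretched") <- stretched
    mask
}

#' Chromatin-free nuclear area fraction
#'
#' The nucleus is the hole-filled mask from \code{\link{nuclearMask}}; the
#' chromatin-occupied area is the above-threshold area within it; the free
#' fraction is their normalized difference.  Because the threshold is
#' applied after min-max stretching, the result is invariant to any affine
#' rescaling of the reconstruction's intensities.
#'
#' @param recon numeric matrix; attribute \code{"pixel"} (nm) is used if
#'   present, else supply \code{pixel}.
#' @param pixel reconstruction pixel size, nm.
#' @param threshold 8-bit threshold (default 50).
#' @param saturate stretch saturation fraction, see
#'   \code{\link{nuclearMask}}.
#' @return a \linkS4class{FreeAreaResult}.
#' @export
freeAreaFraction <- function(recon, pixel = attr(recon, "pixel"),
        threshold = 50, saturate = 0.0035) {
    if (is.null(pixel)) stop("supply the reconstruction pixel size (nm)")
    mask <- nuclearMask(recon, threshold, saturate)
    stretched <- attr(mask, "stretched")
    pxArea <- (pixel / 1000)^2          # um^2 per pixel
    nuclear <- sum(mask) * pxArea
    chrom <- sum(stretched > threshold & mask) * pxArea
    new("FreeAreaResult", nuclearArea = nuclear, chromatinArea = chrom,
        freeFraction = (nuclear - chrom) / nuclear, threshold = threshold)
}

#' Localization density over a mask
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param mask logical matrix (e.g. from \code{\link{nuclearMask}}).
#' @param pixel mask pixel size, nm.
#' @param origin (x, y) of the mask's top-left corner, nm.
#' @return localizations per um^2 within the mask.
#' @export
localizationDensity <- function(table, mask, pixel, origin = c(0, 0)) {
    if (!any(mask)) stop("empty mask")
    rec <- locData(table)
    ix <- floor((rec$x - origin[1]) / pixel) + 1L
    iy <- floor((rec$y - origin[2]) / pixel) + 1L
    inside <- ix >= 1L & ix <= ncol(mask) & iy >= 1L & iy <= nrow(mask)
    inMask <- inside
    inMask[inside] <- mask[cbind(iy[inside], ix[inside])]
    areaUm2 <- sum(mask) * (pixel / 1000)^2
    sum(inMask) / areaUm2
}

#' Fisher-Pearson moment coefficient of skewness
#'
#' \code{g1 = m3 / m2^(3/2)} with central sample moments \code{m2, m3}.
#'
#' @param values numeric vector, length >= 3, non-zero variance.
#' @return dimensionless skewness g1.
#' @export
sampleSkewness <- function(values) {
    if (length(values) < 3) stop("need at least 3 values")
    d <- values - mean(values)
    m2 <- mean(d^2)
    if (m2 == 0) stop("zero variance: skewness undefined")
    mean(d^3) / m2^1.5
}

#' Grid-binned localization counts
#'
#' Overlays a square grid of width \code{binSize} on the field, counts
#' localizations per bin, discards bins holding fewer than two (removing
#' DNA-free area, notably outside the nucleus), and summarizes the retained
#' counts: type-7 quartiles, skewness g1, and the proportion of bins with at
#' least \code{highThreshold} localizations.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param binSize grid width, nm; the analysis is designed for 10-500 nm
#'   (a warning is raised outside).
#' @param origin grid anchor (x, y), nm; defaults to the bounding-box corner
#'   of the data.
#' @param highThreshold count defining a "high-occupancy" bin (default 25).
#' @return a \linkS4class{BinningResult}.
#' @export
binHistogram <- function(table, binSize, origin = NULL, highThreshold = 25) {
    if (binSize < 10 || binSize > 500)
        warning("bin size outside the intended 10-500 nm range")
    rec <- locData(table)
    if (!nrow(rec)) stop("empty localization table")
    if (is.null(origin)) origin <- c(min(rec$x), min(rec$y))
    ix <- floor((rec$x - origin[1]) / binSize)
    iy <- floor((rec$y - origin[2]) / binSize)
    key <- paste(ix, iy)
    cnt <- base::table(key)    # 'table' is shadowed by the argument
    keep <- cnt >= 2
    if (!any(keep))
        stop("no bins with >= 2 localizations at bin size ", binSize, " nm")
    counts <- as.integer(cnt[keep])
    kxy <- do.call(rbind, strsplit(names(cnt)[keep], " "))
    bins <- data.frame(ix = as.integer(kxy[, 1]), iy = as.integer(kxy[, 2]),
        n = counts)
    q <- stats::quantile(counts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    ## a single retained count class carries no asymmetry
    g1 <- if (length(counts) >= 3 && stats::var(counts) > 0)
        sampleSkewness(counts) else 0
    new("BinningResult", binSize = binSize, counts = counts, bins = bins,
        median = q[2], q1 = q[1], q3 = q[3],
        skewness = g1, propHigh = mean(counts >= highThreshold),
        highThreshold = highThreshold)
}

## mean distance to the k nearest neighbours for every point, brute force in
## chunks; self excluded
.knnMeanDist <- function(xy, k, chunk = 512L) {
    n <- nrow(xy)
    stopifnot(n > k)
    out <- numeric(n)
    x <- xy[, 1]
    y <- xy[, 2]
    for (start in seq(1L, n, by = chunk)) {
        ii <- start:min(n, start + chunk - 1L)
        d2 <- outer(x[ii], x, "-")^2 + outer(y[ii], y, "-")^2
        d2[cbind(seq_along(ii), ii)] <- Inf
        out[ii] <- apply(d2, 1, function(row)
            mean(sqrt(sort(row, partial = k)[seq_len(k)])))
    }
    out
}

#' Mean distance to k nearest neighbours within ROIs
#'
#' For every localization inside each rectangular region of interest, the
#' mean Euclidean distance to its k nearest neighbours within the same ROI
#' (self excluded) is computed; per-point values are pooled over ROIs.  When
#' every ROI holds more than 100 points, the fraction of localizations whose
#' mean distance to their 100 nearest neighbours is at least 80 nm is
#' reported as \code{propFar} (a compaction marker).  No edge correction is
#' applied at ROI boundaries.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param rois data.frame with columns \code{xmin, xmax, ymin, ymax} (nm).
#' @param k number of neighbours (supported at least up to 500).
#' @param farK,farCutoff parameters of the \code{propFar} marker
#'   (defaults 100 neighbours, 80 nm).
#' @return an \linkS4class{NNResult}.
#' @export
nnMeanDistances <- function(table, rois, k, farK = 100L, farCutoff = 80) {
    rec <- locData(table)
    rois <- as.data.frame(rois)
    stopifnot(all(c("xmin", "xmax", "ymin", "ymax") %in% names(rois)))
    pooled <- list()
    farVals <- list()
    farOk <- TRUE
    for (i in seq_len(nrow(rois))) {
        inRoi <- rec$x >= rois$xmin[i] & rec$x <= rois$xmax[i] &
            rec$y >= rois$ymin[i] & rec$y <= rois$ymax[i]
        xy <- cbind(rec$x[inRoi], rec$y[inRoi])
        if (nrow(xy) <= k)
            stop("ROI ", i, " holds ", nrow(xy),
                " localizations; need more than k = ", k)
        pooled[[i]] <- .knnMeanDist(xy, k)
        if (nrow(xy) > farK) {
            farVals[[i]] <- if (k == farK) pooled[[i]] else
                .knnMeanDist(xy, farK)
        } else farOk <- FALSE
    }
    md <- unlist(pooled, use.names = FALSE)
    q <- stats::quantile(md, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    propFar <- if (farOk)
        mean(unlist(farVals, use.names = FALSE) >= farCutoff)
    else NA_real_
    new("NNResult", k = as.integer(k), meanDistances = md,
        median = q[2], q1 = q[1], q3 = q[3], propFar = propFar,
        rois = rois)
}
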