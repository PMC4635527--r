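#' Fourier ring correlation curve of two reconstructions
#'
#' Correlates the Fourier transforms of two images over rings of spatial
#' frequency (ring width one frequency pixel):
#' \deqn{FRC(q) = \frac{\Re \sum_{|k| \in q} F_1(k) \overline{F_2(k)}}
#'   {\sqrt{\sum |F_1|^2 \sum |F_2|^2}}}
#'
#' @param img1,img2 equally sized numeric matrices (reconstructions of the
#'   two half data sets on a common grid).
#' @param pixel image pixel size, nm.
#' @return data.frame with columns \code{freq} (1/nm), \code{frc} and
#'   \code{n} (pixels per ring).
#' @export
frcCurve <- function(img1, img2, pixel) {
    stopifnot(all(dim(img1) == dim(img2)))
    ## embed in a common square grid so rings are isotropic
    n <- max(dim(img1))
    if (n %% 2L) n <- n + 1L
    sq <- function(m) {
        out <- matrix(0, n, n)
        out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
        out
    }
    F1 <- stats::fft(sq(img1))
    F2 <- stats::fft(sq(img2))
    k <- c(0:(n / 2), seq(-n / 2 + 1, -1))     # frequency index per axis
    kr <- sqrt(outer(k^2, k^2, "+"))
    ring <- round(kr)
    maxR <- n %/% 2
    keep <- ring <= maxR
    num <- Re(F1 * Conj(F2))
    p1 <- Mod(F1)^2
    p2 <- Mod(F2)^2
    rIdx <- ring[keep] + 1L
    sNum <- tapply(num[keep], rIdx, sum)
    s1 <- tapply(p1[keep], rIdx, sum)
    s2 <- tapply(p2[keep], rIdx, sum)
    cnt <- tapply(rep(1, sum(keep)), rIdx, sum)
    frc <- as.numeric(sNum / sqrt(s1 * s2))
    frc[!is.finite(frc)] <- 0
    data.frame(freq = (seq_len(maxR + 1) - 1) / (n * pixel),
        frc = frc, n = as.numeric(cnt))
}

#' Image resolution by Fourier ring correlation
#'
#' Randomly splits the localization table into two halves, renders each as a
#' 2D histogram on a common grid, computes the FRC curve (smoothed with a
#' 3-ring moving average), and reports the inverse of the first spatial
#' frequency at which the curve drops below the fixed threshold (1/7 by
#' convention).
#'
#' @param table a \linkS4class{LocalizationTable}; fewer than 2000 records
#'   triggers a warning (the curve becomes noisy).
#' @param pixel rendering pixel size, nm (default 10).
#' @param threshold fixed FRC threshold (default 1/7).
#' @return resolution in nm, with the FRC curve attached as attribute
#'   \code{"curve"}; \code{NA} (with a message) when the curve never drops
#'   below the threshold — not resolvable at this pixel scale.
#' @export
frcResolution <- function(table, pixel = 10, threshold = 1 / 7) {
    rec <- locData(table)
    n <- nrow(rec)
    if (n < 2)
        stop("need at least 2 localizations")
    if (n < 2000)
        warning("fewer than 2000 localizations; FRC estimate will be noisy")
    half <- sample.int(n, n %/% 2)
    xlim <- range(rec$x)
    ylim <- range(rec$y)
    i1 <- .histRender(rec$x[half], rec$y[half], pixel, xlim, ylim)
    i2 <- .histRender(rec$x[-half], rec$y[-half], pixel, xlim, ylim)
    curve <- frcCurve(i1, i2, pixel)
    sm <- stats::filter(curve$frc, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- curve$frc[is.na(sm)]
    below <- which(sm < threshold & curve$freq > 0)
    if (!length(below)) {
        message("FRC never crosses the threshold: not resolvable at this ",
            "pixel scale")
        res <- NA_real_
    } else {
        res <- 1 / curve$freq[below[1]]
    }
    attr(res, "curve") <- curve
    res
}
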