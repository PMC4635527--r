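#' Localize single molecules in a frame stack
#'
#' The full per-frame pipeline: an initial background is averaged over the
#' first eight frames; every frame is background-subtracted, candidate
#' signals are detected on the 3x3-mean-smoothed difference image at the
#' \code{(TF - 1) * STD} threshold, refined to subpixel centre-of-intensity
#' positions with overlap clipping, and assigned a localization precision;
#' the background is then updated from the clipped difference image.  Bursts
#' spanning consecutive frames are joined once at the end.  The run is fully
#' deterministic given its inputs.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param cfg a \code{\link{DetectionConfig}}.
#' @param psfSigma assumed PSF standard deviation, nm.
#' @param join logical; join consecutive-frame records (default TRUE).
#' @param verbose log per-stage record counts.
#' @return a \linkS4class{LocalizationTable}.  Its metadata records the
#'   detection parameters plus counters for candidates found and rejected
#'   (by border, overlap clipping, non-positive signal) and records merged.
#' @export
localizeStack <- function(stack, cfg = DetectionConfig(), psfSigma = 130,
        join = TRUE, verbose = FALSE) {
    p <- pixelSize(stack)
    gain <- cameraGain(stack)
    bg <- initialBackground(stack)
    nF <- nFrames(stack)
    rows <- vector("list", nF)
    counters <- c(candidates = 0L, border = 0L, clip_loss = 0L,
        nonpositive = 0L, merged = 0L)
    for (f in seq_len(nF)) {
        diff <- differenceImage(getFrame(stack, f), bg)
        sm <- .meanFilter3(diff)
        cand <- detectCandidates(diff, bg, cfg)
        if (nrow(cand)) {
            counters["candidates"] <- counters["candidates"] + nrow(cand)
            accepted <- vector("list", nrow(cand))
            for (i in seq_len(nrow(cand))) {
                res <- refineCandidate(sm, cand[i, ], cfg, gain,
                    psfSigma, p, bg)
                if (is.null(res$loc)) {
                    counters[res$reason] <- counters[res$reason] + 1L
                } else {
                    accepted[[i]] <- cbind(frame = f, res$loc)
                }
            }
            accepted <- accepted[!vapply(accepted, is.null, logical(1))]
            if (length(accepted))
                rows[[f]] <- do.call(rbind, accepted)
        }
        bg <- updateBackground(bg, diff)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    rec <- if (length(rows)) do.call(rbind, rows) else
        data.frame(frame = integer(), x = numeric(), y = numeric(),
            photons = numeric(), sigma = numeric(), uncertainty = numeric(),
            background = numeric())
    tab <- LocalizationTable(rec, metadata = list(
        pixelSize = p, gain = gain, psfSigma = psfSigma,
        thresholdFactor = cfg$thresholdFactor,
        joinRadiusFactor = cfg$joinRadiusFactor,
        fieldPixels = c(ncol(stack@frames), nrow(stack@frames))))
    if (join) {
        nBefore <- nLocalizations(tab)
        tab <- joinConsecutive(tab, cfg)
        counters["merged"] <- nBefore - nLocalizations(tab)
    }
    tab@metadata$counters <- counters
    if (verbose)
        message(sprintf(
            "localizeStack: %d candidates; rejected %d border, %d clip, %d nonpositive; %d merged; %d records",
            counters["candidates"], counters["border"],
            counters["clip_loss"], counters["nonpositive"],
            counters["merged"], nLocalizations(tab)))
    tab
}

#' Join single-molecule signals occurring in consecutive frames
#'
#' A fluorophore staying on for several frames produces one localization per
#' frame; chains of records in consecutive frames within a search radius of
#' \code{joinRadiusFactor} times the table's mean localization precision are
#' merged into single records with photon-weighted mean position, summed
#' photon count, and the precision recomputed from the summed photons.  No
#' other filtering is applied.
#'
#' @param table a \linkS4class{LocalizationTable} sorted by frame.
#' @param cfg a \code{\link{DetectionConfig}} (only \code{joinRadiusFactor}
#'   is used).
#' @return the joined \linkS4class{LocalizationTable}.
#' @export
joinConsecutive <- function(table, cfg = DetectionConfig()) {
    rec <- locData(table)
    n <- nrow(rec)
    if (n == 0)
        return(table)
    radius <- cfg$joinRadiusFactor * mean(rec$uncertainty)
    chain <- seq_len(n)                 # chain id per record
    ord <- order(rec$frame)
    rec <- rec[ord, , drop = FALSE]
    frames <- sort(unique(rec$frame))
    prevIdx <- integer()                # record indices active in frame f-1
    prevFrame <- -Inf
    for (f in frames) {
        curIdx <- which(rec$frame == f)
        if (length(prevIdx) && f - prevFrame == 1) {
            ## greedy nearest-pair linking within the search radius
            d <- sqrt(outer(rec$x[curIdx], rec$x[prevIdx], "-")^2 +
                      outer(rec$y[curIdx], rec$y[prevIdx], "-")^2)
            repeat {
                m <- which.min(d)
                if (!length(m) || d[m] > radius || !is.finite(d[m])) break
                i <- (m - 1) %% length(curIdx) + 1
                j <- (m - 1) %/% length(curIdx) + 1
                chain[curIdx[i]] <- chain[prevIdx[j]]
                d[i, ] <- Inf
                d[, j] <- Inf
            }
        }
        prevIdx <- curIdx
        prevFrame <- f
    }
    p <- table@metadata$pixelSize
    s <- table@metadata$psfSigma
    merged <- lapply(split(seq_len(n), chain), function(ii) {
        if (length(ii) == 1L)
            return(rec[ii, , drop = FALSE])
        w <- rec$photons[ii]
        N <- sum(w)
        b <- mean(rec$background[ii])
        sig <- rec$sigma[ii][1]
        unc <- if (!is.null(p) && !is.null(s))
            estimatePrecision(N, s, p, b)
        else sqrt(1 / sum(1 / rec$uncertainty[ii]^2))
        data.frame(frame = min(rec$frame[ii]),
            x = sum(w * rec$x[ii]) / N, y = sum(w * rec$y[ii]) / N,
            photons = N, sigma = sig, uncertainty = unc, background = b)
    })
    out <- do.call(rbind, merged)
    LocalizationTable(out, metadata = table@metadata)
}
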