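#' @rdname FrameStack-class
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3])

#' @rdname FrameStack-class
#' @export
setMethod("pixelSize", "FrameStack", function(x) x@pixelSize)

#' @rdname LocalizationTable-class
#' @export
setMethod("pixelSize", "LocalizationTable", function(x) {
    p <- x@metadata$pixelSize
    if (is.null(p)) NA_real_ else p
})

#' @rdname FrameStack-class
#' @export
setMethod("cameraGain", "FrameStack", function(x) x@gain)

#' @rdname FrameStack-class
#' @export
setMethod("getFrame", "FrameStack", function(x, i) {
    stopifnot(i >= 1, i <= nFrames(x))
    x@frames[, , i]
})

#' @rdname FrameStack-class
#' @export
setMethod("groundTruth", "FrameStack", function(x) x@groundTruth)

#' @rdname LocalizationTable-class
#' @export
setMethod("locData", "LocalizationTable", function(x) x@records)

#' @rdname LocalizationTable-class
#' @export
setMethod("nLocalizations", "LocalizationTable", function(x) nrow(x@records))

#' @rdname LocalizationTable-class
#' @export
setMethod("locMetadata", "LocalizationTable", function(x) x@metadata)

#' Construct a LocalizationTable from a data.frame
#'
#' @param records data.frame holding the canonical columns \code{frame, x, y,
#'   photons, sigma, uncertainty, background}; extra columns are kept.
#' @param metadata named list of acquisition/analysis parameters.
#' @return a \linkS4class{LocalizationTable}.
#' @export
LocalizationTable <- function(records, metadata = list()) {
    records <- as.data.frame(records)
    if (nrow(records))
        records <- records[order(records$frame), , drop = FALSE]
    rownames(records) <- NULL
    new("LocalizationTable", records = records, metadata = metadata)
}

setMethod("show", "FrameStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf(
        "FrameStack: %d frame(s) of %d x %d px (%.0f nm/px, gain %.2g)\n",
        d[3], d[2], d[1], object@pixelSize, object@gain))
    if (nrow(object@groundTruth))
        cat(sprintf("  with ground truth: %d burst(s), %d emitter(s)\n",
            nrow(object@groundTruth),
            length(unique(object@groundTruth$emitter_id))))
})

setMethod("show", "LocalizationTable", function(object) {
    n <- nrow(object@records)
    cat(sprintf("LocalizationTable: %d record(s)\n", n))
    if (n) {
        cat(sprintf("  frames %d..%d; median photons %.0f; median sigma_loc %.1f nm\n",
            min(object@records$frame), max(object@records$frame),
            stats::median(object@records$photons),
            stats::median(object@records$uncertainty)))
    }
})

setMethod("show", "ChromatinPhantom", function(object) {
    cat(sprintf(
        "ChromatinPhantom: %.0f x %.0f nm field, %d atoll(s), %d void(s)\n",
        object@fieldSize[1], object@fieldSize[2],
        nrow(object@atolls), nrow(object@voids)))
    cat(sprintf("  diffuse weight %.2f, density contrast %.2f\n",
        object@diffuseWeight, object@densityContrast))
})

setMethod("show", "EmitterSet", function(object) {
    cat(sprintf("EmitterSet: %d emitter(s), %d blink event(s)\n",
        nrow(object@positions), nrow(object@blinks)))
})

setMethod("show", "DriftTrajectory", function(object) {
    rng <- range(c(object@dx, object@dy))
    cat(sprintf(
        "DriftTrajectory: frames %d..%d, %d subset(s), range [%.1f, %.1f] nm\n",
        min(object@frames), max(object@frames), nrow(object@subsetShifts),
        rng[1], rng[2]))
    if (is.finite(object@residualStd))
        cat(sprintf("  residual subset-shift SD: %.2f nm\n",
            object@residualStd))
})

setMethod("show", "ResolutionEstimate", function(object) {
    cat("ResolutionEstimate:\n")
    cat(sprintf("  sigma_loc      %.2f nm\n", object@sigmaLoc))
    cat(sprintf("  sigma_sampling %.2f nm\n", object@sigmaSampling))
    cat(sprintf("  sigma_drift    %.2f nm\n", object@sigmaDrift))
    cat(sprintf("  sigma_total    %.2f nm (structural FWHM %.1f nm, ~%d nm)\n",
        object@sigmaTotal, object@structuralFWHM,
        as.integer(object@structuralFWHM10)))
})

setMethod("show", "BinningResult", function(object) {
    cat(sprintf(
        "BinningResult: bin %.0f nm, %d retained bin(s), median %.0f [%.0f, %.0f]\n",
        object@binSize, length(object@counts), object@median, object@q1,
        object@q3))
    cat(sprintf("  skewness g1 = %.3f; prop(>= %d) = %.3f\n",
        object@skewness, as.integer(object@highThreshold), object@propHigh))
})

setMethod("show", "NNResult", function(object) {
    cat(sprintf(
        "NNResult: k = %d, %d localization(s), median %.1f [%.1f, %.1f] nm\n",
        object@k, length(object@meanDistances), object@median, object@q1,
        object@q3))
    if (is.finite(object@propFar))
        cat(sprintf("  prop(100-NN mean >= 80 nm) = %.3f\n", object@propFar))
})

setMethod("show", "FreeAreaResult", function(object) {
    cat(sprintf(
        "FreeAreaResult: nucleus %.2f um^2, chromatin %.2f um^2, free %.1f%%\n",
        object@nuclearArea, object@chromatinArea,
        100 * object@freeFraction))
})
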