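## ThunderSTORM-compatible column names <-> internal names
.TS_COLUMNS <- c(
    frame = "frame",
    x = "x [nm]",
    y = "y [nm]",
    photons = "intensity [photon]",
    sigma = "sigma [nm]",
    uncertainty = "uncertainty_xy [nm]",
    background = "background [photon]")

#' Read a multi-page TIFF acquisition
#'
#' @param path TIFF file, one grayscale page per frame.
#' @param pixelSize effective pixel size, nm.
#' @param gain photons per count.
#' @return a \linkS4class{FrameStack}.
#' @export
readStack <- function(path, pixelSize = 102, gain = 2) {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
        stop("multi-channel or RGB TIFF not supported: ", path)
    d <- dim(pages[[1]])
    frames <- array(0, c(d[1], d[2], length(pages)))
    for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
    new("FrameStack", frames = frames, pixelSize = pixelSize, gain = gain)
}

#' Write a FrameStack as 16-bit multi-page TIFF
#'
#' Counts are rounded to integers and clamped to [0, 65535]; pixel values
#' round-trip exactly through \code{\link{readStack}}.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeStack <- function(stack, path) {
    pages <- lapply(seq_len(nFrames(stack)), function(i)
        pmin(pmax(round(getFrame(stack, i)), 0), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
    invisible(path)
}

#' Write a localization table as ThunderSTORM-compatible CSV
#'
#' Columns: \code{frame,x [nm],y [nm],intensity [photon],sigma [nm],
#' uncertainty_xy [nm],background [photon]}; any extra columns follow under
#' their own names.  Floats are written with 17 significant digits so the
#' round trip is lossless.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param path output CSV.
#' @return invisibly, the path.
#' @export
writeLocalizations <- function(table, path) {
    rec <- locData(table)
    known <- intersect(names(.TS_COLUMNS), names(rec))
    extra <- setdiff(names(rec), names(.TS_COLUMNS))
    out <- rec[, c(known, extra), drop = FALSE]
    names(out) <- c(.TS_COLUMNS[known], extra)
    fmt <- lapply(out, function(col) {
        if (is.double(col)) formatC(col, digits = 17, format = "g")
        else as.character(col)
    })
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(names(out), collapse = ","), con)
    if (nrow(out))
        writeLines(do.call(paste, c(fmt, sep = ",")), con)
    invisible(path)
}

#' Read a ThunderSTORM-compatible localization CSV
#'
#' Parsing is header-driven, so column order is free.  Missing mandatory
#' columns raise an error naming them; unknown columns are kept.
#'
#' @param path CSV file.
#' @param metadata optional metadata list to attach.
#' @return a \linkS4class{LocalizationTable}.
#' @export
readLocalizations <- function(path, metadata = list()) {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- utils::read.csv(path, check.names = FALSE)
    missing <- setdiff(unname(.TS_COLUMNS), names(raw))
    if (length(missing))
        stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
    inv <- stats::setNames(names(.TS_COLUMNS), .TS_COLUMNS)
    known <- names(raw) %in% names(inv)
    names(raw)[known] <- inv[names(raw)[known]]
    raw$frame <- as.integer(raw$frame)
    LocalizationTable(raw, metadata = metadata)
}

#' Write simulator ground truth as CSV
#'
#' Header: \code{emitter_id,frame,x_nm,y_nm,photons}.
#'
#' @param stack a simulated \linkS4class{FrameStack}.
#' @param path output CSV.
#' @return invisibly, the path.
#' @export
writeGroundTruth <- function(stack, path) {
    utils::write.csv(groundTruth(stack), path, row.names = FALSE,
        quote = FALSE)
    invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML key/value file mirroring the configuration blocks of
#' \code{\link{runPipeline}}; units are nm, photons and counts as annotated
#' in the template produced by \code{\link{defaultPipelineConfig}}.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    yaml::read_yaml(path)
}
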