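#' @rdname FrameStack-class
#' @param object,x an object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname FrameStack-class
#' @export
setGeneric("cameraGain", function(x) standardGeneric("cameraGain"))

#' @rdname FrameStack-class
#' @param i frame index.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname FrameStack-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname LocalizationTable-class
#' @export
setGeneric("locData", function(x) standardGeneric("locData"))

#' @rdname LocalizationTable-class
#' @export
setGeneric("nLocalizations", function(x) standardGeneric("nLocalizations"))

#' @rdname LocalizationTable-class
#' @export
setGeneric("locMetadata", function(x) standardGeneric("locMetadata"))
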