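#' @rdname TirfMovie-class
#' @param object,x a `TirfMovie`
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))

#' @rdname TirfMovie-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname TirfMovie-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname TirfMovie-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname EventList-class
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname EventList-class
#' @export
setGeneric("eventSource", function(x) standardGeneric("eventSource"))

#' @rdname LabelMap-class
#' @export
setGeneric("labels3d", function(x) standardGeneric("labels3d"))

#' @rdname CellMask-class
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))
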