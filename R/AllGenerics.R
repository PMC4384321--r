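#' @rdname smdAccessors
#' @export
setGeneric("smdId", function(x) standardGeneric("smdId"))

#' @rdname smdAccessors
#' @export
setGeneric("smdAttr", function(x) standardGeneric("smdAttr"))

#' @rdname smdAccessors
#' @export
setGeneric("smdDesc", function(x) standardGeneric("smdDesc"))

#' @rdname smdAccessors
#' @export
setGeneric("channelTypes", function(x) standardGeneric("channelTypes"))

#' @rdname smdAccessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname smdAccessors
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname smdAccessors
#' @export
setGeneric("nTraces", function(x) standardGeneric("nTraces"))

#' @rdname smdAccessors
#' @export
setGeneric("traceIndex", function(x) standardGeneric("traceIndex"))

#' @rdname smdAccessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname smdAccessors
#' @export
setGeneric("traceAttr", function(x) standardGeneric("traceAttr"))

#' @rdname canonicalBytes
#' @export
setGeneric("canonicalBytes", function(x) standardGeneric("canonicalBytes"))

#' @rdname contentIds
#' @export
setGeneric("traceId", function(x) standardGeneric("traceId"))

#' @rdname contentIds
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))
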