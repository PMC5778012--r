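#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))

#' @export
setGeneric("telbamPath", function(x) standardGeneric("telbamPath"))

#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))

#' @export
setGeneric("insertMean", function(x) standardGeneric("insertMean"))

#' @export
setGeneric("insertSd", function(x) standardGeneric("insertSd"))

#' @export
setGeneric("errorMask", function(x) standardGeneric("errorMask"))

#' @export
setGeneric("maskThreshold", function(x) standardGeneric("maskThreshold"))

#' @export
setGeneric("tlBp", function(x) standardGeneric("tlBp"))

#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))
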