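#' Accessors for telotape objects
#'
#' @param x a telotape S4 object.
#' @return \code{pairCount}: number of read pairs in a TELBAM.
#'   \code{telbamPath}: file path of a TELBAM.  \code{readLength}: read
#'   length in bases.  \code{insertMean}/\code{insertSd}: insert length
#'   distribution parameters.  \code{errorMask}: the binary error mask E.
#'   \code{maskThreshold}: the threshold k used to build the mask.
#'   \code{tlBp}: estimated telomere length in base pairs.
#'   \code{pairCounts}: named vector of the F1/F2/F3/F4/F2a tallies.
#' @name accessors
#' @aliases pairCount telbamPath readLength insertMean insertSd errorMask
#'   maskThreshold tlBp pairCounts
NULL

#' @rdname accessors
#' @export
setMethod("pairCount", "TelbamHandle", function(x) x@pairCount)

#' @rdname accessors
#' @export
setMethod("telbamPath", "TelbamHandle", function(x) x@path)

#' @rdname accessors
#' @export
setMethod("readLength", "TelbamHandle", function(x) x@readLength)

#' @rdname accessors
#' @export
setMethod("readLength", "InsertSizeModel", function(x) x@readLength)

#' @rdname accessors
#' @export
setMethod("insertMean", "InsertSizeModel", function(x) x@meanInsert)

#' @rdname accessors
#' @export
setMethod("insertSd", "InsertSizeModel", function(x) x@sdInsert)

#' @rdname accessors
#' @export
setMethod("errorMask", "ErrorProfile", function(x) x@E)

#' @rdname accessors
#' @export
setMethod("maskThreshold", "ErrorProfile", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("tlBp", "LengthEstimate", function(x) x@tlBp)

#' @rdname accessors
#' @export
setMethod("pairCounts", "ReadPairCounts", function(x)
  c(F1 = x@f1, F2 = x@f2, F3 = x@f3, F4 = x@f4, F2a = x@f2a))

setMethod("show", "TelbamHandle", function(object) {
  cat("TelbamHandle:", object@path, "\n",
      " pairs:", object@pairCount,
      " read length:", object@readLength,
      " phred offset:", object@phredOffset, "\n")
})

setMethod("show", "InsertSizeModel", function(object) {
  cat(sprintf(
    "InsertSizeModel: mean %.1f bp, sd %.1f bp (read length %d, n = %d)\n",
    object@meanInsert, object@sdInsert, object@readLength,
    object@nObservations))
})

setMethod("show", "ErrorProfile", function(object) {
  cat(sprintf(
    "ErrorProfile: %d x %d mask, %d cells set, k = %g, Phred range [%d, %d]\n",
    nrow(object@E), ncol(object@E), sum(object@E), object@k,
    object@pMin, object@pMax))
})

setMethod("show", "ReadPairCounts", function(object) {
  cat("ReadPairCounts for", object@sampleId, "\n")
  print(pairCounts(object))
})

setMethod("show", "LengthEstimate", function(object) {
  cat(sprintf("LengthEstimate: %.0f bp (F1 = %g, F2a = %g, insert %.1f +/- %.1f)\n",
              object@tlBp, object@f1, object@f2aUsed,
              object@insertModel@meanInsert, object@insertModel@sdInsert))
  if (!is.na(object@tlBpCorrected))
    cat(sprintf("  batch-corrected: %.0f bp (platform %s)\n",
                object@tlBpCorrected, object@platform))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec '%s': %d telomere(s) of %d bp, %d ITR locus group(s), %.0fx coverage\n",
    object@sampleId, object@nTelomeres, object@tlBp,
    length(object@itrList), object@coverageX))
})
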