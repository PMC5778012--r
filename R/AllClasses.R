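#' TelbamHandle: a BAM subset of candidate telomeric read pairs
#'
#' Points at a TELBAM on disk: a coordinate-sorted, indexed BAM holding
#' exactly those read pairs where at least one mate carries two or more
#' occurrences of the telomeric hexamer (on either strand).  Created by
#' [extractTelbam()].
#'
#' @slot path character(1), path to the TELBAM file.
#' @slot pairCount integer(1), number of retained read pairs.
#' @slot readLength integer(1), modal read length L (0 for an empty TELBAM).
#' @slot phredOffset integer(1), quality encoding offset (Sanger, 33).
#' @export
setClass("TelbamHandle",
  representation(path = "character", pairCount = "integer",
                 readLength = "integer", phredOffset = "integer"),
  prototype(phredOffset = 33L))

setValidity("TelbamHandle", function(object) {
  msg <- NULL
  if (length(object@path) != 1L || !nzchar(object@path))
    msg <- c(msg, "'path' must be a single non-empty string")
  if (length(object@pairCount) != 1L || is.na(object@pairCount) ||
      object@pairCount < 0L)
    msg <- c(msg, "'pairCount' must be a single non-negative integer")
  if (object@readLength < 0L)
    msg <- c(msg, "'readLength' must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' InsertSizeModel: fragment-length distribution of a library
#'
#' Mean and standard deviation of the sequencing insert (outer fragment
#' length), estimated from template-length fields by
#' [estimateInsertSize()] or supplied by the user.
#'
#' @slot meanInsert numeric(1), mean insert length in bases.
#' @slot sdInsert numeric(1), standard deviation of the insert length.
#' @slot readLength integer(1), read length L in bases.
#' @slot nObservations integer(1), number of template-length observations
#'   used (0 when the model was supplied rather than estimated).
#' @export
setClass("InsertSizeModel",
  representation(meanInsert = "numeric", sdInsert = "numeric",
                 readLength = "integer", nObservations = "integer"))

setValidity("InsertSizeModel", function(object) {
  msg <- NULL
  if (object@meanInsert < object@readLength)
    msg <- c(msg, "'meanInsert' must be at least the read length")
  if (object@sdInsert < 0)
    msg <- c(msg, "'sdInsert' must be non-negative")
  if (object@nObservations < 0L)
    msg <- c(msg, "'nObservations' must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' ErrorProfile: binary mask of Phred/mismatch cells treated as error
#'
#' Holds the joint count matrices of mean-Phred-at-mismatch (rows, offset
#' by the minimum observed Phred) against mismatch count (columns) for
#' observed mismatch loci (X) and for random loci (Y), their difference
#' D = X - Y, and the final binary mask E.  A read whose (lambda, z) cell
#' is set in E is treated as a complete telomere read suffering from
#' sequencing error.  Built by [buildErrorMask()].
#'
#' @slot E integer matrix, the binary mask (values 0/1).
#' @slot X,Y,D integer matrices of the same shape as E.
#' @slot k numeric(1), the threshold used for the initial mask
#'   (maximum of D over the high-Phred/high-mismatch quadrant).
#' @slot pMin,pMax integer(1), global minimum/maximum observed Phred.
#' @slot seed integer(1), seed used when sampling the random loci for Y.
#' @slot dropped integer(1), reads excluded because every locus
#'   mismatched (z = L is not representable in the column range).
#' @export
setClass("ErrorProfile",
  representation(E = "matrix", X = "matrix", Y = "matrix", D = "matrix",
                 k = "numeric", pMin = "integer", pMax = "integer",
                 seed = "integer", dropped = "integer"))

setValidity("ErrorProfile", function(object) {
  msg <- NULL
  dm <- dim(object@E)
  if (!identical(dm, dim(object@X)) || !identical(dm, dim(object@Y)) ||
      !identical(dm, dim(object@D)))
    msg <- c(msg, "E, X, Y and D must share one shape")
  if (!all(object@E %in% c(0L, 1L)))
    msg <- c(msg, "mask entries must be 0 or 1")
  if (is.null(msg)) TRUE else msg
})

#' ReadPairCounts: per-sample tallies of the four read-pair categories
#'
#' F1: both mates complete telomere; F2: exactly one complete, reading
#' CCCTAA (telomere boundary or the matching side of an interstitial
#' repeat); F3: neither complete; F4: exactly one complete, reading TTAGGG
#' (the far side of an interstitial repeat).  F2a = F2 - F4 estimates the
#' count of true boundary pairs (clamped at zero).  Built by
#' [countPairs()].
#'
#' @slot sampleId character(1).
#' @slot f1,f2,f3,f4 integer(1) category tallies.
#' @slot f2a numeric(1), F2 - F4 clamped at zero.
#' @export
setClass("ReadPairCounts",
  representation(sampleId = "character", f1 = "integer", f2 = "integer",
                 f3 = "integer", f4 = "integer", f2a = "numeric"))

setValidity("ReadPairCounts", function(object) {
  msg <- NULL
  if (any(c(object@f1, object@f2, object@f3, object@f4) < 0L))
    msg <- c(msg, "category counts must be non-negative")
  if (object@f2a < 0)
    msg <- c(msg, "'f2a' must be non-negative (clamped)")
  if (is.null(msg)) TRUE else msg
})

#' LengthEstimate: a telomere length in base pairs with provenance
#'
#' Result of [estimateLength()]: the mean telomere length whose simulated
#' internal:boundary ratio matches the observed F1/F2a ratio, together
#' with the inputs used to produce it.
#'
#' @slot tlBp numeric(1), estimated mean telomere length in base pairs.
#' @slot f1 numeric(1), internal pair count used.
#' @slot f2aUsed numeric(1), boundary pair count used (cohort-corrected
#'   when the cohort correction ran).
#' @slot insertModel the [InsertSizeModel-class] used.
#' @slot nSim integer(1), fragments simulated per ratio evaluation.
#' @slot seed integer(1), seed of the simulation stream.
#' @slot platform character(1), sequencing platform label ("" if unset).
#' @slot tlBpCorrected numeric(1), batch-corrected length (NA until
#'   [batchCorrect()] runs).
#' @export
setClass("LengthEstimate",
  representation(tlBp = "numeric", f1 = "numeric", f2aUsed = "numeric",
                 insertModel = "InsertSizeModel", nSim = "integer",
                 seed = "integer", platform = "character",
                 tlBpCorrected = "numeric"),
  prototype(platform = "", tlBpCorrected = NA_real_))

setValidity("LengthEstimate", function(object) {
  msg <- NULL
  if (object@tlBp < 0) msg <- c(msg, "'tlBp' must be non-negative")
  if (object@f2aUsed <= 0) msg <- c(msg, "'f2aUsed' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticSpec: parameters of a synthetic paired-end WGS sample
#'
#' Describes a sample for [generateSample()]: telomere tracts of known
#' length behind random subtelomere, optional interstitial telomeric
#' repeats (ITRs) embedded in random sequence, random decoy sequence, and
#' a two-level Phred model with substitution/indel errors placed
#' preferentially on low-quality loci.
#'
#' @slot sampleId character(1), unique sample label.
#' @slot tlBp integer(1), true telomere tract length in base pairs.
#' @slot nTelomeres integer(1), number of telomere-bearing constructs.
#' @slot subtelomereBp integer(1), random subtelomere per construct.
#' @slot itrList list of two-element numeric vectors
#'   \code{c(length_bp, copies)} describing ITR loci.
#' @slot coverageX numeric(1), mean read coverage over each construct.
#' @slot readLength integer(1), read length L.
#' @slot insertMean,insertSd numeric(1), insert length distribution.
#' @slot errorRate numeric(1) in [0, 1), per-base error probability.
#' @slot lowPhredBias numeric(1) in [0, 1], fraction of errors forced
#'   onto low-Phred loci.
#' @slot lowPhredFrac numeric(1) in (0, 1), fraction of loci assigned the
#'   low Phred score.
#' @slot indelFrac numeric(1) in [0, 1], fraction of errors that are
#'   indels rather than substitutions.
#' @slot phredHigh,phredLow integer(1), the two Phred levels.
#' @slot decoyBp integer(1), random decoy construct length (0 disables).
#' @slot seed integer(1), RNG seed; the sample is reproducible from it.
#' @export
setClass("SyntheticSpec",
  representation(sampleId = "character", tlBp = "integer",
                 nTelomeres = "integer", subtelomereBp = "integer",
                 itrList = "list", coverageX = "numeric",
                 readLength = "integer", insertMean = "numeric",
                 insertSd = "numeric", errorRate = "numeric",
                 lowPhredBias = "numeric", lowPhredFrac = "numeric",
                 indelFrac = "numeric", phredHigh = "integer",
                 phredLow = "integer", decoyBp = "integer",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (object@tlBp <= 0L || object@subtelomereBp <= 0L ||
      object@readLength <= 0L)
    msg <- c(msg, "lengths must be positive")
  if (object@nTelomeres < 0L)
    msg <- c(msg, "'nTelomeres' must be non-negative")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "'errorRate' must lie in [0, 1)")
  if (object@lowPhredBias < 0 || object@lowPhredBias > 1)
    msg <- c(msg, "'lowPhredBias' must lie in [0, 1]")
  if (object@lowPhredFrac <= 0 || object@lowPhredFrac >= 1)
    msg <- c(msg, "'lowPhredFrac' must lie in (0, 1)")
  if (object@indelFrac < 0 || object@indelFrac > 1)
    msg <- c(msg, "'indelFrac' must lie in [0, 1]")
  if (object@insertMean < 2 * object@readLength)
    msg <- c(msg, "'insertMean' must be at least twice the read length")
  if (object@insertSd < 0) msg <- c(msg, "'insertSd' must be non-negative")
  if (object@phredLow < 0 || object@phredHigh <= object@phredLow)
    msg <- c(msg, "need 0 <= phredLow < phredHigh")
  if (length(object@itrList) &&
      !all(vapply(object@itrList, length, 1L) == 2L))
    msg <- c(msg, "each 'itrList' entry must be c(length_bp, copies)")
  if (is.null(msg)) TRUE else msg
})
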