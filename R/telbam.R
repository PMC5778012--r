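BAM_WHAT <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
              "mpos", "isize", "seq", "qual")

# Primary, analysis-grade records only: secondary, supplementary and
# QC-fail alignments never represent an additional template.
primaryFlag <- function(...) {
  scanBamFlag(isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
              isNotPassingQualityControls = FALSE, ...)
}

asBamIfSam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    asBam(path, tempfile(), overwrite = TRUE, indexDestination = TRUE)
  } else path
}

scanReads <- function(path, what = BAM_WHAT, ...) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  res <- tryCatch(
    scanBam(path, param = ScanBamParam(what = what, flag = primaryFlag(...))),
    error = function(e) stop("failed to read BAM file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  res[[1L]]
}

headerLines <- function(path) {
  txt <- scanBamHeader(path)[[1L]]$text
  if (!length(txt)) return("@HD\tVN:1.6\tSO:unsorted")
  vapply(seq_along(txt), function(i)
    paste(c(names(txt)[i], txt[[i]]), collapse = "\t"), "")
}

samField <- function(x, na) {
  x <- as.character(x)
  x[is.na(x)] <- na
  x
}

# Serialise scanned records plus a header to SAM text, then convert to a
# sorted, indexed BAM at `dest` (sans extension).
writeBamFromRecords <- function(header, rec, dest) {
  lines <- header
  if (length(rec$qname)) {
    rn <- samField(rec$rname, "*")
    mr <- samField(rec$mrnm, "*")
    mr[mr == rn & mr != "*"] <- "="
    lines <- c(lines, paste(
      rec$qname, rec$flag, rn,
      samField(rec$pos, "0"), samField(rec$mapq, "0"),
      samField(rec$cigar, "*"), mr, samField(rec$mpos, "0"),
      samField(rec$isize, "0"), as.character(rec$seq),
      as.character(rec$qual), sep = "\t"))
  }
  sam <- paste0(dest, ".sam")
  writeLines(lines, sam)
  on.exit(unlink(sam))
  asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
}

#' Extract the TELBAM subset of candidate telomeric read pairs
#'
#' Scans a paired-end BAM (or SAM) and writes a new BAM containing exactly
#' those read pairs where at least one mate's sequence carries two or more
#' occurrences of the telomeric hexamer or of its reverse complement.
#' Both mates of every retained pair are written; the source file is not
#' modified.  Secondary, supplementary and QC-fail records are ignored,
#' and qualifying reads whose mate is missing are dropped with a message.
#'
#' @param bamPath path to a paired-end BAM or SAM file.
#' @param outPath destination TELBAM path; defaults to
#'   \code{<input>.telbam.bam} next to the input.
#' @param hexamer the telomeric repeat unit (default \code{"TTAGGG"});
#'   its reverse complement is searched as well.
#' @return a [TelbamHandle-class] pointing at the new file.
#' @examples
#' spec <- syntheticSpec(tlBp = 1500L, coverageX = 10, decoyBp = 2000L)
#' smp <- generateSample(spec, tempdir())
#' tb <- extractTelbam(smp$bam)
#' pairCount(tb)
#' @export
extractTelbam <- function(bamPath, outPath = NULL, hexamer = TELO_G) {
  bam <- asBamIfSam(bamPath)
  if (is.null(outPath))
    outPath <- sub("(\\.telbam)?\\.bam$", ".telbam.bam", bam)
  rec <- scanReads(bam)
  if (length(rec$qname)) {
    paired <- bitwAnd(rec$flag, 1L) > 0L
    if (!any(paired))
      stop("input contains no paired-end reads; telomere length ",
           "estimation requires paired-end data")
    rec <- lapply(rec, `[`, paired)
  }
  keep <- character(0)
  nOrphan <- 0L
  if (length(rec$qname)) {
    cand <- hexamerCounts(rec$seq, hexamer) >= 2L
    mates <- table(rec$qname)
    candNames <- unique(rec$qname[cand])
    full <- names(mates)[mates == 2L]
    keep <- intersect(candNames, full)
    nOrphan <- length(setdiff(candNames, full))
    if (nOrphan > 0L)
      message(nOrphan, " candidate read(s) dropped: mate not present")
    sel <- rec$qname %in% keep
    rec <- lapply(rec, `[`, sel)
  }
  hdr <- c(headerLines(bam),
           paste0("@PG\tID:telotape\tPN:telotape\tCL:extractTelbam(",
                  basename(bamPath), ")"))
  dest <- sub("\\.bam$", "", outPath)
  out <- writeBamFromRecords(hdr, rec, dest)
  new("TelbamHandle", path = out, pairCount = length(keep),
      readLength = modalLength(if (length(rec$qname)) width(rec$seq) else
                               integer(0)),
      phredOffset = 33L)
}

#' Estimate the insert-length distribution of a library
#'
#' Computes the mean and standard deviation of the absolute template
#' length over properly paired primary alignments (one observation per
#' pair).  Observations are winsorised at the 1st/99th percentiles before
#' the moments are taken, so a handful of chimeric pairs cannot distort
#' the model.  An explicit \code{override} bypasses estimation entirely.
#'
#' @param path BAM or TELBAM file.
#' @param override optional numeric vector \code{c(mean, sd)} used
#'   verbatim; \code{nObservations} is then 0.
#' @return an [InsertSizeModel-class].
#' @export
estimateInsertSize <- function(path, override = NULL) {
  bam <- asBamIfSam(path)
  rec <- scanReads(bam, what = c("isize", "seq"))
  rl <- modalLength(if (length(rec$seq)) width(rec$seq) else integer(0))
  if (!is.null(override)) {
    stopifnot(is.numeric(override), length(override) == 2L)
    return(new("InsertSizeModel", meanInsert = override[1L],
               sdInsert = override[2L], readLength = rl,
               nObservations = 0L))
  }
  tlen <- rec$isize
  tlen <- tlen[!is.na(tlen) & tlen > 0L]
  if (!length(tlen))
    stop("no usable proper pairs with template lengths in '", path,
         "'; supply the insert model explicitly ",
         "(--insert-mean/--insert-sd)")
  if (length(tlen) >= 100L) {
    # guard against chimeric pairs; below ~100 pairs the 1% tails are
    # empty and clamping would only distort the moments
    q <- quantile(tlen, c(0.01, 0.99), names = FALSE, type = 7)
    tlen <- pmin(pmax(tlen, q[1L]), q[2L])
  }
  s <- if (length(tlen) > 1L) sd(tlen) else 0
  new("InsertSizeModel", meanInsert = mean(tlen), sdInsert = s,
      readLength = rl, nObservations = length(tlen))
}

#' Load TELBAM reads in sequenced orientation
#'
#' Reads primary records from a TELBAM (or any BAM) and returns them with
#' sequence and Phred vectors in the orientation the instrument read
#' them: records flagged reverse-strand are reverse-complemented and
#' their qualities reversed.  The boundary-pair classification keys on
#' sequenced orientation (a boundary-complete read always reads CCCTAA),
#' which aligner-forward storage would otherwise obscure.
#'
#' @param path a TELBAM path or [TelbamHandle-class].
#' @return a [S4Vectors::DataFrame] with columns \code{qname},
#'   \code{flag}, \code{reversed}, \code{seq} (character),
#'   \code{phred} (IntegerList), and metadata entries \code{pMin},
#'   \code{pMax}, \code{readLength}, \code{path}.
#' @export
readTelbam <- function(path) {
  if (is(path, "TelbamHandle")) path <- telbamPath(path)
  rec <- scanReads(path, what = c("qname", "flag", "seq", "qual"))
  if (!length(rec$qname)) {
    out <- DataFrame(qname = character(0), flag = integer(0),
                     reversed = logical(0), seq = character(0),
                     phred = IntegerList())
    metadata(out) <- list(pMin = 0L, pMax = 0L, readLength = 0L,
                          path = path)
    return(out)
  }
  reversed <- bitwAnd(rec$flag, 16L) > 0L
  seqs <- rec$seq
  if (any(reversed))
    seqs[reversed] <- reverseComplement(seqs[reversed])
  phred <- as(rec$qual, "IntegerList")
  if (any(reversed))
    phred <- revElements(phred, reversed)
  pAll <- unlist(phred, use.names = FALSE)
  out <- DataFrame(qname = rec$qname, flag = rec$flag, reversed = reversed,
                   seq = as.character(seqs), phred = phred)
  metadata(out) <- list(pMin = min(pAll), pMax = max(pAll),
                        readLength = modalLength(width(rec$seq)),
                        path = path)
  out
}
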