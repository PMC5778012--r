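#' Is a read fully telomeric?
#'
#' A read counts as a complete telomere read when at least 90% of its
#' loci agree with the telomeric repeat, or when its (lambda, z) cell is
#' set in the error profile mask, marking it as a complete read suffering
#' from sequencing error.  The orientation reports which repeat dominates
#' the sequenced read: \code{"G"} (TTAGGG), \code{"C"} (CCCTAA), or
#' \code{"none"} when the two counts tie.
#'
#' @param seq single read sequence in sequenced orientation.
#' @param phred integer Phred vector of the same length.
#' @param profile an [ErrorProfile-class] built on the same TELBAM.
#' @param completeness minimum matching fraction (default 0.90; values
#'   above 0.90 are reported to reduce accuracy).
#' @return list with \code{complete} (logical) and \code{orientation}.
#' @export
isFullyTelomeric <- function(seq, phred, profile, completeness = 0.9) {
  nf <- .count_occurrences_cpp(seq, TELO_G)
  nr <- .count_occurrences_cpp(seq, TELO_C)
  unit <- if (nr > nf) TELO_C else TELO_G
  m <- .mismatch_loci_cpp(seq, as.integer(phred), unit)
  z <- sum(m)
  L <- nchar(seq)
  complete <- (L - z) / L >= completeness
  if (!complete && z >= 1L) {
    lam <- floor(sum(m * phred) / z) - profile@pMin
    complete <- maskHit(profile, lam, z)
  }
  orientation <- if (nf > nr) "G" else if (nr > nf) "C" else "none"
  list(complete = complete, orientation = orientation)
}

maskHit <- function(profile, lam, z) {
  E <- profile@E
  !is.na(lam) & !is.na(z) & lam >= 0L & lam < nrow(E) & z >= 1L &
    z < ncol(E) & E[cbind(pmax(lam, 0L) + 1L,
                          pmin(pmax(z, 0L), ncol(E) - 1L) + 1L)] == 1L
}

# Vectorised completeness/orientation over a reads DataFrame with
# mismatch statistics attached.
readCompleteness <- function(reads, profile, completeness = 0.9) {
  reads <- mismatchStats(reads)
  L <- nchar(reads$seq)
  complete <- (L - reads$z) / L >= completeness
  rescue <- !complete & reads$z >= 1L &
    maskHit(profile, reads$lam, reads$z)
  orientation <- ifelse(reads$nFwd > reads$nRev, "G",
                        ifelse(reads$nRev > reads$nFwd, "C", "none"))
  list(complete = complete | rescue, rescued = rescue,
       orientation = orientation)
}

#' Classify one read pair
#'
#' F1: both mates complete telomere.  F2: exactly one complete and it
#' reads CCCTAA (a true boundary pair or the matching side of an
#' interstitial repeat).  F4: exactly one complete and it reads TTAGGG
#' (the far side of an interstitial repeat; the chromosome does not
#' continue beyond a true telomere, so these can only arise inside an
#' arm).  F3: everything else, including the tie case where a complete
#' read has equal TTAGGG and CCCTAA content.
#'
#' @param seq1,seq2 mate sequences in sequenced orientation.
#' @param phred1,phred2 integer Phred vectors.
#' @param profile an [ErrorProfile-class].
#' @param completeness minimum matching fraction for a complete read.
#' @return one of \code{"F1"}, \code{"F2"}, \code{"F3"}, \code{"F4"}.
#' @export
classifyPair <- function(seq1, phred1, seq2, phred2, profile,
                         completeness = 0.9) {
  r1 <- isFullyTelomeric(seq1, phred1, profile, completeness)
  r2 <- isFullyTelomeric(seq2, phred2, profile, completeness)
  pairCategory(r1$complete, r2$complete, r1$orientation, r2$orientation)
}

pairCategory <- function(c1, c2, o1, o2) {
  ifelse(c1 & c2, "F1",
    ifelse(!c1 & !c2, "F3", {
      oc <- ifelse(c1, o1, o2)
      ifelse(oc == "C", "F2", ifelse(oc == "G", "F4", "F3"))
    }))
}

#' Tally read-pair categories over a TELBAM
#'
#' Classifies every read pair and derives the boundary count
#' F2a = F2 - F4: each interstitial telomeric repeat contributes, on
#' average, one TTAGGG-complete (F4) pair for every CCCTAA-complete pair
#' it adds to F2, so the subtraction leaves the pairs at true telomere
#' boundaries.  A negative difference can only arise from sampling noise
#' and is clamped to zero with a warning.
#'
#' @param telbam a [TelbamHandle-class], a TELBAM path, or a reads
#'   DataFrame from [readTelbam()].
#' @param profile an [ErrorProfile-class] built on the same TELBAM.
#' @param completeness minimum matching fraction for a complete read.
#' @param sampleId label recorded in the result.
#' @return a [ReadPairCounts-class].
#' @export
countPairs <- function(telbam, profile, completeness = 0.9,
                       sampleId = "sample") {
  reads <- if (is(telbam, "DataFrame")) telbam else readTelbam(telbam)
  if (!nrow(reads))
    return(new("ReadPairCounts", sampleId = sampleId, f1 = 0L, f2 = 0L,
               f3 = 0L, f4 = 0L, f2a = 0))
  cc <- readCompleteness(reads, profile, completeness)
  ord <- order(reads$qname)
  qn <- reads$qname[ord]
  first <- which(!duplicated(qn))
  sizes <- diff(c(first, length(qn) + 1L))
  pairsIdx <- first[sizes == 2L]
  i1 <- ord[pairsIdx]
  i2 <- ord[pairsIdx + 1L]
  cat4 <- pairCategory(cc$complete[i1], cc$complete[i2],
                       cc$orientation[i1], cc$orientation[i2])
  nTies <- sum(xor(cc$complete[i1], cc$complete[i2]) &
                 ifelse(cc$complete[i1], cc$orientation[i1],
                        cc$orientation[i2]) == "none")
  if (nTies > 0L)
    message(nTies, " pair(s) with a complete read of tied repeat ",
            "orientation classified F3")
  tab <- table(factor(cat4, levels = c("F1", "F2", "F3", "F4")))
  f2a <- as.integer(tab[["F2"]]) - as.integer(tab[["F4"]])
  if (f2a < 0) {
    warning("F4 exceeds F2 (", tab[["F4"]], " > ", tab[["F2"]],
            "); clamping F2a to 0")
    f2a <- 0L
  }
  new("ReadPairCounts", sampleId = sampleId,
      f1 = as.integer(tab[["F1"]]), f2 = as.integer(tab[["F2"]]),
      f3 = as.integer(tab[["F3"]]), f4 = as.integer(tab[["F4"]]),
      f2a = as.numeric(f2a))
}
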