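# Shared fixture builders and independent oracles.  Everything is built
# in code at test time; no binary fixtures live in the repository.

suppressPackageStartupMessages({
  library(S4Vectors)
  library(IRanges)
})

PHRED_I <- strtoi(charToRaw("I"), 16L) - 33L  # 40

# Write SAM text (header + records) and convert to an indexed BAM.
samToBam <- function(recordLines, sqLines = "@SQ\tSN:chr1\tLN:100000",
                     dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, paste0("fx", as.integer(stats::runif(1, 1, 1e8)), ".sam"))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", sqLines, recordLines), sam)
  Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE,
                   indexDestination = TRUE)
}

# A proper pair: r1 stored as given (forward), r2 given in *sequenced*
# orientation and stored reverse-complemented, as an aligner would.
pairRecords <- function(qname, r1, r2seq, pos1 = 100L, isize = 300L,
                        q1 = strrep("I", nchar(r1)),
                        q2 = strrep("I", nchar(r2seq)),
                        rname = "chr1") {
  L2 <- nchar(r2seq)
  pos2 <- pos1 + isize - L2
  r2stored <- oracleRevComp(r2seq)
  q2stored <- paste(rev(strsplit(q2, "")[[1]]), collapse = "")
  c(paste(qname, 99L, rname, pos1, 60L, paste0(nchar(r1), "M"), "=",
          pos2, isize, r1, q1, sep = "\t"),
    paste(qname, 147L, rname, pos2, 60L, paste0(L2, "M"), "=", pos1,
          -isize, r2stored, q2stored, sep = "\t"))
}

# --- independent oracles (no package code paths) ---------------------

oracleRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force non-overlapping substring count
oracleCount <- function(seq, pat) {
  n <- 0L
  i <- 1L
  w <- nchar(pat)
  while (i + w - 1L <= nchar(seq)) {
    if (substr(seq, i, i + w - 1L) == pat) {
      n <- n + 1L
      i <- i + w
    } else i <- i + 1L
  }
  n
}

# capture rule over both strands, applied to one read
oracleIsCandidate <- function(seq) {
  max(oracleCount(seq, "TTAGGG"), oracleCount(seq, "CCCTAA")) >= 2L
}

# closed-form expected F1:F2a ratio for a fixed insert I
oracleRatio <- function(tl, I, L) (tl - I + 1) / (I - L)

# best single-phase Hamming alignment of a read against (unit)*
oraclePhaseHamming <- function(seq, unit = "TTAGGG") {
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  ref <- strsplit(strrep(unit, ceiling((L + 6) / 6)), "")[[1]]
  min(vapply(0:5, function(off) sum(ref[(1:L) + off] != s), 1))
}

# delta-method Monte-Carlo standard error of a simulated n1/(n-n1) ratio
ratioSE <- function(p, n) sqrt(p * (1 - p) / n) / (1 - p)^2

# --- in-memory reads table mimicking readTelbam() output -------------

makeReadsDF <- function(seqs, phreds, qnames = sprintf("q%04d",
                                                       seq_along(seqs)),
                        flags = rep(0L, length(seqs)),
                        pMin = NULL, pMax = NULL, readLength = NULL) {
  pAll <- unlist(phreds)
  out <- DataFrame(qname = qnames, flag = as.integer(flags),
                   reversed = rep(FALSE, length(seqs)),
                   seq = seqs, phred = IntegerList(phreds))
  metadata(out) <- list(
    pMin = if (is.null(pMin)) min(pAll) else pMin,
    pMax = if (is.null(pMax)) max(pAll) else pMax,
    readLength = if (is.null(readLength)) max(nchar(seqs)) else readLength,
    path = "<memory>")
  out
}

# an ErrorProfile with an all-zero mask, for classification tests that
# should not involve error rescue
emptyProfile <- function(p = 29L, L = 100L, pMin = 10L) {
  Z <- matrix(0L, p + 1L, L, dimnames = list(lam = 0:p, z = 0:(L - 1L)))
  new("ErrorProfile", E = Z, X = Z, Y = Z, D = Z, k = 0,
      pMin = as.integer(pMin), pMax = as.integer(pMin + p), seed = 1L,
      dropped = 0L)
}

randomSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = "")

perfectRepeat <- function(L, unit = "TTAGGG")
  substr(strrep(unit, ceiling(L / 6)), 1, L)
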