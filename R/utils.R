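# Repeat units: the G-strand hexamer and its reverse complement, which is
# what a read sequenced off the C-strand contains.
TELO_G <- "TTAGGG"
TELO_C <- "CCCTAA"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Normal draws truncated below at `lower`.  sd = 0 collapses to the mean.
rnormTruncLow <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  plo <- pnorm(lower, mean, sd)
  if (plo >= 1) return(rep(lower, n))
  qnorm(runif(n, plo, 1), mean, sd)
}

revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Occurrence counts of the hexamer; the telomeric hexamer cannot overlap
# itself so overlapping and non-overlapping counts coincide.
hexamerCounts <- function(seqs, hexamer = TELO_G) {
  ss <- DNAStringSet(seqs)
  pmax(vcountPattern(hexamer, ss), vcountPattern(revComp(hexamer), ss))
}

# Repeat tract of exactly `n` bases starting at phase 0 of `unit`.
repeatTract <- function(n, unit = TELO_G) {
  substr(strrep(unit, ceiling(n / nchar(unit))), 1L, n)
}

phredToChar <- function(p, offset = 33L) {
  vapply(p, function(v) intToUtf8(v + offset), "")
}

modalLength <- function(w) {
  if (!length(w)) return(0L)
  tw <- table(w)
  as.integer(names(tw)[which.max(tw)])
}
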