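#' Expected internal:boundary ratio at a given telomere length
#'
#' Monte-Carlo model of read-pair sampling at one telomere: fragments
#' with insert lengths drawn from Normal(mean, sd) truncated below at
#' twice the read length are placed uniformly over a construct whose
#' first \code{tl} bases are telomere, followed by ample subtelomere.  A
#' fragment scores F1 when both reads lie wholly inside the telomere and
#' F2a when it crosses the boundary with its telomere-proximal read
#' complete.  Returns the F1:F2a count ratio; the ratio grows with
#' \code{tl} because a longer tract admits more interior fragments while
#' the boundary zone stays fixed at (insert - read length) positions.
#'
#' @param tl telomere length in bases (must exceed the read length).
#' @param model an [InsertSizeModel-class].
#' @param nSim fragments to simulate.
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return the simulated ratio; \code{Inf} with a warning when no
#'   simulated fragment crossed the boundary (tl far too large for nSim).
#' @export
simulateExpectedRatio <- function(tl, model, nSim = 10000L, seed = 1L) {
  stopifnot(is(model, "InsertSizeModel"), nSim >= 1L)
  L <- model@readLength
  if (tl <= L) stop("'tl' must exceed the read length")
  nF1 <- withSeed(seed, {
    ins <- round(rnormTruncLow(nSim, model@meanInsert, model@sdInsert,
                               2 * L))
    start <- sample.int(floor(tl) - L + 1L, nSim, replace = TRUE) - 1L
    sum(start + ins <= tl)
  })
  nF2a <- nSim - nF1
  if (nF2a == 0L) {
    warning("no simulated boundary fragments at tl = ", tl,
            "; increase nSim or reconsider the inputs")
    return(Inf)
  }
  nF1 / nF2a
}

#' Estimate telomere length from read-pair counts
#'
#' Inverts the fragment-placement model: finds the telomere length whose
#' simulated F1:F2a ratio matches the observed ratio, by bracket
#' expansion and bisection.  Every ratio evaluation reuses the same
#' random number stream (common random numbers), which makes the
#' simulated ratio monotone in \code{tl} and the inversion
#' deterministic for a fixed seed.
#'
#' @param f1 internal pair count, or a [ReadPairCounts-class].
#' @param f2a boundary pair count (use the cohort-corrected value when
#'   available); ignored when \code{f1} is a ReadPairCounts, unless
#'   supplied to override the raw F2a.
#' @param model an [InsertSizeModel-class].
#' @param nSim fragments per ratio evaluation.
#' @param seed RNG seed for the simulation stream.
#' @param tol bisection tolerance on tl, in base pairs.
#' @param maxIter bisection iteration cap.
#' @param platform optional platform label recorded for batch correction.
#' @return a [LengthEstimate-class].
#' @export
estimateLength <- function(f1, f2a = NULL, model, nSim = 10000L, seed = 1L,
                           tol = 1, maxIter = 60L, platform = "") {
  if (is(f1, "ReadPairCounts")) {
    counts <- f1
    if (is.null(f2a)) f2a <- counts@f2a
    f1 <- counts@f1
  }
  if (is.null(f2a) || is.na(f2a) || f2a <= 0)
    stop("no boundary reads; cannot normalise the telomere read count ",
         "into a length")
  stopifnot(is(model, "InsertSizeModel"))
  if (f1 < 0) stop("'f1' must be non-negative")
  L <- model@readLength
  target <- f1 / f2a
  if (f1 == 0)
    warning("F1 = 0: no interior fragments observed; the telomere is ",
            "shorter than the typical insert and the estimate is a ",
            "degenerate lower bound")
  ratioAt <- function(tl) simulateExpectedRatio(tl, model, nSim, seed)
  lo <- L + 1
  hi <- max(2 * model@meanInsert, lo + 1)
  expand <- 0L
  while (ratioAt(hi) < target) {
    expand <- expand + 1L
    if (expand > 30L)
      stop("cannot bracket the observed ratio ", signif(target, 6),
           " (tl searched up to ", hi, " bp); counts and insert model ",
           "are inconsistent")
    hi <- hi * 2
  }
  iter <- 0L
  while (hi - lo > tol && iter < maxIter) {
    mid <- (lo + hi) / 2
    if (ratioAt(mid) < target) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  new("LengthEstimate", tlBp = (lo + hi) / 2, f1 = as.numeric(f1),
      f2aUsed = as.numeric(f2a), insertModel = model,
      nSim = as.integer(nSim), seed = as.integer(seed),
      platform = platform, tlBpCorrected = NA_real_)
}

#' Mean-matching batch correction across sequencing platforms
#'
#' Estimates from different platforms can differ by an additive offset
#' (lower-quality runs depress the boundary-read signal).  This shifts
#' every non-reference platform group by the difference of group means,
#' so all group means coincide with the reference group's.  Within-group
#' differences are preserved exactly.  With a single platform the
#' correction is a no-op.
#'
#' @param tl numeric vector of length estimates in bp.
#' @param platform character vector of platform labels, same length.
#' @param reference reference platform; defaults to the first label
#'   alphabetically.
#' @param offset optional named numeric vector of explicit per-platform
#'   offsets to add, bypassing mean matching.
#' @return numeric vector of corrected lengths.
#' @export
batchCorrect <- function(tl, platform, reference = NULL, offset = NULL) {
  stopifnot(length(tl) == length(platform))
  platform <- as.character(platform)
  if (!is.null(offset)) {
    shift <- ifelse(platform %in% names(offset), offset[platform], 0)
    return(tl + unname(shift))
  }
  groups <- sort(unique(platform))
  if (length(groups) < 2L) {
    message("single platform: batch correction is a no-op")
    return(tl)
  }
  if (is.null(reference)) reference <- groups[1L]
  if (!reference %in% groups) stop("unknown reference platform")
  refMean <- mean(tl[platform == reference])
  out <- tl
  for (g in setdiff(groups, reference)) {
    idx <- platform == g
    out[idx] <- tl[idx] + (refMean - mean(tl[idx]))
  }
  out
}
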