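#' Estimate telomere lengths for one or more TELBAMs
#'
#' Runs the full per-sample pipeline: load TELBAM reads in sequenced
#' orientation, build the Phred/mismatch error profile, classify read
#' pairs into F1/F2/F3/F4, derive the boundary count F2a = F2 - F4,
#' apply the cohort-weighted correction when two or more samples are
#' processed together, estimate the insert-length model from template
#' lengths (or use the supplied override), and invert the F1:F2a ratio
#' into a mean telomere length by fragment-placement simulation.
#'
#' @param telbams character vector of TELBAM paths and/or a list of
#'   [TelbamHandle-class] objects.
#' @param sampleIds sample labels; defaults to the file base names.
#' @param insertOverride optional \code{c(mean, sd)} insert model used
#'   for every sample instead of estimation.
#' @param seed base seed; per-sample streams are derived from it, so a
#'   fixed seed gives bit-identical output.
#' @param nSim fragments per ratio evaluation in the length inversion.
#' @param cohortCorrection apply the cohort F2a correction when at least
#'   two samples are given.
#' @param cohortWeight weight w of the cohort mean (default 3).
#' @param strictDenominator use the strict non-normalised correction
#'   denominator (see [correctTheta()]).
#' @param completeness minimum matching fraction for a complete read.
#' @param platforms optional character vector of platform labels (same
#'   length as \code{telbams}); triggers mean-matching batch correction.
#' @param tol bisection tolerance in bp.
#' @param profileDir optional directory; when set, the X/Y/D/E error
#'   profile diagnostics of every sample are written there.
#' @return data.frame with one row per sample: \code{sample}, the four
#'   category counts, raw and corrected F2a, psi, theta values, the
#'   insert model, \code{tl_bp}, \code{tl_bp_corrected} and the seed.
#' @export
telbamToLength <- function(telbams, sampleIds = NULL,
                           insertOverride = NULL, seed = 1L,
                           nSim = 10000L, cohortCorrection = TRUE,
                           cohortWeight = 3, strictDenominator = FALSE,
                           completeness = 0.9, platforms = NULL,
                           tol = 1, profileDir = NULL) {
  if (is(telbams, "TelbamHandle")) telbams <- list(telbams)
  paths <- vapply(telbams, function(x)
    if (is(x, "TelbamHandle")) telbamPath(x) else as.character(x), "")
  n <- length(paths)
  if (!n) stop("no TELBAMs supplied")
  if (is.null(sampleIds))
    sampleIds <- sub("\\.(tel)?bam$", "", basename(paths))
  stopifnot(length(sampleIds) == n)
  if (!is.null(platforms)) stopifnot(length(platforms) == n)

  perSample <- vector("list", n)
  for (i in seq_len(n)) {
    reads <- mismatchStats(readTelbam(paths[i]))
    md <- metadata(reads)
    jm <- buildJointMatrices(reads, seed = seed + i)
    profile <- buildErrorMask(jm$X, jm$Y, seed = seed + i,
                              pMin = md$pMin, pMax = md$pMax)
    counts <- countPairs(reads, profile, completeness = completeness,
                         sampleId = sampleIds[i])
    if (!is.null(profileDir))
      writeErrorProfile(profile, profileDir, prefix = sampleIds[i])
    perSample[[i]] <- list(counts = counts, psi = computePsi(jm$X),
                           readLength = md$readLength)
  }
  cohort <- data.frame(
    sample_id = sampleIds,
    F1 = vapply(perSample, function(x) x$counts@f1, 1L),
    F2 = vapply(perSample, function(x) x$counts@f2, 1L),
    F3 = vapply(perSample, function(x) x$counts@f3, 1L),
    F4 = vapply(perSample, function(x) x$counts@f4, 1L),
    F2a = vapply(perSample, function(x) x$counts@f2a, 1),
    psi = vapply(perSample, function(x) x$psi, 1))
  doCohort <- isTRUE(cohortCorrection) && n >= 2L
  if (doCohort) {
    cohort <- correctTheta(cohort, w = cohortWeight,
                           strictDenominator = strictDenominator)
  } else {
    denom <- cohort$F2 + cohort$F4
    cohort$theta_obs <- ifelse(denom > 0, cohort$F2a / denom, 0)
    cohort$theta_cor <- cohort$theta_obs
    cohort$F2a_adjusted <- cohort$F2a
  }

  tl <- numeric(n)
  insMean <- numeric(n)
  insSd <- numeric(n)
  for (i in seq_len(n)) {
    f2aUsed <- cohort$F2a_adjusted[i]
    if (is.na(f2aUsed) || f2aUsed <= 0)
      stop("no boundary reads; cannot normalise the telomere read ",
           "count into a length (sample ", sampleIds[i], ")")
    model <- estimateInsertSize(paths[i], override = insertOverride)
    est <- estimateLength(cohort$F1[i], f2aUsed, model, nSim = nSim,
                          seed = seed + 1000L + i, tol = tol)
    tl[i] <- tlBp(est)
    insMean[i] <- insertMean(model)
    insSd[i] <- insertSd(model)
  }
  tlCorrected <- if (!is.null(platforms))
    batchCorrect(tl, platforms) else rep(NA_real_, n)

  data.frame(
    sample = sampleIds,
    F1 = cohort$F1, F2 = cohort$F2, F3 = cohort$F3, F4 = cohort$F4,
    F2a_raw = cohort$F2a, F2a_corrected = cohort$F2a_adjusted,
    psi = cohort$psi, theta_obs = cohort$theta_obs,
    theta_cor = cohort$theta_cor,
    insert_mean = insMean, insert_sd = insSd,
    read_len = vapply(perSample, function(x) x$readLength, 1L),
    tl_bp = tl, tl_bp_corrected = tlCorrected,
    seed = rep(as.integer(seed), n))
}

#' Estimate telomere lengths straight from BAM files
#'
#' Composes [extractTelbam()] and [telbamToLength()].
#'
#' @param bams character vector of BAM/SAM paths.
#' @param outDir directory for the intermediate TELBAMs.
#' @param ... passed on to [telbamToLength()].
#' @return the [telbamToLength()] data.frame.
#' @export
bamToLength <- function(bams, outDir = tempfile("telbams"), ...) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  telbams <- vapply(bams, function(b) {
    out <- file.path(outDir,
                     sub("\\.(bam|sam)$", ".telbam.bam", basename(b)))
    telbamPath(extractTelbam(b, out))
  }, "")
  telbamToLength(telbams, ...)
}

#' Write the per-sample results table to CSV
#'
#' @param results data.frame from [telbamToLength()].
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
writeLengthCsv <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
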