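#' Describe a synthetic paired-end WGS sample
#'
#' Constructor for [SyntheticSpec-class].  Defaults describe the
#' validation conditions used throughout the package: 100 bp reads at
#' 50x coverage, 350 +/- 30 bp inserts, 1% per-base error with 90% of
#' errors forced onto low-Phred loci, twelve telomere-bearing constructs
#' (a tractable stand-in for the dozens of telomere ends of a real
#' genome; the estimator sees only the F1:F2a ratio, but more ends mean
#' more boundary pairs and less sampling noise per sample) with 1.5 kb
#' of random subtelomere each, and a 5 kb random decoy.
#'
#' @param sampleId unique sample label.
#' @param tlBp true telomere tract length (bp).
#' @param nTelomeres number of telomere-bearing constructs (0 allowed,
#'   e.g. for ITR-only fixtures).
#' @param subtelomereBp random subtelomere per construct (bp).
#' @param itrList list of \code{c(length_bp, copies)} ITR descriptors.
#' @param coverageX mean read coverage per construct.
#' @param readLength read length L (bp).
#' @param insertMean,insertSd insert length distribution (bp).
#' @param errorRate per-base error probability in [0, 1).
#' @param lowPhredBias fraction of errors placed on low-Phred loci.
#' @param lowPhredFrac fraction of loci assigned the low Phred score.
#' @param indelFrac fraction of errors that are indels.
#' @param phredHigh,phredLow the two Phred levels.
#' @param decoyBp random decoy construct length (0 disables).
#' @param seed RNG seed.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(sampleId = "sample1", tlBp = 5000L,
                          nTelomeres = 12L, subtelomereBp = 1500L,
                          itrList = list(), coverageX = 50,
                          readLength = 100L, insertMean = 350,
                          insertSd = 30, errorRate = 0.01,
                          lowPhredBias = 0.9, lowPhredFrac = 0.1,
                          indelFrac = 0.1, phredHigh = 39L,
                          phredLow = 11L, decoyBp = 5000L, seed = 1L) {
  new("SyntheticSpec", sampleId = sampleId, tlBp = as.integer(tlBp),
      nTelomeres = as.integer(nTelomeres),
      subtelomereBp = as.integer(subtelomereBp), itrList = itrList,
      coverageX = coverageX, readLength = as.integer(readLength),
      insertMean = insertMean, insertSd = insertSd,
      errorRate = errorRate, lowPhredBias = lowPhredBias,
      lowPhredFrac = lowPhredFrac, indelFrac = indelFrac,
      phredHigh = as.integer(phredHigh), phredLow = as.integer(phredLow),
      decoyBp = as.integer(decoyBp), seed = as.integer(seed))
}

OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

# Inject substitution/indel errors into one read (sequenced orientation).
# Error loci are drawn preferentially from the low-Phred loci; indels
# shift the remainder of the read and keep its length by borrowing a
# random terminal base.
injectErrors <- function(chars, phred, spec) {
  L <- length(chars)
  nErr <- rbinom(1L, L, spec@errorRate)
  if (nErr == 0L) return(chars)
  lowIdx <- which(phred == spec@phredLow)
  nLow <- min(rbinom(1L, nErr, spec@lowPhredBias), length(lowIdx))
  loci <- integer(0)
  if (nLow > 0L)
    loci <- sample(lowIdx, nLow)
  nRest <- nErr - length(loci)
  if (nRest > 0L) {
    pool <- setdiff(seq_len(L), loci)
    loci <- c(loci, sample(pool, min(nRest, length(pool))))
  }
  isIndel <- runif(length(loci)) < spec@indelFrac
  for (i in loci[!isIndel])
    chars[i] <- sample(OTHER_BASES[[chars[i]]], 1L)
  for (i in sort(loci[isIndel], decreasing = TRUE)) {
    if (runif(1L) < 0.5) {            # deletion
      chars <- c(chars[-i], sample(c("A", "C", "G", "T"), 1L))
    } else {                          # insertion
      chars <- c(head(chars, i - 1L),
                 sample(c("A", "C", "G", "T"), 1L),
                 chars[i:(L - 1L)])
    }
  }
  chars[seq_len(L)]
}

# Fragment geometry for one construct: 0-based starts and insert sizes.
# ITR constructs are sampled in mirrored twins (reflection about the
# construct midpoint), so the two ITR boundaries contribute exactly
# matched pair counts and the F2b == F4 cancellation is exact in truth.
drawFragments <- function(clen, nFrag, spec, mirrored) {
  if (mirrored) nFrag <- ceiling(nFrag / 2)
  if (nFrag == 0L)
    return(data.frame(start = integer(0), insert = integer(0)))
  ins <- pmin(as.integer(round(rnormTruncLow(
    nFrag, spec@insertMean, spec@insertSd, 2 * spec@readLength))), clen)
  start <- floor(runif(nFrag) * (clen - ins + 1))
  df <- data.frame(start = as.integer(start), insert = ins)
  if (mirrored)
    df <- rbind(df, data.frame(start = as.integer(clen - start - ins),
                               insert = ins))
  df
}

pairOrigin <- function(kind, start, insert, L, region) {
  if (is.null(region)) {
    none <- rep(FALSE, length(start))
    return(list(origin = rep("other", length(start)), r1 = none,
                r2 = none))
  }
  r1c <- start >= region[1L] & start + L <= region[2L]
  r2c <- start + insert - L >= region[1L] & start + insert <= region[2L]
  origin <- rep("other", length(start))
  if (kind == "telomere") {
    origin[r1c & r2c] <- "f1"
    origin[!r1c & r2c] <- "boundary"
    origin[r1c & !r2c] <- "g_side"
  } else {
    origin[r1c & r2c] <- "itr_internal"
    origin[!r1c & r2c] <- "itr_c"
    origin[r1c & !r2c] <- "itr_g"
  }
  list(origin = origin, r1 = r1c, r2 = r2c)
}

#' Generate a synthetic paired-end BAM with ground truth
#'
#' Emits proper read pairs from telomere-bearing constructs (random
#' subtelomere followed by a TTAGGG tract of known length), optional ITR
#' constructs (a telomere-repeat run embedded in random sequence) and a
#' random decoy construct.  Reads are written with correct flags, mate
#' information and template lengths so insert-size estimation works; the
#' reverse mate is stored reference-forward per the SAM convention.
#' Per-base Phred scores follow a two-level model and
#' substitution/indel errors are injected at the specified rate,
#' preferentially onto low-Phred loci.  The returned truth table records
#' the generative origin of every pair.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if needed).
#' @return list with \code{bam} (path), \code{truth} (per-pair
#'   data.frame: qname, construct, origin, r1_telomeric, r2_telomeric,
#'   start, insert), and \code{summary} (one-row data.frame of origin
#'   tallies and the true length).
#' @export
generateSample <- function(spec, dir = tempdir()) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  L <- spec@readLength
  withSeed(spec@seed, {
    constructs <- list()
    if (spec@nTelomeres > 0L) for (t in seq_len(spec@nTelomeres)) {
      seqc <- paste0(randomDna(spec@subtelomereBp), repeatTract(spec@tlBp))
      constructs[[sprintf("telo%02d", t)]] <- list(
        kind = "telomere", seq = seqc,
        region = c(spec@subtelomereBp, spec@subtelomereBp + spec@tlBp),
        mirrored = FALSE)
    }
    if (length(spec@itrList)) for (g in seq_along(spec@itrList)) {
      len <- as.integer(spec@itrList[[g]][1L])
      copies <- as.integer(spec@itrList[[g]][2L])
      flank <- max(2000L, as.integer(2 * spec@insertMean))
      for (cp in seq_len(copies)) {
        seqc <- paste0(randomDna(flank), repeatTract(len), randomDna(flank))
        constructs[[sprintf("itr%02d_%03d", g, cp)]] <- list(
          kind = "itr", seq = seqc, region = c(flank, flank + len),
          mirrored = TRUE)
      }
    }
    if (spec@decoyBp > 0L)
      constructs[["decoy"]] <- list(kind = "decoy",
                                    seq = randomDna(spec@decoyBp),
                                    region = NULL, mirrored = FALSE)
    if (!length(constructs))
      stop("spec describes no constructs (no telomeres, ITRs or decoy)")

    samLines <- c("@HD\tVN:1.6\tSO:unsorted",
                  vapply(names(constructs), function(nm) sprintf(
                    "@SQ\tSN:%s\tLN:%d", nm, nchar(constructs[[nm]]$seq)),
                    ""),
                  "@PG\tID:telotape-sim\tPN:telotape\tCL:generateSample")
    truth <- list()
    fragId <- 0L
    for (nm in names(constructs)) {
      con <- constructs[[nm]]
      clen <- nchar(con$seq)
      nFrag <- max(0L, as.integer(round(
        spec@coverageX * clen / (2 * L))))
      fr <- drawFragments(clen, nFrag, spec, con$mirrored)
      if (!nrow(fr)) next
      og <- pairOrigin(con$kind, fr$start, fr$insert, L, con$region)
      r1raw <- substring(con$seq, fr$start + 1L, fr$start + L)
      r2raw <- revComp(substring(con$seq, fr$start + fr$insert - L + 1L,
                                 fr$start + fr$insert))
      qn <- sprintf("%s_frag%07d", spec@sampleId, fragId + seq_len(nrow(fr)))
      fragId <- fragId + nrow(fr)
      nf <- nrow(fr)
      c1all <- strsplit(r1raw, "", fixed = TRUE)
      c2all <- strsplit(r2raw, "", fixed = TRUE)
      s1 <- character(nf); s2stored <- character(nf)
      q1 <- character(nf); q2stored <- character(nf)
      for (i in seq_len(nf)) {
        p1 <- rep(spec@phredHigh, L)
        p1[runif(L) < spec@lowPhredFrac] <- spec@phredLow
        p2 <- rep(spec@phredHigh, L)
        p2[runif(L) < spec@lowPhredFrac] <- spec@phredLow
        c1 <- injectErrors(c1all[[i]], p1, spec)
        c2 <- injectErrors(c2all[[i]], p2, spec)
        s1[i] <- paste(c1, collapse = "")
        # SAM stores the reverse mate reference-forward
        s2stored[i] <- paste(BASE_COMP[rev(c2)], collapse = "")
        q1[i] <- intToUtf8(p1 + 33L)
        q2stored[i] <- intToUtf8(rev(p2) + 33L)
      }
      pos1 <- fr$start + 1L
      pos2 <- fr$start + fr$insert - L + 1L
      cig <- paste0(L, "M")
      samLines <- c(samLines,
        paste(qn, 99L, nm, pos1, 60L, cig, "=", pos2, fr$insert,
              s1, q1, sep = "\t"),
        paste(qn, 147L, nm, pos2, 60L, cig, "=", pos1, -fr$insert,
              s2stored, q2stored, sep = "\t"))
      truth[[nm]] <- data.frame(
        qname = qn, construct = nm, origin = og$origin,
        r1_telomeric = og$r1, r2_telomeric = og$r2,
        start = fr$start, insert = fr$insert)
    }
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    samPath <- file.path(dir, paste0(spec@sampleId, ".sam"))
    writeLines(samLines, samPath)
    on.exit(unlink(samPath), add = TRUE)
    bam <- asBam(samPath, file.path(dir, spec@sampleId),
                 overwrite = TRUE, indexDestination = TRUE)
    tab <- table(factor(truth$origin,
                        levels = c("f1", "boundary", "g_side", "itr_c",
                                   "itr_g", "itr_internal", "other")))
    summary <- data.frame(sample_id = spec@sampleId, tl_bp = spec@tlBp,
                          n_pairs = nrow(truth), as.list(tab),
                          check.names = FALSE)
    list(bam = bam, truth = truth, summary = summary)
  })
}

#' Generate a cohort of synthetic samples with a manifest
#'
#' @param specs non-empty list of [SyntheticSpec-class] objects with
#'   unique sample ids.
#' @param dir output directory.
#' @return the manifest data.frame (also written to
#'   \code{dir/manifest.csv}): one row per sample linking the BAM path
#'   to the truth tallies.
#' @export
generateCohort <- function(specs, dir = tempdir()) {
  if (!length(specs)) stop("empty spec list")
  ids <- vapply(specs, function(s) s@sampleId, "")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(specs, function(s) {
    smp <- generateSample(s, dir)
    cbind(smp$summary, bam = smp$bam)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
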