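test_that("fragmentary alignment marks divergence as worked by hand", {
  # perfect repeat: no divergence
  expect_equal(sum(findMismatchingLoci(perfectRepeat(24), rep(30L, 24))), 0)
  # long perfect read with trailing partial repeat still clean
  expect_equal(sum(findMismatchingLoci(perfectRepeat(100), rep(35L, 100))), 0)
  # single substitution: exactly that locus
  m <- findMismatchingLoci("TTAGGGTTAGGGTTCGGGTTAGGG", rep(30L, 24))
  expect_identical(which(m == 1L), 15L)
  # one deleted base: one mismatch at the lower-Phred junction locus
  ph <- rep(30L, 23); ph[6] <- 12L
  m <- findMismatchingLoci("TTAGGTTAGGGTTAGGGTTAGGG", ph)
  expect_identical(which(m == 1L), 6L)
  ph2 <- rep(30L, 23); ph2[5] <- 12L
  m2 <- findMismatchingLoci("TTAGGTTAGGGTTAGGGTTAGGG", ph2)
  expect_identical(which(m2 == 1L), 5L)
  # shorter than one hexamer: no complete repeat can exist
  expect_equal(sum(findMismatchingLoci("TTAGG", rep(30L, 5))), 5)
  # N bases never match
  mN <- findMismatchingLoci("TTAGGGTTANGGTTAGGGTTAGGG", rep(30L, 24))
  expect_identical(which(mN == 1L), 10L)
})

test_that("sparse substitutions agree with the single-phase Hamming oracle", {
  set.seed(5)
  for (r in 1:60) {
    L <- 100L
    s <- strsplit(perfectRepeat(L), "")[[1]]
    pos <- sample(seq(10, 90, by = 13), sample(1:3, 1))
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    seq <- paste(s, collapse = "")
    z <- sum(findMismatchingLoci(seq, rep(30L, L)))
    expect_equal(z, oraclePhaseHamming(seq))
  }
})

test_that("random sequence diverges at most loci but not all", {
  set.seed(7)
  frac <- replicate(120, {
    L <- 100L
    sum(findMismatchingLoci(randomSeq(L), rep(30L, L))) / L
  })
  expect_gt(mean(frac), 0.55)
  expect_lt(mean(frac), 0.85)
  expect_true(all(frac > 0.3))   # never close to telomere-complete
})

test_that("summarizeRead computes z and lambda per the definition", {
  s <- summarizeRead(c(0L, 0L, 1L, 0L, 1L), c(30L, 30L, 20L, 30L, 40L),
                     pMin = 2L)
  expect_identical(s$z, 2L)
  expect_identical(s$lam, 28L)  # floor(60/2) - 2
  sAll <- summarizeRead(rep(1L, 10), rep(33L, 10), pMin = 5L)
  expect_identical(sAll$z, 10L)
  expect_identical(sAll$lam, 28L)  # constant mean
  sMin <- summarizeRead(c(1L, rep(0L, 9)), c(7L, rep(40L, 9)), pMin = 7L)
  expect_identical(sMin$lam, 0L)   # lower bound
  expect_error(summarizeRead(rep(0L, 5), rep(30L, 5), 2L), "no mismatch")
})

test_that("joint matrices tally (lambda, z) cells and conserve totals", {
  # ten identical reads with z = 1 land in a single cell
  L <- 30L
  s <- perfectRepeat(L)
  substr(s, 15, 15) <- "C"
  ph <- rep(25L, L); ph[15] <- 16L
  reads <- makeReadsDF(rep(s, 10), replicate(10, ph, simplify = FALSE),
                       pMin = 11L, pMax = 39L, readLength = L)
  jm <- buildJointMatrices(reads, seed = 3L)
  expect_equal(jm$X[["5", "1"]], 10L)     # lam = 16 - 11, z = 1
  expect_equal(sum(jm$X), 10L)
  expect_equal(sum(jm$Y), 10L)

  # mixed reads conserve: sum X == sum Y == #reads with z >= 1
  set.seed(11)
  seqs <- c(replicate(15, randomSeq(40)), replicate(5, perfectRepeat(40)))
  phs <- replicate(20, sample(c(11L, 39L), 40, TRUE), simplify = FALSE)
  rr <- makeReadsDF(seqs, phs, pMin = 11L, pMax = 39L, readLength = 40L)
  jm2 <- buildJointMatrices(rr, seed = 9L)
  zz <- telotape:::mismatchStats(rr)$z
  expect_equal(sum(jm2$X), sum(zz >= 1L))
  expect_equal(sum(jm2$X), sum(jm2$Y))
  # seeded: reproducible
  jm3 <- buildJointMatrices(rr, seed = 9L)
  expect_identical(jm2$Y, jm3$Y)
})

test_that("mask threshold k and the quadrant rule follow the definition", {
  p <- 19L; L <- 60L
  dn <- list(lam = 0:p, z = 0:(L - 1L))
  X <- matrix(0L, p + 1L, L, dimnames = dn)
  Y <- matrix(0L, p + 1L, L, dimnames = dn)
  # noise in the high-Phred/high-z quadrant caps k at 2
  X["15", "40"] <- 2L
  # a strong two-cell low-Phred component, plus an isolated stray
  X["1", "8"] <- 10L; X["2", "8"] <- 8L
  X["12", "20"] <- 9L
  Y["19", "8"] <- 20L; Y["19", "20"] <- 9L
  prof <- buildErrorMask(X, Y, pMin = 10L, pMax = 10L + p)
  expect_equal(maskThreshold(prof), 2)
  E <- errorMask(prof)
  expect_equal(E["1", "8"], 1L)
  expect_equal(E["2", "8"], 1L)
  # isolated high-Phred cell removed by the noise rule
  expect_equal(E["12", "20"], 0L)
  # monotone fill: low-Phred cells with positive D left of the anchor set
  X2 <- X; X2["3", "5"] <- 1L   # D > 0 but below k, inside fill region
  prof2 <- buildErrorMask(X2, Y, pMin = 10L, pMax = 10L + p)
  expect_equal(errorMask(prof2)["3", "5"], 1L)
})

test_that("identical matrices give an empty mask", {
  X <- matrix(2L, 11L, 20L, dimnames = list(lam = 0:10, z = 0:19))
  prof <- buildErrorMask(X, X, pMin = 0L, pMax = 10L)
  expect_equal(sum(errorMask(prof)), 0)
  expect_gte(maskThreshold(prof), 0)
})

test_that("a random-mismatch null leaves the mask empty almost surely", {
  nonempty <- 0L
  for (r in 1:8) {
    set.seed(200 + r)
    n <- 250L; L <- 80L
    seqs <- replicate(n, randomSeq(L))
    phs <- replicate(n, sample(c(11L, 39L), L, TRUE, prob = c(0.1, 0.9)),
                     simplify = FALSE)
    reads <- makeReadsDF(seqs, phs, pMin = 11L, pMax = 39L,
                         readLength = L)
    jm <- buildJointMatrices(reads, seed = r)
    prof <- buildErrorMask(jm$X, jm$Y, pMin = 11L, pMax = 39L)
    if (sum(errorMask(prof)) > 0L) nonempty <- nonempty + 1L
  }
  expect_lte(nonempty, 1L)
})

test_that("matrices of mismatched shape are rejected", {
  A <- matrix(0L, 5, 10)
  B <- matrix(0L, 6, 10)
  expect_error(buildErrorMask(A, B), "identical dimensions")
})
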