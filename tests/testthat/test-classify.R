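test_that("category assignment follows completeness and orientation", {
  prof <- emptyProfile(p = 29L, L = 100L, pMin = 10L)
  telo <- perfectRepeat(100)
  cclo <- perfectRepeat(100, "CCCTAA")
  junk <- randomSeq(100)
  ph <- rep(30L, 100)
  expect_identical(classifyPair(telo, ph, cclo, ph, prof), "F1")
  expect_identical(classifyPair(cclo, ph, junk, ph, prof), "F2")
  expect_identical(classifyPair(telo, ph, junk, ph, prof), "F4")
  set.seed(3)
  expect_identical(classifyPair(junk, ph, randomSeq(100), ph, prof), "F3")
})

test_that("the 90% rule and the mask rescue interact as specified", {
  # 84 matching loci out of 100: fails the 90% rule on its own
  s <- paste0(perfectRepeat(84), strrep("N", 16))
  ph <- c(rep(30L, 84), rep(12L, 16))
  pMin <- 10L
  prof0 <- emptyProfile(p = 29L, L = 100L, pMin = pMin)
  r0 <- isFullyTelomeric(s, ph, prof0)
  expect_false(r0$complete)
  expect_identical(r0$orientation, "G")
  # same read with its (lambda, z) cell set in the mask: rescued
  profE <- prof0
  lam <- floor(sum(ph[85:100]) / 16) - pMin
  E <- errorMask(prof0)
  E[as.character(lam), as.character(16L)] <- 1L
  profE@E <- E
  r1 <- isFullyTelomeric(s, ph, profE)
  expect_true(r1$complete)
  # 90% exactly passes without any mask
  s90 <- paste0(perfectRepeat(90), strrep("N", 10))
  expect_true(isFullyTelomeric(s90, rep(30L, 100), prof0)$complete)
})

test_that("F2a = F2 - F4 and negative differences clamp with a warning", {
  prof <- emptyProfile()
  telo <- perfectRepeat(100)
  # one F4 pair, no F2 pairs
  recs <- pairRecords("only4", telo, randomSeq(100), isize = 300L)
  bam <- samToBam(recs)
  expect_warning(counts <- countPairs(bam, prof), "clamping F2a")
  expect_equal(counts@f4, 1L)
  expect_equal(counts@f2a, 0)
  # normal subtraction
  set.seed(9)
  recs2 <- c(pairRecords("a", perfectRepeat(100, "CCCTAA"),
                         randomSeq(100), pos1 = 100L),
             pairRecords("b", perfectRepeat(100, "CCCTAA"),
                         randomSeq(100), pos1 = 600L),
             pairRecords("c", telo, randomSeq(100), pos1 = 1200L))
  counts2 <- countPairs(samToBam(recs2), prof)
  expect_equal(counts2@f2a, counts2@f2 - counts2@f4)
})

test_that("classification matches generator ground truth with error off", {
  spec <- syntheticSpec(sampleId = "cl1", tlBp = 2000L, nTelomeres = 3L,
                        subtelomereBp = 1200L, coverageX = 20,
                        errorRate = 0, decoyBp = 2000L, seed = 61L)
  smp <- generateSample(spec, withr::local_tempdir())
  tb <- extractTelbam(smp$bam)
  reads <- telotape:::mismatchStats(readTelbam(tb))
  md <- S4Vectors::metadata(reads)
  jm <- buildJointMatrices(reads, seed = 2L)
  prof <- buildErrorMask(jm$X, jm$Y, pMin = md$pMin, pMax = md$pMax)
  cc <- telotape:::readCompleteness(reads, prof)

  ord <- order(reads$qname)
  qn <- reads$qname[ord]
  first <- which(!duplicated(qn))
  i1 <- ord[first]; i2 <- ord[first + 1L]
  got <- telotape:::pairCategory(cc$complete[i1], cc$complete[i2],
                                 cc$orientation[i1], cc$orientation[i2])
  tr <- smp$truth[match(qn[first], smp$truth$qname), ]
  # oracle on pairs without marginal (80-100% but not complete) overlap:
  # interior pairs must be F1, fully non-telomeric pairs F3
  frac <- function(s, e, lo, hi) pmax(0, pmin(e, hi) - pmax(s, lo)) / 100
  lo <- spec@subtelomereBp; hi <- lo + spec@tlBp
  isTelo <- grepl("^telo", tr$construct)
  f1r <- ifelse(isTelo, frac(tr$start, tr$start + 100L, lo, hi), 0)
  f2r <- ifelse(isTelo, frac(tr$start + tr$insert - 100L,
                             tr$start + tr$insert, lo, hi), 0)
  # reads between 70% and 100% telomeric sit in the ambiguous band where
  # chance phase matches of the non-telomeric tail can tip the 90% rule
  clearcut <- (f1r == 1 | f1r <= 0.7) & (f2r == 1 | f2r <= 0.7)
  oracle <- ifelse(f1r == 1 & f2r == 1, "F1",
                   ifelse(f2r == 1, "F2", ifelse(f1r == 1, "F4", "F3")))
  expect_identical(got[clearcut], oracle[clearcut])
  # and the headline case: every interior pair classifies F1
  expect_true(all(got[tr$origin == "f1"] == "F1"))
})

test_that("reverse-complementing reads and swapping mates maps F2 to F4", {
  spec <- syntheticSpec(sampleId = "sym1", tlBp = 1000L, nTelomeres = 0L,
                        itrList = list(c(150, 8)), coverageX = 25,
                        errorRate = 0, decoyBp = 0L, seed = 71L)
  smp <- generateSample(spec, withr::local_tempdir())
  tb <- extractTelbam(smp$bam)
  reads <- readTelbam(tb)
  md <- S4Vectors::metadata(reads)
  prof <- buildErrorProfile(reads, seed = 2L)
  counts <- countPairs(reads, prof)
  flipped <- reads
  flipped$seq <- vapply(reads$seq, oracleRevComp, "")
  flipped$phred <- S4Vectors::revElements(reads$phred,
                                          seq_len(nrow(reads)))
  flipped <- telotape:::mismatchStats(flipped)
  countsF <- suppressWarnings(countPairs(flipped, prof))
  expect_equal(countsF@f2, counts@f4)
  expect_equal(countsF@f4, counts@f2)
  expect_equal(countsF@f1, counts@f1)
  expect_equal(countsF@f3, counts@f3)
})
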