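test_that("capture keeps pairs with >= 2 hexamers on either mate, on either strand", {
  filler <- strrep("ACGTC", 16)  # 80 bp, repeat-free
  recs <- c(
    pairRecords("keep_fwd", paste0("TTAGGGTTAGGG", filler),
                randomSeq(92), pos1 = 100L),
    pairRecords("drop_single", paste0("TTAGGG", filler),
                paste0("TTAGGG", filler), pos1 = 500L),
    # read 2 sequenced CCCTAACCCTAA: stored form carries TTAGGG twice
    pairRecords("keep_rev", randomSeq(92),
                paste0("CCCTAACCCTAA", filler), pos1 = 900L))
  bam <- samToBam(recs)
  tb <- extractTelbam(bam, file.path(dirname(bam), "out.telbam.bam"))
  got <- sort(unique(Rsamtools::scanBam(
    telbamPath(tb),
    param = Rsamtools::ScanBamParam(what = "qname"))[[1]]$qname))
  expect_identical(got, c("keep_fwd", "keep_rev"))
  expect_identical(pairCount(tb), 2L)

  # agrees with the brute-force two-strand scanner on every pair
  src <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "seq")))[[1]]
  keepOracle <- tapply(vapply(as.character(src$seq), oracleIsCandidate,
                              TRUE), src$qname, any)
  expect_setequal(got, names(keepOracle)[keepOracle])
})

test_that("an empty BAM yields an empty TELBAM and zero counts", {
  bam <- samToBam(character(0))
  tb <- extractTelbam(bam, file.path(dirname(bam), "empty.telbam.bam"))
  expect_identical(pairCount(tb), 0L)
  expect_equal(Rsamtools::countBam(telbamPath(tb))$records, 0)
  counts <- countPairs(telbamPath(tb), emptyProfile())
  expect_equal(unname(pairCounts(counts)), c(0, 0, 0, 0, 0))
})

test_that("TELBAM is a subset of the source and extraction is idempotent", {
  spec <- syntheticSpec(sampleId = "sub1", tlBp = 1200L, nTelomeres = 2L,
                        subtelomereBp = 800L, coverageX = 15,
                        decoyBp = 1500L, seed = 41L)
  smp <- generateSample(spec, withr::local_tempdir())
  tb <- extractTelbam(smp$bam)
  key <- function(path) {
    r <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "seq")))[[1]]
    sort(paste(r$qname, bitwAnd(r$flag, 192L), as.character(r$seq)))
  }
  expect_true(all(key(telbamPath(tb)) %in% key(smp$bam)))
  tb2 <- extractTelbam(telbamPath(tb),
                       file.path(dirname(smp$bam), "twice.telbam.bam"))
  expect_identical(key(telbamPath(tb2)), key(telbamPath(tb)))
  expect_identical(pairCount(tb2), pairCount(tb))
})

test_that("single-end input is rejected with a paired-end message", {
  rec <- paste("solo", 0L, "chr1", 100L, 60L, "20M", "*", 0L, 0L,
               perfectRepeat(20), strrep("I", 20), sep = "\t")
  bam <- samToBam(rec)
  expect_error(extractTelbam(bam), "paired-end")
})

test_that("insert-size estimation matches hand-computed moments", {
  filler <- strrep("ACGTC", 16)
  recs <- c(pairRecords("a", filler, filler, isize = 290L),
            pairRecords("b", filler, filler, isize = 300L),
            pairRecords("c", filler, filler, isize = 310L))
  bam <- samToBam(recs)
  m <- estimateInsertSize(bam)
  expect_equal(insertMean(m), 300)
  expect_equal(insertSd(m), sd(c(290, 300, 310)))
  expect_equal(m@nObservations, 3L)
  expect_identical(readLength(m), 80L)

  const <- samToBam(c(pairRecords("a", filler, filler, isize = 300L),
                      pairRecords("b", filler, filler, isize = 300L),
                      pairRecords("c", filler, filler, isize = 300L)))
  mc <- estimateInsertSize(const)
  expect_equal(insertMean(mc), 300)
  expect_equal(insertSd(mc), 0)
})

test_that("insert override is used verbatim; absent data demands one", {
  filler <- strrep("ACGTC", 16)
  bam <- samToBam(pairRecords("a", filler, filler, isize = 300L))
  m <- estimateInsertSize(bam, override = c(350, 25))
  expect_equal(insertMean(m), 350)
  expect_equal(insertSd(m), 25)
  expect_identical(m@nObservations, 0L)
  empty <- samToBam(character(0))
  expect_error(estimateInsertSize(empty), "--insert-mean")
})

test_that("reads load in sequenced orientation", {
  telo <- perfectRepeat(60)
  recs <- pairRecords("p", randomSeq(60), telo, isize = 200L,
                      q2 = paste(rep("5", 60), collapse = ""))
  bam <- samToBam(recs)
  reads <- readTelbam(bam)
  r2 <- reads[bitwAnd(reads$flag, 128L) > 0L, ]
  expect_identical(r2$seq, telo)   # undoes the reference-forward storage
  expect_identical(unique(unlist(r2$phred)), 20L)   # "5" - 33
})
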