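test_that("read counts land in bins by leftmost position and are conserved", {
  dir <- withr::local_tempdir()
  ref <- writeRefFasta(list(chrT = refSequence(2000)), dir)
  # 3 primary reads at 10, 500, 1500 plus excluded records
  reads <- rbind(simpleReads("chrT", c(10L, 500L, 1500L)),
                 simpleReads("chrT", 700L, flag = 256L),   # secondary
                 simpleReads("chrT", 800L, flag = 1024L))  # duplicate
  bam <- writeBam(reads, list(chrT = 2000L), dir)
  prof <- binReadCounts(bam, ref, binSize = 1000L)
  b <- bins(prof)
  expect_equal(length(b), 2L)
  expect_equal(b$rd, c(2, 1))
  # conservation: counts sum to the number of retained alignments
  expect_equal(sum(b$rd_raw), 3)
  expect_equal(binSize(prof), 1000L)
  expect_true(all(b$gc >= 0 & b$gc <= 1))
})

test_that("uniform 10x coverage yields ~100 read starts per kb bin", {
  dir <- withr::local_tempdir()
  ref <- writeRefFasta(list(chrU = refSequence(5000)), dir)
  # one 100 bp read every 10 bp: exactly 100 starts per interior kb
  reads <- simpleReads("chrU", seq(1L, 4901L, by = 10L))
  bam <- writeBam(reads, list(chrU = 5000L), dir)
  prof <- binReadCounts(bam, ref, binSize = 1000L)
  expect_equal(bins(prof)$rd, c(100, 100, 100, 100, 91))
})

test_that("degenerate alignments raise actionable errors", {
  dir <- withr::local_tempdir()
  ref <- writeRefFasta(list(chrT = refSequence(2000)), dir)
  # empty alignment
  bam0 <- writeBam(simpleReads("chrT", integer(0)), list(chrT = 2000L), dir)
  expect_error(binReadCounts(bam0, ref, 1000L), "no mapped reads")
  # missing index
  bam <- writeBam(simpleReads("chrT", c(10L, 500L)), list(chrT = 2000L), dir)
  file.remove(paste0(bam, ".bai"))
  expect_error(binReadCounts(bam, ref, 1000L), "index")
  # contig in the alignment header but absent from the reference
  dir2 <- withr::local_tempdir()
  bam2 <- writeBam(simpleReads("chrT", c(10L, 500L)),
                   list(chrT = 2000L, chrGhost = 1000L), dir2)
  expect_error(binReadCounts(bam2, ref, 1000L), "chrGhost")
})

test_that("N-dominated bins are masked and excluded from the mean RD", {
  dir <- withr::local_tempdir()
  # 10 kb contig with bins 3-5 (1-based) fully N
  ref <- writeRefFasta(list(chrN = refSequence(10000, nRun = 2001:5000)), dir)
  reads <- simpleReads("chrN", seq(1L, 9901L, by = 100L))  # 10 per bin
  bam <- writeBam(reads, list(chrN = 10000L), dir)
  prof <- binReadCounts(bam, ref, binSize = 1000L)
  m <- maskNBins(prof, nFracThreshold = 0.5)
  expect_equal(bins(m)$masked, c(FALSE, FALSE, TRUE, TRUE, TRUE,
                                 rep(FALSE, 5)))
  # mean over the 7 unmasked bins, hand computed
  expect_equal(meanRD(m), mean(bins(prof)$rd[-(3:5)]))
  # idempotent
  expect_identical(bins(maskNBins(m, 0.5))$masked, bins(m)$masked)
  # threshold 1.0 disables masking; fully-N bin has n_frac = 1 > no bins
  expect_false(any(bins(maskNBins(prof, 1.0))$masked))
  # fill-with-mean alternative leaves nothing masked
  f <- maskNBins(prof, 0.5, fill = "mean")
  expect_false(any(bins(f)$masked))
  expect_equal(bins(f)$rd[3], mean(bins(prof)$rd[-(3:5)]))
})

test_that("meanRD is the mean over unmasked bins and rejects zero profiles", {
  p <- makeProfile(c(5, 7.5, 10, 17.5))
  expect_equal(meanRD(p), 10)
  expect_equal(meanRD(makeProfile(10)), 10)
  expect_error(meanRD(makeProfile(rep(0, 4))), "not positive")
  pm <- makeProfile(c(1, 2, 100), masked = c(FALSE, FALSE, TRUE))
  expect_equal(meanRD(pm), 1.5)
})

test_that("GC correction rescales strata to the global median", {
  # two strata with medians 80 and 120; global median 100
  rd <- c(rep(80, 25), rep(120, 25))
  gc <- c(rep(0.305, 25), rep(0.605, 25))
  p <- correctGCBias(makeProfile(rd, gc = gc), minStratumBins = 20L)
  expect_equal(bins(p)$rd, rep(100, 50))   # 80*1.25, 120*0.8333...
  # identical rd everywhere -> identity
  p2 <- correctGCBias(makeProfile(rep(7, 60), gc = runif(60)),
                      minStratumBins = 5L)
  expect_equal(bins(p2)$rd, rep(7, 60))
  # global median is preserved
  set.seed(3)
  rd3 <- rpois(400, 100); gc3 <- runif(400, 0.3, 0.6)
  p3 <- correctGCBias(makeProfile(rd3, gc = gc3), minStratumBins = 10L)
  expect_equal(median(bins(p3)$rd), median(rd3), tolerance = 0.01)
  # masked bins untouched, all-masked errors
  pm <- makeProfile(c(80, 80, 120), masked = c(FALSE, FALSE, TRUE))
  expect_equal(bins(correctGCBias(pm, 1L))$rd[3], 120)
  pall <- makeProfile(c(1, 2), masked = c(TRUE, TRUE))
  expect_error(correctGCBias(pall), "masked")
})

test_that("GC correction removes an injected sinusoidal coverage bias", {
  sim <- simulateProfile(simConfig(0.5, nBins = 5000, gcBiasAmplitude = 0.2,
                                   segments = data.frame(startBin = integer(0),
                                                         endBin = integer(0),
                                                         cn = integer(0)),
                                   seed = 4))
  before <- abs(cor(bins(sim$profile)$rd, bins(sim$profile)$gc))
  corr <- correctGCBias(sim$profile)
  after <- abs(cor(bins(corr)$rd, bins(corr)$gc))
  expect_gt(before, 0.5)     # the bias is real before correction
  expect_lt(after, before)
  expect_lt(after, 0.1)
})

test_that("profile TSV round-trips through write/read", {
  p <- makeProfile(c(5, 7.5, 10), gc = c(0.3, 0.4, 0.5),
                   masked = c(FALSE, TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRDProfile(p, path)
  q <- readRDProfile(path)
  expect_equal(bins(q)$rd, bins(p)$rd)
  expect_equal(bins(q)$masked, bins(p)$masked)
  expect_equal(start(bins(q)), start(bins(p)))
  # coordinates are written as plain integers
  expect_false(any(grepl("e\\+", readLines(path))))
})
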