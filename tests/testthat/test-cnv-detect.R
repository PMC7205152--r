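# isolation forest ----------------------------------------------------------

test_that("forest respects its configuration and is deterministic", {
  set.seed(1)
  rd <- rpois(2000, 100)
  f <- buildIsolationForest(rd, nTrees = 64L, subsample = 128L, seed = 7)
  expect_length(f$trees, 64L)
  expect_true(all(lengths(f$samples) == 128L))
  s1 <- anomalyScores(f, rd)
  f2 <- buildIsolationForest(rd, nTrees = 64L, subsample = 128L, seed = 7)
  expect_identical(s1, anomalyScores(f2, rd))
  expect_true(all(s1 > 0 & s1 < 1))
  # subsample larger than the profile is reduced with a warning
  expect_warning(buildIsolationForest(rd[1:50], subsample = 256L, seed = 1),
                 "reducing subsample")
})

test_that("identical read depths give one-leaf trees with equal scores", {
  f <- buildIsolationForest(rep(5, 500), nTrees = 16L, subsample = 64L,
                            seed = 2)
  s <- anomalyScores(f, rep(5, 10))
  expect_true(all(s == s[1]))
  expect_equal(s[1], 0.5)   # E[h] equals the normalizer exactly
})

test_that("an extreme read depth scores above the bulk", {
  set.seed(5)
  rd <- c(rpois(999, 100), 1000)
  f <- buildIsolationForest(rd, seed = 6)
  s <- anomalyScores(f, rd)
  expect_gt(s[1000], max(s[1:999]))
})

test_that("fast interval scoring matches a tree-by-tree path walk", {
  set.seed(8)
  rd <- c(rpois(46, 50), 0, 200, 120, 5)   # 50-bin toy profile
  f <- buildIsolationForest(rd, nTrees = 32L, subsample = 32L, seed = 9)
  expect_equal(anomalyScores(f, rd), forestScoreOracle(f, rd),
               tolerance = 1e-12)
})

# total-variation denoising --------------------------------------------------

test_that("TV denoising handles the identity and flat limits", {
  s <- c(0, 0, 0, 1, 1, 1)
  expect_identical(tvDenoise(s, 0), s)
  expect_equal(tvDenoise(s, 1000), rep(mean(s), 6))
  expect_error(tvDenoise(s, -1), "non-negative")
  expect_equal(tvDenoise(5, 3), 5)     # single point
})

test_that("TV solution matches a dual projected-gradient oracle", {
  s <- c(0, 0, 0, 1, 1, 1)
  expect_equal(tvDenoise(s, 0.2), tvOracle(s, 0.2), tolerance = 1e-6)
  # levels pulled together by lam / (segment length)
  expect_equal(tvDenoise(s, 0.2), rep(c(0.2 / 3, 1 - 0.2 / 3), each = 3),
               tolerance = 1e-10)
  set.seed(11)
  for (rep in 1:5) {
    y <- rnorm(40)
    for (lam in c(0.05, 0.3, 1.5))
      expect_equal(tvDenoise(y, lam), tvOracle(y, lam), tolerance = 1e-5)
  }
})

test_that("TV never increases total variation and splits by chromosome", {
  set.seed(12)
  for (rep in 1:10) {
    y <- rnorm(200) + rep(c(0, 3, 0), c(80, 40, 80))
    lam <- runif(1, 0, 2)
    expect_lte(totalVariation(tvDenoise(y, lam)), totalVariation(y) + 1e-12)
  }
  y <- rnorm(60)
  chrom <- rep(c("c1", "c2"), each = 30)
  split2 <- c(tvDenoise(y[1:30], 0.4), tvDenoise(y[31:60], 0.4))
  expect_equal(tvDenoise(y, 0.4, chrom = chrom), split2)
})

# Gamma significance test ----------------------------------------------------

test_that("Gamma tail test is calibrated on Gamma-distributed scores", {
  set.seed(13)
  x <- rgamma(10000, shape = 5, scale = 0.08)
  gt <- gammaTest(x, level = 0.01)
  # binomial 99% interval around 100 expected calls
  expect_gt(sum(gt$call), 100 - 2.58 * sqrt(10000 * 0.01 * 0.99))
  expect_lt(sum(gt$call), 100 + 2.58 * sqrt(10000 * 0.01 * 0.99))
  expect_true(all(gt$pvalue >= 0 & gt$pvalue <= 1))
  # level 0 calls nothing; zero variance warns and calls nothing
  expect_equal(sum(gammaTest(x, level = 0)$call), 0L)
  expect_warning(gt0 <- gammaTest(rep(1, 100)), "zero-variance")
  expect_equal(sum(gt0$call), 0L)
})

test_that("a planted run of high scores is called in full", {
  set.seed(14)
  x <- rgamma(10000, shape = 5, scale = 0.08)
  hot <- 4001:4020
  x[hot] <- mean(x) + 8 * sd(x)       # >= 5 SD effect
  gt <- gammaTest(x, level = 0.01)
  expect_true(all(gt$call[hot]))
})

# merging and external calls -------------------------------------------------

test_that("flagged bins merge into maximal directional runs", {
  p <- makeProfile(c(5, 5, 12, 5), binSize = 1000L)
  reg <- mergeCalls(c(TRUE, TRUE, FALSE, TRUE), p, rBar = 10)
  expect_length(reg, 2L)
  expect_equal(start(reg), c(1L, 3001L))
  expect_equal(end(reg), c(2000L, 4000L))
  expect_equal(reg$direction, c("loss", "loss"))
  expect_equal(reg$observed_rd, c(5, 5))
  expect_equal(reg$n_bins, c(2L, 1L))
  # no flags -> empty; a run crossing a chromosome boundary splits
  expect_length(mergeCalls(rep(FALSE, 4), p, rBar = 10), 0L)
  p2 <- makeProfile(c(5, 5, 5, 5), chrom = rep(c("c1", "c2"), each = 2))
  expect_length(mergeCalls(rep(TRUE, 4), p2, rBar = 10), 2L)
  # gain direction, and a region at exactly rBar is dropped with a warning
  expect_equal(mergeCalls(c(FALSE, FALSE, TRUE, FALSE), p, rBar = 10)$direction,
               "gain")
  expect_warning(r0 <- mergeCalls(c(TRUE, FALSE, FALSE, FALSE), p, rBar = 5),
                 "equal to rBar")
  expect_length(r0, 0L)
})

test_that("external BED calls acquire RDs from unmasked bins", {
  rd <- c(rep(5, 5), rep(10, 5))
  p <- makeProfile(rd, chrom = rep("chr21", 10), binSize = 1000L)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr21\t1000\t5000", bed)
  reg <- loadExternalCalls(bed, p, rBar = 10)
  expect_length(reg, 1L)
  expect_equal(reg$direction, "loss")
  expect_equal(reg$observed_rd, 5)
  # the 4th column can force direction
  writeLines("chr21\t1000\t5000\tgain", bed)
  expect_equal(loadExternalCalls(bed, p, rBar = 10)$direction, "gain")
  # empty file -> empty result
  writeLines(character(0), bed)
  expect_length(loadExternalCalls(bed, p, rBar = 10), 0L)
  # malformed line -> error naming the line
  writeLines(c("chr21\t0\t2000", "chr21\toops"), bed)
  expect_error(loadExternalCalls(bed, p, rBar = 10), "line 2")
})

test_that("regions spanning masked bins use unmasked RDs only", {
  rd <- c(4, 4, 99, 6, 10, 10)
  p <- makeProfile(rd, masked = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrT\t0\t4000", bed)
  reg <- loadExternalCalls(bed, p, rBar = 10)
  expect_equal(reg$observed_rd, mean(c(4, 4, 6)))  # masked bin excluded
  expect_equal(reg$n_bins, 3L)
  # a region living entirely in masked space is skipped with a warning
  writeLines("chrT\t2000\t3000", bed)
  expect_warning(r <- loadExternalCalls(bed, p, rBar = 10), "no unmasked bin")
  expect_length(r, 0L)
})

# end-to-end detection -------------------------------------------------------

test_that("planted segments are detected with controlled false calls", {
  segs <- data.frame(startBin = c(500L, 2000L, 3500L),
                     endBin = c(560L, 2080L, 3540L),
                     cn = c(0L, 5L, 1L))
  sim <- simulateProfile(simConfig(0.6, nBins = 5000, segments = segs,
                                   seed = 21))
  det <- detectCNV(sim$profile, level = 0.01, seed = 22)
  segBins <- unlist(mapply(function(s, e) (s + 1L):e,
                           segs$startBin, segs$endBin))
  called <- which(det$scores$call)
  sens <- mean(segBins %in% called)
  fp <- length(setdiff(called, segBins)) / (5000 - length(segBins))
  expect_gte(sens, 0.9)
  expect_lte(fp, 2 * 0.01)
  # determinism: same seed, identical regions
  det2 <- detectCNV(sim$profile, level = 0.01, seed = 22)
  expect_identical(as.data.frame(det$regions), as.data.frame(det2$regions))
})
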