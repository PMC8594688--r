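.twoSampleSe <- function(m1, t1, m2, t2, pos = 100L) {
  layout <- genomeLayout("chr1", 10000)
  s1 <- makeMethylome(pos, m1, t1, id = "a1", layout = layout)
  s2 <- makeMethylome(pos, m2, t2, id = "b1", layout = layout)
  buildTiles(list(s1, s2), layout)
}

test_that("tile grid arithmetic is half-open on 500-bp boundaries", {
  layout <- genomeLayout("chr1", 10000)
  # 0-based 600 (= 1-based 601) lands in tile [500,1000)
  m <- makeMethylome(601, 5, 10, layout = layout)
  se <- buildTiles(list(m, m), layout)  # same sample twice to satisfy groups
  rr <- SummarizedExperiment::rowRanges(se)
  expect_equal(start(rr), 501L); expect_equal(end(rr), 1000L)
  # 0-based 499 and 500 fall in different tiles
  m2 <- makeMethylome(c(500, 501), c(5, 5), c(10, 10), layout = layout)
  se2 <- buildTiles(list(m2), layout)
  expect_equal(length(SummarizedExperiment::rowRanges(se2)), 2L)
})

test_that("coverage gates exclude tiles lacking per-sample or group depth", {
  layout <- genomeLayout("chr1", 2000)
  s1 <- makeMethylome(c(100, 700), c(5, 5), c(10, 10), id = "a1",
                      layout = layout)
  s2 <- makeMethylome(100, 5, 10, id = "b1", layout = layout)  # no tile-2 depth
  se <- buildTiles(list(s1, s2), layout)
  res <- testTiles(se, "a1", "b1")
  expect_equal(length(res), 1L)
  expect_equal(S4Vectors::metadata(res)$nExcluded, 1L)
})

test_that("likelihood-ratio test matches closed-form and dbinom oracles", {
  res <- testTiles(.twoSampleSe(80, 100, 20, 100), "a1", "b1")
  # 2*(80 log .8 + 20 log .2)*... computed by hand from the binomial
  # log-likelihoods: 2*(2*(80*log(0.8) + 20*log(0.2)) - 200*log(0.5))
  expect_equal(mcols(res)$lrt, 77.0979028, tolerance = 1e-8)
  expect_equal(mcols(res)$lrt, bruteLrt(80, 100, 20, 100), tolerance = 1e-9)
  expect_equal(mcols(res)$diff, 60)
  expect_equal(mcols(res)$direction, "gain")

  same <- testTiles(.twoSampleSe(40, 100, 40, 100), "a1", "b1")
  expect_equal(mcols(same)$lrt, 0)
  expect_equal(mcols(same)$p, 1)
  expect_equal(mcols(same)$diff, 0)

  extreme <- testTiles(.twoSampleSe(100, 100, 0, 100), "a1", "b1")
  expect_equal(mcols(extreme)$diff, 100)
  expect_equal(mcols(extreme)$lrt, 2 * 200 * log(2), tolerance = 1e-9)
  expect_lt(mcols(extreme)$p, 1e-20)

  set.seed(17)
  for (i in 1:20) {
    t1 <- sample(10:60, 1); t2 <- sample(10:60, 1)
    m1 <- rbinom(1, t1, runif(1)); m2 <- rbinom(1, t2, runif(1))
    got <- testTiles(.twoSampleSe(m1, t1, m2, t2), "a1", "b1")
    expect_equal(mcols(got)$lrt, bruteLrt(m1, t1, m2, t2), tolerance = 1e-8)
  }
})

test_that("swapping group labels negates the difference and preserves p", {
  se <- .twoSampleSe(70, 90, 30, 80)
  a <- testTiles(se, "a1", "b1"); b <- testTiles(se, "b1", "a1")
  expect_equal(mcols(a)$diff, -mcols(b)$diff)
  expect_equal(mcols(a)$p, mcols(b)$p)
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(adjustQ(0.04), 0.04)
  expect_equal(adjustQ(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustQ(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.01, 0.04, 0.9)
  expect_true(all(diff(adjustQ(p)[order(p)] / 1) >= 0))  # monotone in rank
  expect_true(all(adjustQ(p, "pi0") <= adjustQ(p)))
})

test_that("DMR calling uses strict cutoffs and gain/loss partition the whole set", {
  gr <- GRanges("chr1", IRanges(c(1, 501, 1001, 1501), width = 500),
                p = c(1e-4, 1e-4, 1e-4, 0.5),
                diff = c(6, 5, -8, 20))
  mcols(gr)$q <- c(0.005, 0.005, 0.005, 0.6)
  d <- callDmrs(gr, qCutoff = 0.01, diffCutoff = 5)
  expect_equal(length(d$whole), 2L)          # diff = +5.0 excluded (strict)
  expect_equal(start(d$gain), 1L)
  expect_equal(start(d$loss), 1001L)
  expect_equal(length(d$gain) + length(d$loss), length(d$whole))
  expect_error(callDmrs(granges(gr), 0.01), "q-values")
})

test_that("planted tile differences are recovered by the group comparison", {
  layout <- genomeLayout("chr1", 2e6)
  tiles <- GRanges("chr1", IRanges(seq(500001, 500001 + 19 * 500, 500),
                                   width = 500),
                   levelGroup1 = 0.75, levelGroup2 = 0.45, seqinfo = layout)
  des <- simulationDesign(layout, coverageMean = 20,
                          plantedDmrTiles = tiles, nSamplesPerGroup = 3L,
                          seed = 77L)
  sim <- simulateMethylomes(des)
  ids <- names(sim$samples)
  se <- buildTiles(sim$samples, layout)
  res <- adjustQ(testTiles(se, ids[1:3], ids[4:6]))
  d <- callDmrs(res, 0.01, 5)
  hits <- countOverlaps(tiles, d$gain) > 0
  expect_gte(mean(hits), 0.8)  # recall of 30-point differences
})
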