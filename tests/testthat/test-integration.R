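test_that("global comparison over common loci handles identity and symmetry", {
  m1 <- makeMethylome(c(100, 200, 300), c(5, 6, 7), 10, id = "a1")
  same <- globalMethylationTest(list(m1), list(m1))
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  # differences +0.1 and -0.1 -> t = 0
  a <- makeMethylome(c(100, 200), c(6, 5), 10, id = "a1")
  b <- makeMethylome(c(100, 200), c(5, 6), 10, id = "b1")
  sym <- globalMethylationTest(list(a), list(b))
  expect_equal(sym$t, 0, tolerance = 1e-12)
  expect_equal(sym$meanDiff, 0)

  few <- makeMethylome(100, 5, 10)
  expect_error(globalMethylationTest(list(few), list(few)), "common CpG")
})

test_that("a planted global methylation shift is detected by the paired t-test", {
  layout <- genomeLayout("chr1", 1e6)
  desHi <- simulationDesign(layout, baselineMeth = 0.80,
                            nSamplesPerGroup = 1L, seed = 3L)
  desLo <- simulationDesign(layout, baselineMeth = 0.75,
                            nSamplesPerGroup = 1L, seed = 3L)
  hi <- simulateMethylomes(desHi)$samples
  lo <- simulateMethylomes(desLo)$samples
  res <- globalMethylationTest(hi, lo)
  expect_lt(res$p, 1e-10)
  expect_gt(res$nLoci, 5000)
  expect_true(res$meanDiff > 0.03 && res$meanDiff < 0.07)
})

test_that("fold enrichment behaves at the identity, nesting and null cases", {
  genome <- 1e6
  feats <- GRanges("chr1", IRanges(1001, 2000))
  whole <- GRanges("chr1", IRanges(1, genome))
  expect_equal(elementFoldEnrichment(feats, whole, genome), 1)
  # feature entirely inside an element covering 10% of the genome
  elem <- GRanges("chr1", IRanges(1, genome / 10))
  inner <- GRanges("chr1", IRanges(5001, 6000))
  expect_equal(elementFoldEnrichment(inner, elem, genome), 10)
  expect_equal(elementFoldEnrichment(inner,
                                     GRanges("chr1", IRanges(9e5, 9.5e5)),
                                     genome), 0)
  expect_error(elementFoldEnrichment(GRanges(), elem, genome), "empty")

  # scale invariance: doubling all coordinates leaves the fold unchanged
  f2 <- GRanges("chr1", IRanges(10001, 12000))
  e2 <- GRanges("chr1", IRanges(1, 2 * genome / 10))
  expect_equal(elementFoldEnrichment(inner, elem, genome),
               elementFoldEnrichment(f2, e2, 2 * genome))
})

test_that("random features show no fold enrichment in random elements", {
  set.seed(91)
  folds <- vapply(1:10, function(i) {
    f <- GRanges("chr1", IRanges(sample(9.9e5, 2000), width = 300))
    e <- GRanges("chr1", IRanges(sample(9.9e5, 2000), width = 300))
    elementFoldEnrichment(f, e, 1e6)
  }, 1.0)
  expect_lt(abs(mean(folds) - 1), 0.1)
})

test_that("Fisher overlap matches brute-force enumeration and edge cases", {
  set.seed(51)
  for (i in 1:25) {
    nT <- sampleOne(20:500)
    nA <- sampleOne(1:nT); nB <- sampleOne(1:nT)
    nS <- sampleOne(max(0, nA + nB - nT):min(nA, nB))
    got <- overlapFisher(nT, nA, nB, nS)
    expect_equal(got$p, bruteHyperUpper(nS, nA, nT - nA, nB),
                 tolerance = 1e-10, info = paste(nT, nA, nB, nS))
  }
  # expected overlap sits in the central mass
  ex <- overlapFisher(10000, 1000, 800, 80)
  expect_true(ex$p > 0.3 && ex$p < 0.7)
  # every draw a success
  expect_equal(overlapFisher(100, 100, 30, 30)$p, 1)
  expect_error(overlapFisher(100, 10, 10, 11), "margins")
})

test_that("gain-vs-loss comparison uses exact small-sample enumeration", {
  same <- gainLossComparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  res <- gainLossComparison(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$method, "exact")
  expect_equal(res$p, 0.1)  # 2/20 orderings as extreme, two-sided
  expect_error(gainLossComparison(c(1, NA), c(2, 3)), "NA")
  big <- gainLossComparison(rnorm(30) + 2, rnorm(30))
  expect_equal(big$method, "normal approximation")
  expect_lt(big$p, 0.05)
})

test_that("candidate gene table joins concordant gain DMRs to suggestive SNPs", {
  layout <- genomeLayout("chr1", 2e6)
  tiles <- GRanges("chr1", IRanges(c(99501, 500001), width = 500),
                   seqinfo = layout)
  mkRes <- function(q, diff) {
    gr <- tiles
    mcols(gr) <- DataFrame(p = q / 2, q = q, diff = diff)
    gr
  }
  # gene with promoter covering the first tile: gene on + at 100001,
  # promoter [98001, 100000] with promoterBp = 2000
  genes <- GRanges("chr1", IRanges(100001, 120000), strand = "+",
                   seqinfo = layout)
  mcols(genes)$gene_id <- "geneA"
  mcols(genes)$tss <- 100001L
  snp <- function(pos, t2) {
    gr <- GRanges("chr1", IRanges(pos, width = 1), seqinfo = layout)
    mcols(gr) <- DataFrame(trait = "scr", b = sqrt(t2), se = 1, t2 = t2)
    gr
  }
  strongT2 <- qchisq(1e-7, 1, lower.tail = FALSE)
  age <- mkRes(c(0.001, 0.5), c(10, 1))
  scr <- mkRes(c(0.005, 0.5), c(8, 1))
  tab <- candidateGeneTable(age, scr, genes, list(scr = snp(150000, strongT2)))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$gene_id, "geneA")
  expect_equal(tab$trait, "scr")
  expect_lt(tab$topSnpP, 1e-6)

  # weaker SNP: p = 1e-4 fails the strict 1e-5 threshold
  weakT2 <- qchisq(1e-4, 1, lower.tail = FALSE)
  expect_equal(nrow(candidateGeneTable(age, scr, genes,
                                       list(scr = snp(150000, weakT2)))), 0L)
  # no shared significant DMRs
  null <- mkRes(c(0.5, 0.5), c(1, 1))
  expect_equal(nrow(candidateGeneTable(null, null, genes,
                                       list(scr = snp(150000, strongT2)))), 0L)
  # loss in one comparison: excluded by the gain-gain filter
  lossScr <- mkRes(c(0.005, 0.5), c(-8, 1))
  expect_equal(nrow(candidateGeneTable(age, lossScr, genes,
                                       list(scr = snp(150000, strongT2)))), 0L)
})
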