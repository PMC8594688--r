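test_that("CpG call reader applies the coverage filter and keeps 1-based positions", {
  # empty file
  p <- writeCallsFile(data.frame())
  expect_equal(length(readCpGCalls(p)), 0L)

  rows <- data.frame(chrom = "chr1", pos = c(101L, 201L),
                     nMeth = c(3L, 1L), nUnmeth = c(1L, 1L))
  expect_equal(length(readCpGCalls(writeCallsFile(rows), minCoverage = 5)), 0L)

  rows2 <- data.frame(chrom = "chr1", pos = c(101L, 201L),
                      nMeth = c(4L, 9L), nUnmeth = c(1L, 1L))
  m <- readCpGCalls(writeCallsFile(rows2), minCoverage = 5)
  expect_equal(start(calls(m)), c(101L, 201L))  # BED half-open: 100 and 200
  expect_equal(methLevels(m), c(0.8, 0.9))

  # minCoverage = 1 retains every well-formed row
  set.seed(1)
  rows3 <- data.frame(chrom = "chr1", pos = sort(sample(1e5, 50)),
                      nMeth = rbinom(50, 5, 0.5), nUnmeth = 1L)
  expect_equal(length(readCpGCalls(writeCallsFile(rows3), minCoverage = 1)), 50L)
})

test_that("CpG call reader accepts the 6-column Bismark dialect and rejects malformed rows", {
  p6 <- tempfile(fileext = ".cov")
  writeLines(c("chr1\t101\t101\t80.0\t4\t1", "chr1\t201\t201\t90.0\t9\t1"), p6)
  m <- readCpGCalls(p6, minCoverage = 5)
  expect_equal(methLevels(m), c(0.8, 0.9))

  bad <- tempfile(); writeLines(c("chr1\t101\t4\t1", "chr1\tx\t3\t1"), bad)
  expect_error(readCpGCalls(bad), "line 2")
  neg <- writeCallsFile(data.frame(chrom = "chr1", pos = 10L,
                                   nMeth = -1L, nUnmeth = 3L))
  expect_error(readCpGCalls(neg), "negative")
})

test_that("GWAS reader recomputes t2 and sorts by layout order", {
  layout <- genomeLayout(c("chr2", "chr1"), c(5e5, 1e6))  # chr2 first
  p <- tempfile()
  writeLines(c("tr\tchr1\t100\t0\t1", "tr\tchr2\t50\t2\t0.5"), p)
  gw <- readGwasStats(p, layout)
  expect_equal(as.character(seqnames(gw)), c("chr2", "chr1"))
  expect_equal(mcols(gw)$t2, c(16, 0))

  bad <- tempfile(); writeLines("tr\tchr1\t100\t1\t0", bad)
  expect_error(readGwasStats(bad, layout), "positive")
})

test_that("interval merge handles overlap and half-open adjacency", {
  expect_equal(length(mergeIntervals(GRanges())), 0L)
  # [0,100) + [50,150) -> [0,150);  [0,100) + [100,200) abut -> [0,200)
  g <- GRanges("chr1", IRanges(c(1, 51), c(100, 150)))
  expect_equal(width(mergeIntervals(g)), 150L)
  g2 <- GRanges("chr1", IRanges(c(1, 101), c(100, 200)))
  m2 <- mergeIntervals(g2)
  expect_equal(length(m2), 1L)
  expect_equal(c(start(m2), end(m2)), c(1L, 200L))

  layout <- tinyLayout()
  tooFar <- suppressWarnings(
    GRanges("chr1", IRanges(999990, 1000010), seqinfo = layout))
  expect_error(mergeIntervals(tooFar), "beyond")
})

test_that("base-pair intersection matches hand enumeration and its bounds", {
  a <- GRanges("chr1", IRanges(1, 100))
  expect_equal(intersectBp(a, GRanges()), 0)
  expect_equal(intersectBp(a, GRanges("chr1", IRanges(51, 150))), 50)
  # {[0,10),[20,30)} vs {[5,25)} -> 5 + 5 = 10
  x <- GRanges("chr1", IRanges(c(1, 21), c(10, 30)))
  y <- GRanges("chr1", IRanges(6, 25))
  expect_equal(intersectBp(x, y), 10)
  expect_equal(intersectBp(y, x), 10)
  expect_equal(intersectBp(x, x), totalBp(x))
  set.seed(7)
  for (i in 1:20) {
    r1 <- GRanges("chr1", IRanges(sample(1e4, 5), width = sample(500, 5)))
    r2 <- GRanges("chr1", IRanges(sample(1e4, 5), width = sample(500, 5)))
    expect_lte(intersectBp(r1, r2), min(totalBp(r1), totalBp(r2)))
  }
  inner <- GRanges("chr1", IRanges(11, 60))
  outer <- GRanges("chr1", IRanges(1, 100))
  expect_equal(intersectBp(inner, outer), totalBp(inner))
})

test_that("BED round trip reproduces a merged interval set exactly", {
  set.seed(11)
  layout <- tinyLayout()
  gr <- mergeIntervals(GRanges("chr1",
                               IRanges(sample(9e5, 20), width = sample(1000, 20)),
                               seqinfo = layout))
  path <- tempfile(fileext = ".bed")
  writeBedIntervals(gr, path)
  back <- readBedIntervals(path, layout)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(as.character(seqnames(back)), as.character(seqnames(gr)))
})

test_that("interval set comparison counts shared members per input set", {
  a <- GRanges("chr1", IRanges(c(1, 201), c(100, 300)))
  cmpSelf <- compareIntervalSets(a, a)
  expect_equal(cmpSelf$sharedA, 2L); expect_equal(cmpSelf$aSpecific, 0L)
  b <- GRanges("chr1", IRanges(501, 600))
  cmpDisj <- compareIntervalSets(a, b)
  expect_equal(cmpDisj$sharedA, 0L); expect_equal(cmpDisj$bSpecific, 1L)
  # a={[0,100)}, b={[90,200),[300,400)}
  x <- GRanges("chr1", IRanges(1, 100))
  y <- GRanges("chr1", IRanges(c(91, 301), c(200, 400)))
  cmp <- compareIntervalSets(x, y)
  expect_equal(cmp$sharedA, 1L); expect_equal(cmp$sharedB, 1L)
  expect_equal(cmp$aSpecific, 0L); expect_equal(cmp$bSpecific, 1L)
})
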