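test_that("window binarization pools counts and applies a strict threshold", {
  layout <- tinyLayout(c(chr1 = 100000, chr2 = 40000))
  # window 1 of chr1: CpGs 9/10 and 8/10 -> 17/20 = 0.85 -> symbol 1
  # window 2: pooled exactly 0.60 -> symbol 0 (strict >)
  m <- makeMethylome(c(1000, 2000, 21000, 22000), c(9, 8, 6, 6),
                     c(10, 10, 10, 10), layout = layout)
  tr <- binarizeWindows(m, pmdParams(), layout)
  w1 <- tr[seqnames(tr) == "chr1"]
  expect_equal(mcols(w1)$level[1], 0.85)
  expect_equal(mcols(w1)$symbol[1:2], c(1L, 0L))
  # chromosome with no CpGs: all windows missing
  expect_true(all(is.na(mcols(tr[seqnames(tr) == "chr2"])$symbol)))
})

.trackFromSymbols <- function(sym, window = 20000L) {
  layout <- genomeLayout("chr1", length(sym) * window)
  tiles <- GenomicRanges::tileGenome(seqlengths(layout), tilewidth = window,
                                     cut.last.tile.in.chrom = TRUE)
  mcols(tiles) <- DataFrame(level = ifelse(is.na(sym), NA_real_,
                                           ifelse(sym == 1L, 0.8, 0.4)),
                            symbol = as.integer(sym))
  tiles
}

test_that("HMM decoding finds contiguous low-methylation window runs", {
  expect_equal(length(decodePmdStates(.trackFromSymbols(rep(1L, 10)))), 0L)

  got <- decodePmdStates(.trackFromSymbols(c(1, 1, 0, 0, 0, 0, 1, 1)))
  expect_equal(length(got), 1L)
  expect_equal(start(got), 2L * 20000L + 1L)  # windows 3-6
  expect_equal(end(got), 6L * 20000L)
  expect_equal(width(got), 80000L)

  # isolated 0 shorter than minWindows
  lone <- decodePmdStates(.trackFromSymbols(c(1, 0, 1, 1, 1, 1, 1, 1)))
  expect_equal(length(lone), 0L)
})

test_that("missing windows are skipped without breaking domain runs", {
  got <- decodePmdStates(.trackFromSymbols(c(1, 1, 0, 0, NA, 0, 0, 1, 1)))
  expect_equal(length(got), 1L)
  expect_equal(width(got), 5L * 20000L)
})

test_that("Viterbi decoding equals exhaustive path enumeration", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    sym <- sample(c(0L, 1L), n, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (sample(3, 1) == 1L) sym[sample(n, 1)] <- NA
    if (length(unique(sym[!is.na(sym)])) < 2L) next
    par <- methylomeGWAS:::.hmmFit(sym, 100L, 1e-6)
    states <- methylomeGWAS:::.hmmViterbi(sym, par)
    oracle <- brutePaths(sym, par$eB, par$eP, par$A, par$start)
    # the decoded path attains the exhaustive maximum likelihood
    emit <- function(st, s) {
      if (is.na(s)) 1
      else if (st == 1L) (if (s == 1L) par$eB else 1 - par$eB)
      else (if (s == 0L) par$eP else 1 - par$eP)
    }
    lp <- log(par$start[states[1]]) + log(emit(states[1], sym[1]))
    for (t in 2:n) lp <- lp + log(par$A[states[t - 1], states[t]]) +
      log(emit(states[t], sym[t]))
    expect_equal(lp, oracle$logp, tolerance = 1e-9)
  }
})

test_that("consensus keeps >=3-sample cores spanning >=3 windows", {
  w <- 20000L
  layout <- genomeLayout("chr1", 40L * w)
  mk <- function(s, e) GRanges("chr1", IRanges(s, e), seqinfo = layout)
  pmd <- mk(5L * w + 1L, 10L * w)

  # identical PMD in 3 of 6 samples -> kept as-is
  per <- list(pmd, pmd, pmd, mk(30L * w + 1L, 33L * w), GRanges(seqinfo = layout),
              GRanges(seqinfo = layout))
  cons <- consensusPmds(per, pmdParams(), layout)
  expect_equal(start(cons), start(pmd)); expect_equal(end(cons), end(pmd))

  # present in only 2 samples -> dropped
  per2 <- list(pmd, pmd, GRanges(seqinfo = layout), GRanges(seqinfo = layout),
               GRanges(seqinfo = layout), GRanges(seqinfo = layout))
  expect_equal(length(consensusPmds(per2, pmdParams(), layout)), 0L)

  # staggered overlaps whose 3-sample core spans only 2 windows -> dropped
  per3 <- list(mk(1L, 4L * w), mk(2L * w + 1L, 8L * w), mk(2L * w + 1L, 6L * w),
               GRanges(seqinfo = layout), GRanges(seqinfo = layout),
               GRanges(seqinfo = layout))
  # depth >= 3 core: [2w, 4w) = 2 windows
  expect_equal(length(consensusPmds(per3, pmdParams(), layout)), 0L)

  expect_error(consensusPmds(per[1:2], pmdParams(), layout), "minSupport")
})

test_that("planted partially methylated domains are recovered with high fidelity", {
  w <- 20000L
  layout <- genomeLayout("chr1", 2e6)
  planted <- GRanges("chr1", IRanges(c(10L * w + 1L, 60L * w + 1L), width = 5L * w),
                     level = 0.40, seqinfo = layout)
  des <- simulationDesign(layout, plantedPmds = planted,
                          nSamplesPerGroup = 3L, seed = 55L)
  sim <- simulateMethylomes(des)
  per <- lapply(sim$samples, function(s) {
    g <- calls(s)
    decodePmdStates(binarizeWindows(Methylome(sampleId(s),
                                              g[mcols(g)$nTotal >= 5L]),
                                    pmdParams(), layout))
  })
  cons <- suppressMessages(consensusPmds(per, pmdParams(), layout))
  expect_true(all(width(cons) >= 3L * w))
  recall <- intersectBp(cons, planted) / totalBp(planted)
  precision <- intersectBp(cons, planted) / totalBp(cons)
  expect_gte(recall, 0.9); expect_gte(precision, 0.9)
})
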