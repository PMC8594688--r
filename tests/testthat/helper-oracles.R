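# Shared fixtures and independent oracles, deliberately written with plain
# loops so they share no code path with the package implementation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

tinyLayout <- function(lens = c(chr1 = 1e6, chr2 = 5e5)) {
  genomeLayout(names(lens), unname(lens))
}

makeMethylome <- function(pos, meth, total, chrom = "chr1", id = "s1",
                          layout = NULL, ageGroup = "none") {
  gr <- GRanges(chrom, IRanges(pos, width = 1L),
                nMeth = as.integer(meth), nTotal = as.integer(total))
  if (!is.null(layout)) {
    seqlevels(gr) <- seqlevels(layout)
    seqinfo(gr) <- layout
  }
  Methylome(id, gr, ageGroup = ageGroup)
}

writeCallsFile <- function(rows) {
  # rows: data.frame chrom, pos (1-based), nMeth, nUnmeth
  path <- tempfile(fileext = ".tsv")
  if (nrow(rows) == 0) file.create(path)
  else write.table(rows, path, sep = "\t", row.names = FALSE,
                   col.names = FALSE, quote = FALSE)
  path
}

# Brute-force HMR scan: literal reading of the sliding-window rule over
# every window placement, quadratic and loop-based.
bruteHmrSpans <- function(pos0, hypo, chromLen, window = 200L, step = 50L,
                         hypoFraction = 0.8, minCpgs = 5L) {
  okSpan <- function(a, b) {
    sel <- pos0 >= a & pos0 < b
    n <- sum(sel)
    n >= 1 && sum(hypo[sel]) >= hypoFraction * n
  }
  spans <- list()
  for (s in seq(0L, max(0L, chromLen - 1L), by = step)) {
    e <- min(s + window, chromLen)
    if (e <= s || !okSpan(s, e)) next
    repeat {
      e2 <- min(e + step, chromLen)
      if (e2 == e || !okSpan(s, e2)) break
      e <- e2
    }
    sel <- pos0 >= s & pos0 < e & hypo
    h <- pos0[sel]
    spans[[length(spans) + 1L]] <- c(h[1], h[length(h)] + 1)
  }
  if (!length(spans)) return(IRanges())
  ir <- reduce(IRanges(vapply(spans, `[`, 0, 1) + 1,
                       vapply(spans, `[`, 0, 2)))
  keep <- vapply(seq_along(ir), function(i) {
    sum(pos0 + 1 >= start(ir)[i] & pos0 + 1 <= end(ir)[i]) >= minCpgs
  }, TRUE)
  ir[keep]
}

# Exhaustive most-likely-path decoder for the 2-state Bernoulli HMM:
# enumerates all 2^n state paths. States: 1 = background, 2 = PMD.
brutePaths <- function(sym, eB, eP, A, start) {
  n <- length(sym)
  emit <- function(state, s) {
    if (is.na(s)) return(1)
    if (state == 1L) { if (s == 1L) eB else 1 - eB }
    else { if (s == 0L) eP else 1 - eP }
  }
  best <- -Inf; bestPaths <- list()
  for (code in 0:(2^n - 1)) {
    path <- as.integer(intToBits(code))[1:n] + 1L
    lp <- log(start[path[1]]) + log(emit(path[1], sym[1]))
    if (n > 1) for (t in 2:n) {
      lp <- lp + log(A[path[t - 1], path[t]]) + log(emit(path[t], sym[t]))
    }
    if (lp > best + 1e-12) { best <- lp; bestPaths <- list(path) }
    else if (abs(lp - best) <= 1e-12) bestPaths <- c(bestPaths, list(path))
  }
  list(logp = best, paths = bestPaths)
}

# Exhaustive upper-tail hypergeometric via log-binomial sums (no phyper).
bruteHyperUpper <- function(q, nWhite, nBlack, k) {
  kk <- max(q, 0):min(k, nWhite)
  if (!length(kk) || q > min(k, nWhite)) return(if (q <= 0) 1 else 0)
  terms <- lchoose(nWhite, kk) + lchoose(nBlack, k - kk) -
    lchoose(nWhite + nBlack, k)
  sum(exp(terms))
}

# Direct binomial log-likelihood LRT via dbinom (oracle for testTiles).
bruteLrt <- function(m1, t1, m2, t2) {
  ll <- function(m, t, p) dbinom(m, t, p, log = TRUE)
  p1 <- m1 / t1; p2 <- m2 / t2; p0 <- (m1 + m2) / (t1 + t2)
  2 * (ll(m1, t1, p1) + ll(m2, t2, p2) - ll(m1, t1, p0) - ll(m2, t2, p0))
}

# sample() treats a length-1 numeric as 1:n; always draw from a vector.
sampleOne <- function(v) v[sample.int(length(v), 1L)]

# Base-level Jaccard between two interval sets.
jaccardBp <- function(a, b) {
  i <- intersectBp(a, b)
  u <- totalBp(a) + totalBp(b) - i
  if (u == 0) 1 else i / u
}
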