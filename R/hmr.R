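# Hypomethylated-region (HMR) detection: 200-bp seed windows slid at 50-bp
# resolution, extended in 50-bp steps while >= 80% of the covered CpGs in
# the whole span stay below the 20% methylation level.

#' Pool a group of methylomes into one count track
#'
#' Per-position sums of methylated and total counts across samples; the
#' position set is the union. Pooling is commutative, so the result does
#' not depend on sample order. Group-level segmentation (one HMR set per
#' animal group) runs on the pooled track.
#'
#' @param samples non-empty list of [Methylome-class] objects.
#' @param sampleId identifier for the pooled pseudo-sample.
#' @return a [Methylome-class] with summed counts.
#' @export
poolGroup <- function(samples, sampleId = "pooled") {
  if (!length(samples)) stop("cannot pool an empty group")
  if (length(samples) == 1L) return(samples[[1L]])
  grs <- lapply(samples, calls)
  all <- do.call(c, unname(lapply(grs, granges)))
  key <- paste(seqnames(all), start(all))
  nMeth <- rowsum(unlist(lapply(grs, function(g) as.numeric(mcols(g)$nMeth))),
                  key, reorder = FALSE)
  nTotal <- rowsum(unlist(lapply(grs, function(g) as.numeric(mcols(g)$nTotal))),
                   key, reorder = FALSE)
  uniq <- !duplicated(key)
  gr <- all[uniq]
  mcols(gr) <- DataFrame(nMeth = as.integer(nMeth[match(key[uniq], rownames(nMeth)), 1L]),
                         nTotal = as.integer(nTotal[match(key[uniq], rownames(nTotal)), 1L]))
  Methylome(sampleId, gr)
}

# Detect HMR spans on one chromosome. pos: sorted 0-based CpG positions,
# hypo: logical, chromLen in bp. Returns matrix of 0-based half-open spans.
.hmrSpansOneChrom <- function(pos, hypo, chromLen, window, step,
                              hypoFraction) {
  nHypoLe <- cumsum(hypo)                # counts over pos index
  countIn <- function(a, b) {            # CpGs with a <= pos < b
    hi <- findInterval(b - 1L, pos); lo <- findInterval(a - 1L, pos)
    c(n = hi - lo, h = (if (hi) nHypoLe[hi] else 0L) -
        (if (lo) nHypoLe[lo] else 0L))
  }
  ok <- function(a, b) {
    cnt <- countIn(a, b)
    cnt[["n"]] >= 1L && cnt[["h"]] >= hypoFraction * cnt[["n"]]
  }
  hp <- pos[hypo]
  if (!length(hp)) return(matrix(numeric(), ncol = 2L))
  # candidate seed starts: step-grid windows containing >= 1 hypomethylated CpG
  starts <- unique(unlist(lapply(hp, function(q) {
    s <- seq(step * ceiling((q - window + 1L) / step), step * (q %/% step),
             by = step)
    s[s >= 0L]                           # windows past the end are clipped
  })))
  starts <- sort(starts)
  spans <- matrix(numeric(), ncol = 2L)
  for (s in starts) {
    e <- min(s + window, chromLen)
    if (!ok(s, e)) next
    repeat {
      e2 <- min(e + step, chromLen)
      if (e2 == e || !ok(s, e2)) break
      e <- e2
    }
    spans <- rbind(spans, c(s, e))
  }
  if (!nrow(spans)) return(spans)
  # trim to outermost hypomethylated CpGs so boundaries are data-supported
  t(apply(spans, 1L, function(se) {
    inside <- hp[hp >= se[1L] & hp < se[2L]]
    c(inside[1L], inside[length(inside)] + 1L)
  }))
}

#' Detect hypomethylated regions on a pooled methylome
#'
#' A CpG is hypomethylated when its pooled level is strictly below
#' `hypoLevel`. Any 200-bp window on the 50-bp grid whose covered CpGs are
#' at least `hypoFraction` hypomethylated (and >= 1) seeds a region; the
#' region grows rightward in 50-bp steps while the criterion holds over the
#' whole extended span (the failing step is not included; leftward growth
#' is captured by seeds starting further left). Accepted spans are trimmed
#' to their outermost hypomethylated CpGs, merged, and kept when they
#' contain at least `minCpgs` covered CpGs.
#'
#' @param pooled a [Methylome-class], typically from [poolGroup()].
#' @param params an [HmrParams-class]; CpGs below `minCoverage` pooled
#'   reads are dropped before segmentation.
#' @return a sorted `GRanges` with metadata columns `nCpgs` and
#'   `meanLevel` (pooled counts within the region).
#' @export
detectHmrs <- function(pooled, params = hmrParams()) {
  gr <- calls(pooled)
  gr <- gr[mcols(gr)$nTotal >= params@minCoverage]
  if (!length(gr)) {
    out <- GRanges(seqinfo = seqinfo(gr))
    mcols(out) <- DataFrame(nCpgs = integer(), meanLevel = numeric())
    return(out)
  }
  lens <- seqlengths(gr)
  out <- list()
  for (chr in unique(as.character(seqnames(gr)))) {
    g <- gr[seqnames(gr) == chr]
    pos <- start(g) - 1L                       # 0-based
    lev <- mcols(g)$nMeth / mcols(g)$nTotal
    hypo <- lev < params@hypoLevel
    chromLen <- lens[[chr]]
    if (is.na(chromLen)) chromLen <- max(pos) + 1L
    spans <- .hmrSpansOneChrom(pos, hypo, chromLen, params@window,
                               params@step, params@hypoFraction)
    if (!nrow(spans)) next
    sp <- reduce(IRanges(spans[, 1L] + 1L, spans[, 2L]))  # to 1-based closed
    idx <- findOverlaps(IRanges(pos + 1L, width = 1L), sp)
    nC <- tabulate(subjectHits(idx), length(sp))
    keep <- nC >= params@minCpgs
    if (!any(keep)) next
    sp <- sp[keep]
    idx <- findOverlaps(IRanges(pos + 1L, width = 1L), sp)
    mSum <- rowsum(as.numeric(mcols(g)$nMeth[queryHits(idx)]),
                   subjectHits(idx))
    tSum <- rowsum(as.numeric(mcols(g)$nTotal[queryHits(idx)]),
                   subjectHits(idx))
    out[[chr]] <- GRanges(chr, sp, nCpgs = nC[keep],
                          meanLevel = as.numeric(mSum / tSum))
  }
  if (!length(out)) {
    res <- GRanges()
    mcols(res) <- DataFrame(nCpgs = integer(), meanLevel = numeric())
  } else {
    res <- do.call(c, unname(out))
  }
  seqlevels(res) <- seqlevels(gr)
  seqinfo(res) <- seqinfo(gr)
  GenomicRanges::sort(res, ignore.strand = TRUE)
}
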