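# Tile-based differential methylation: 500-bp genome tiles, per-tile
# binomial logistic regression (two-group likelihood-ratio test in closed
# form), Benjamini-Hochberg adjustment, and gain/loss DMR calling.

#' Summarize methylomes over genome tiles
#'
#' Tiles every chromosome into non-overlapping windows (500 bp by default)
#' and sums each sample's methylated and total counts within each tile;
#' `unit = "cpg"` instead keeps one unit per CpG position (for
#' differentially methylated cytosines). Only units with coverage in at
#' least one sample are kept; the per-sample and per-group coverage gates
#' are applied at test time, when the groups are known.
#'
#' @param samples list of [Methylome-class] objects.
#' @param layout a `Seqinfo` (chromosomes must cover all calls).
#' @param unit `"tile500"` or `"cpg"`.
#' @param tileWidth tile width in bp for `unit = "tile500"`.
#' @return a [SummarizedExperiment::RangedSummarizedExperiment] with assays
#'   `meth` and `total` (units x samples) and the sample identifiers and
#'   group labels in `colData`.
#' @export
buildTiles <- function(samples, layout, unit = c("tile500", "cpg"),
                       tileWidth = 500L) {
  unit <- match.arg(unit)
  grs <- lapply(samples, calls)
  for (g in grs)
    if (!all(as.character(seqnames(g)) %in% seqlevels(layout)))
      stop("sample calls on chromosomes absent from layout")
  if (unit == "tile500") {
    units <- GenomicRanges::tileGenome(seqlengths(layout),
                                       tilewidth = as.integer(tileWidth),
                                       cut.last.tile.in.chrom = TRUE)
  } else {
    all <- unique(do.call(c, lapply(grs, function(g) {
      g2 <- granges(g); seqlevels(g2) <- seqlevels(layout)
      seqinfo(g2) <- layout; g2
    })))
    units <- GenomicRanges::sort(all, ignore.strand = TRUE)
  }
  meth <- matrix(0, length(units), length(samples))
  total <- matrix(0, length(units), length(samples))
  for (j in seq_along(grs)) {
    g <- grs[[j]]
    hits <- findOverlaps(g, units, ignore.strand = TRUE)
    if (!length(hits)) next
    mm <- rowsum(as.numeric(mcols(g)$nMeth[queryHits(hits)]), subjectHits(hits))
    tt <- rowsum(as.numeric(mcols(g)$nTotal[queryHits(hits)]), subjectHits(hits))
    ix <- as.integer(rownames(mm))
    meth[ix, j] <- mm[, 1L]; total[ix, j] <- tt[, 1L]
  }
  covered <- rowSums(total) > 0
  ids <- vapply(samples, sampleId, character(1))
  colnames(meth) <- colnames(total) <- ids
  SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth[covered, , drop = FALSE],
                  total = total[covered, , drop = FALSE]),
    rowRanges = units[covered],
    colData = DataFrame(sampleId = ids,
                        ageGroup = vapply(samples, function(s) s@ageGroup, ""),
                        scrGroup = vapply(samples, function(s) s@scrGroup, "")))
}

.binomLogLik <- function(m, t, p) {
  # log-likelihood of pooled binomial counts; 0*log(0) treated as 0
  term <- function(k, lp) ifelse(k == 0, 0, k * lp)
  term(m, log(p)) + term(t - m, log1p(-p))
}

#' Test tiles for group methylation differences
#'
#' Per unit, fits the binomial logistic regression
#' `logit(pi_j) = b0 + b1 * g_j` over samples `j` and tests `b1 = 0` by a
#' one-degree likelihood-ratio chi-square. With a binary group covariate
#' the alternative model's maximum likelihood is attained at the pooled
#' group proportions, so both fits are computed in closed form from pooled
#' counts. The methylation difference is the difference of pooled group
#' proportions in percentage points (group 1 minus group 2); its sign
#' defines the direction (`gain` when group 1 is higher).
#'
#' @param se tile table from [buildTiles()].
#' @param group1Ids,group2Ids sample identifiers of the two groups.
#' @param minPerSample a unit is tested only if every sample has at least
#'   this total count (default 1).
#' @param minGroupCoverage minimum pooled total count per group (default 10).
#' @return a `GRanges` of tested units with metadata columns `p`, `diff`
#'   (percentage points) and `direction`; the number of excluded units is
#'   in `metadata(result)$nExcluded`.
#' @export
testTiles <- function(se, group1Ids, group2Ids, minPerSample = 1L,
                      minGroupCoverage = 10L) {
  ids <- colnames(SummarizedExperiment::assay(se, "meth"))
  if (!length(group1Ids) || !length(group2Ids))
    stop("both groups must be non-empty")
  if (!all(c(group1Ids, group2Ids) %in% ids))
    stop("unknown sample identifiers")
  meth <- SummarizedExperiment::assay(se, "meth")
  total <- SummarizedExperiment::assay(se, "total")
  g1 <- match(group1Ids, ids); g2 <- match(group2Ids, ids)
  use <- c(g1, g2)
  ok <- rowSums(total[, use, drop = FALSE] >= minPerSample) == length(use)
  m1 <- rowSums(meth[, g1, drop = FALSE]); t1 <- rowSums(total[, g1, drop = FALSE])
  m2 <- rowSums(meth[, g2, drop = FALSE]); t2 <- rowSums(total[, g2, drop = FALSE])
  ok <- ok & t1 >= minGroupCoverage & t2 >= minGroupCoverage
  nExcluded <- sum(!ok)
  m1 <- m1[ok]; t1 <- t1[ok]; m2 <- m2[ok]; t2 <- t2[ok]
  p1 <- m1 / t1; p2 <- m2 / t2; p0 <- (m1 + m2) / (t1 + t2)
  l1 <- .binomLogLik(m1, t1, p1) + .binomLogLik(m2, t2, p2)
  l0 <- .binomLogLik(m1 + m2, t1 + t2, p0)
  lrt <- pmax(0, 2 * (l1 - l0))
  p <- pchisq(lrt, df = 1L, lower.tail = FALSE)
  diff <- 100 * (p1 - p2)
  out <- SummarizedExperiment::rowRanges(se)[ok]
  mcols(out) <- DataFrame(p = p, lrt = lrt, diff = diff,
                          direction = ifelse(diff >= 0, "gain", "loss"),
                          meth1 = m1, total1 = t1, meth2 = m2, total2 = t2)
  S4Vectors::metadata(out)$nExcluded <- nExcluded
  out
}

#' Adjust tile p-values for multiple testing
#'
#' Benjamini-Hochberg step-up q-values over the tested units, optionally
#' rescaled by a Storey-type null-proportion estimate
#' (`pi0 = min(1, mean(p > 0.5) / 0.5)`), a lighter stand-in for adaptive
#' q-value estimators.
#'
#' @param p numeric p-values in `(0, 1]`, or a `GRanges` with a `p` column
#'   (the q-values are then appended as a `q` column).
#' @param method `"BH"` (default) or `"pi0"` for the rescaled variant.
#' @return q-values in the same shape as the input.
#' @export
adjustQ <- function(p, method = c("BH", "pi0")) {
  method <- match.arg(method)
  if (is(p, "GRanges")) {
    mcols(p)$q <- adjustQ(mcols(p)$p, method)
    return(p)
  }
  q <- p.adjust(p, method = "BH")
  if (method == "pi0" && length(p)) {
    pi0 <- min(1, mean(p > 0.5) / 0.5)
    q <- pmin(1, q * pi0)
  }
  q
}

#' Call differentially methylated regions
#'
#' A unit is a DMR when `q < qCutoff` and `|diff| > diffCutoff` percentage
#' points (both strict). The gain and loss subsets partition the whole set
#' by the sign of the difference.
#'
#' @param results `GRanges` from [testTiles()] with a `q` column (see
#'   [adjustQ()]).
#' @param qCutoff q-value cutoff (e.g. 0.05, 0.01, 1e-5, 1e-8, 1e-10).
#' @param diffCutoff methylation-difference cutoff in percentage points
#'   (default 5).
#' @return a list of `GRanges`: `whole`, `gain` (`diff > +diffCutoff`) and
#'   `loss` (`diff < -diffCutoff`).
#' @export
callDmrs <- function(results, qCutoff, diffCutoff = 5) {
  if (is.null(mcols(results)$q)) stop("results lack q-values; run adjustQ()")
  q <- mcols(results)$q; d <- mcols(results)$diff
  whole <- results[q < qCutoff & abs(d) > diffCutoff]
  list(whole = whole,
       gain = whole[mcols(whole)$diff > diffCutoff],
       loss = whole[mcols(whole)$diff < -diffCutoff])
}
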