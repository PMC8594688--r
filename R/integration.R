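# Cross-cutting analyses: global group comparison over common CpG loci,
# fold enrichment of features across genomic elements, Fisher overlap of
# two DMR sets on a shared tile universe, gain-vs-loss rank comparison,
# and the candidate-gene table joining DMRs to GWAS hits.

#' Global methylation comparison between two groups
#'
#' Restricts to the CpG loci covered (at `minCoverage` or more reads) in
#' every sample of both groups, computes each group's pooled level per
#' locus, and runs a t-test across loci on the per-locus level differences
#' (paired by default; set `paired = FALSE` for the two-sample variant).
#'
#' @param groupA,groupB lists of [Methylome-class] objects.
#' @param minCoverage per-sample coverage for a locus to count (default 5).
#' @param paired paired across loci (default) or two-sample.
#' @return list with `t`, `p`, `meanDiff` (A minus B, in level fraction)
#'   and `nLoci`.
#' @export
globalMethylationTest <- function(groupA, groupB, minCoverage = 5L,
                                  paired = TRUE) {
  keyLevels <- function(samples) {
    grs <- lapply(samples, calls)
    keys <- lapply(grs, function(g) {
      g <- g[mcols(g)$nTotal >= minCoverage]
      paste(seqnames(g), start(g))
    })
    list(grs = grs, keys = keys)
  }
  a <- keyLevels(groupA); b <- keyLevels(groupB)
  common <- Reduce(intersect, c(a$keys, b$keys))
  if (length(common) < 2L) stop("fewer than 2 common CpG loci")
  pooledLevel <- function(grs) {
    m <- 0; t <- 0
    for (g in grs) {
      ix <- match(common, paste(seqnames(g), start(g)))
      m <- m + as.numeric(mcols(g)$nMeth[ix])
      t <- t + as.numeric(mcols(g)$nTotal[ix])
    }
    m / t
  }
  la <- pooledLevel(a$grs); lb <- pooledLevel(b$grs)
  d <- la - lb
  if (paired && stats::sd(d) == 0) {
    # degenerate but well-defined: identical groups give t = 0, p = 1
    tt <- list(statistic = c(t = if (mean(d) == 0) 0 else Inf),
               p.value = if (mean(d) == 0) 1 else 0)
  } else if (paired) {
    tt <- t.test(d)
  } else {
    tt <- t.test(la, lb)
  }
  list(t = unname(tt$statistic), p = tt$p.value, meanDiff = mean(d),
       nLoci = length(common))
}

#' Fold enrichment of a feature set across a genomic element
#'
#' `fold = (overlap_bp / feature_bp) / (element_bp / genome_bp)`: how much
#' more of the feature set lies in the element than expected from the
#' element's genome share. 1 means no enrichment, 0 no overlap.
#'
#' @param features,elements `GRanges` (merged internally).
#' @param genomeBp total genome length in bp.
#' @return a single fold value.
#' @export
elementFoldEnrichment <- function(features, elements, genomeBp) {
  fb <- totalBp(features)
  if (fb == 0) stop("empty feature set")
  eb <- totalBp(elements)
  if (eb == 0) return(0)
  (intersectBp(features, elements) / fb) / (eb / genomeBp)
}

#' Fisher overlap of two DMR sets on a common tile universe
#'
#' One-sided (enrichment) Fisher exact test that `nShared` of the
#' `nTotal` commonly tested tiles being called in both comparisons is more
#' than expected: the upper hypergeometric tail `P(X >= nShared)` with
#' `nA` successes in the population and `nB` draws, computed in log space.
#'
#' @param nTotal commonly tested tiles.
#' @param nA,nB DMR counts of the two sets.
#' @param nShared tiles called in both.
#' @return a list: the four inputs, `expected` (`nA * nB / nTotal`), `p`
#'   and `log10p`.
#' @export
overlapFisher <- function(nTotal, nA, nB, nShared) {
  if (nShared > min(nA, nB) || nA + nB - nShared > nTotal ||
      any(c(nTotal, nA, nB, nShared) < 0))
    stop("inconsistent overlap margins")
  tail <- .hyperUpperTail(nShared, nA, nTotal - nA, nB)
  list(nTotal = nTotal, nA = nA, nB = nB, nShared = nShared,
       expected = nA * nB / nTotal, p = tail$p, log10p = tail$log10p)
}

#' Compare gain- and loss-DMR enrichment values
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum comparison of two panels of
#' enrichment values (e.g. -log10 empirical p across traits and q-value
#' cutoffs for DMRs that gained vs lost methylation). Exact enumeration
#' when both panels have at most 10 untied values, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param gain,loss numeric vectors (no NAs).
#' @return list with `W`, `p`, `method`.
#' @export
gainLossComparison <- function(gain, loss) {
  if (!length(gain) || !length(loss)) stop("empty enrichment vector")
  if (anyNA(gain) || anyNA(loss)) stop("NA in enrichment values")
  ties <- anyDuplicated(c(gain, loss)) > 0L
  exact <- length(gain) <= 10L && length(loss) <= 10L && !ties
  wt <- suppressWarnings(wilcox.test(gain, loss, exact = exact,
                                     correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

# p-value of a variant from its squared t-statistic (chi-square, 1 df)
.snpP <- function(t2) pchisq(t2, df = 1L, lower.tail = FALSE)

#' Candidate genes bearing concordant DMRs and suggestive GWAS hits
#'
#' Joins the two differential comparisons (e.g. aged vs young and low vs
#' high sire conception rate) on their shared tile universe, keeps tiles
#' significant in both (`q < qCutoff`, `|diff| > diffCutoff`) that gained
#' methylation in both, assigns them to genes whose gene body or promoter
#' (`promoterBp` upstream of the TSS, strand-aware) overlaps the tile, and
#' reports each gene-trait pair whose most significant variant within the
#' gene span extended by `snpWindowBp` passes `topSnpP < snpThreshold`.
#' Each row carries the gene's most significant DMR (smallest first-
#' comparison q).
#'
#' @param ageResults,scrResults `GRanges` from [testTiles()]+[adjustQ()]
#'   sharing one tile universe.
#' @param genes gene `GRanges` with `gene_id`, `tss`, strand.
#' @param gwasByTrait named list of variant `GRanges`.
#' @param qCutoff,diffCutoff DMR thresholds (defaults 0.01, 5).
#' @param snpThreshold suggestive-significance threshold (default 1e-5).
#' @param promoterBp promoter extent upstream of the TSS (default 2000).
#' @param snpWindowBp variant search window around the gene (default
#'   250000).
#' @return a `data.frame`: `gene_id`, `chrom`, `dmrStart`, `dmrEnd`,
#'   `qAge`, `diffAge`, `qScr`, `diffScr`, `trait`, `topSnpPos`, `topSnpP`.
#' @export
candidateGeneTable <- function(ageResults, scrResults, genes, gwasByTrait,
                               qCutoff = 0.01, diffCutoff = 5,
                               snpThreshold = 1e-5, promoterBp = 2000L,
                               snpWindowBp = 250000L) {
  key <- function(gr) paste(seqnames(gr), start(gr), end(gr))
  ix <- match(key(ageResults), key(scrResults))
  shared <- which(!is.na(ix))
  a <- ageResults[shared]; s <- scrResults[ix[shared]]
  sig <- mcols(a)$q < qCutoff & abs(mcols(a)$diff) > diffCutoff &
    mcols(s)$q < qCutoff & abs(mcols(s)$diff) > diffCutoff
  gg <- sig & mcols(a)$diff > diffCutoff & mcols(s)$diff > diffCutoff
  a <- a[gg]; s <- s[gg]
  empty <- data.frame(gene_id = character(), chrom = character(),
                      dmrStart = integer(), dmrEnd = integer(),
                      qAge = numeric(), diffAge = numeric(),
                      qScr = numeric(), diffScr = numeric(),
                      trait = character(), topSnpPos = integer(),
                      topSnpP = numeric())
  if (!length(a)) return(empty)
  # gene body plus strand-aware promoter
  prom <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(genes, upstream = promoterBp,
                             downstream = 0L)))
  body <- granges(genes)
  hits <- BiocGenerics::union(findOverlaps(a, body, ignore.strand = TRUE),
                              findOverlaps(a, prom, ignore.strand = TRUE))
  if (!length(hits)) return(empty)
  rows <- list()
  for (gi in unique(subjectHits(hits))) {
    ti <- queryHits(hits)[subjectHits(hits) == gi]
    best <- ti[which.min(mcols(a)$q[ti])]
    g <- genes[gi]
    lo <- max(1L, start(g) - snpWindowBp)
    hi <- end(g) + snpWindowBp
    win <- GRanges(seqnames(g), IRanges(lo, hi))
    for (tr in names(gwasByTrait)) {
      vars <- gwasByTrait[[tr]]
      if (is.null(vars)) { warning("missing trait table: ", tr); next }
      inWin <- subsetByOverlaps(vars, win, ignore.strand = TRUE)
      if (!length(inWin)) next
      pv <- .snpP(mcols(inWin)$t2)
      top <- which.min(pv)
      if (pv[top] < snpThreshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = mcols(g)$gene_id, chrom = as.character(seqnames(a)[best]),
          dmrStart = start(a)[best], dmrEnd = end(a)[best],
          qAge = mcols(a)$q[best], diffAge = mcols(a)$diff[best],
          qScr = mcols(s)$q[best], diffScr = mcols(s)$diff[best],
          trait = tr, topSnpPos = start(inWin)[top], topSnpP = pv[top])
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$dmrStart, out$gene_id, out$trait), ,
      drop = FALSE]
}
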