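# Synthetic methylomes, GWAS statistics and annotations with planted,
# recoverable ground truth. All randomness flows from a single integer seed.

.rtruncCount <- function(n, mu, size = Inf) {
  # count distribution truncated at >= 1 (every simulated CpG is observed)
  if (is.finite(size)) {
    p0 <- stats::pnbinom(0, size = size, mu = mu)
    stats::qnbinom(runif(n, p0, 1), size = size, mu = mu)
  } else {
    stats::qpois(runif(n, ppois(0, mu), 1), mu)
  }
}

.drawPositions <- function(len, spacingMean) {
  # geometric gaps (>= 1 bp) with mean spacingMean
  n <- max(16L, ceiling(len / spacingMean * 1.3) + 50L)
  pos <- cumsum(1L + rgeom(n, 1 / spacingMean))
  while (pos[length(pos)] <= len) {
    pos <- c(pos, pos[length(pos)] +
               cumsum(1L + rgeom(n, 1 / spacingMean)))
  }
  pos[pos <= len]
}

#' Simulate a group-structured set of sperm methylomes
#'
#' Draws CpG positions with geometric spacing (denser, CpG-island-like
#' spacing inside planted hypomethylated blocks), then per CpG and sample a
#' truncated-Poisson read depth and a binomial methylated count whose
#' success probability is the baseline level or, inside a planted feature,
#' that feature's level: hypomethylated blocks and partially methylated
#' domains apply to every sample; differential tiles take a group-specific
#' level. Two groups are generated (labelled `aged` / `young`), each of
#' `nSamplesPerGroup` samples.
#'
#' @param design a [SimulationDesign-class].
#' @return a list with `samples` (list of [Methylome-class]) and `truth`,
#'   the planted record: `hmrIntervals`, `pmdIntervals`, `dmrTiles` (with
#'   the true per-group levels and difference sign) and the group
#'   assignment. The truth is stored exactly as planted; recovery scoring
#'   is always against this record.
#' @export
simulateMethylomes <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  validObject(design)
  set.seed(design@seed)
  layout <- design@layout
  chroms <- seqlevels(layout)
  pos <- lapply(seqlengths(layout)[chroms], .drawPositions,
                spacingMean = design@cpgSpacingMean)
  posGR <- GRanges(rep(chroms, lengths(pos)),
                   IRanges(unlist(pos, use.names = FALSE), width = 1L),
                   seqinfo = layout)
  if (length(design@plantedHmrs)) {
    # hypomethylated blocks carry CpG-island-like density
    dense <- lapply(seq_along(design@plantedHmrs), function(i) {
      f <- design@plantedHmrs[i]
      p <- start(f) - 1L + cumsum(1L + rgeom(
        ceiling(width(f) / design@cpgSpacingHmr * 1.5) + 20L,
        1 / design@cpgSpacingHmr))
      GRanges(seqnames(f), IRanges(p[p <= end(f)], width = 1L),
              seqinfo = layout)
    })
    posGR <- GenomicRanges::sort(unique(c(posGR, do.call(c, dense))),
                                 ignore.strand = TRUE)
  }

  base1 <- rep(design@baselineMeth, length(posGR))
  base2 <- base1
  assignLevel <- function(lv1, lv2, feats, col1, col2) {
    if (!length(feats)) return(list(lv1, lv2))
    seqlevels(feats) <- seqlevels(layout)
    seqinfo(feats) <- layout
    ov <- findOverlaps(posGR, feats, ignore.strand = TRUE)
    lv1[queryHits(ov)] <- mcols(feats)[[col1]][subjectHits(ov)]
    lv2[queryHits(ov)] <- mcols(feats)[[col2]][subjectHits(ov)]
    list(lv1, lv2)
  }
  tmp <- assignLevel(base1, base2, design@plantedHmrs, "level", "level")
  tmp <- assignLevel(tmp[[1]], tmp[[2]], design@plantedPmds, "level", "level")
  tmp <- assignLevel(tmp[[1]], tmp[[2]], design@plantedDmrTiles,
                     "levelGroup1", "levelGroup2")
  groupLevel <- list(tmp[[1]], tmp[[2]])

  nPer <- design@nSamplesPerGroup
  groups <- rep(1:2, each = nPer)
  ages <- c("aged", "young")[groups]
  samples <- vector("list", length(groups))
  for (j in seq_along(groups)) {
    lv <- groupLevel[[groups[j]]]
    nTotal <- .rtruncCount(length(posGR), design@coverageMean,
                           design@coverageDispersion)
    nMeth <- rbinom(length(posGR), nTotal, lv)
    gr <- posGR
    mcols(gr) <- DataFrame(nMeth = as.integer(nMeth),
                           nTotal = as.integer(nTotal))
    samples[[j]] <- Methylome(sprintf("sim%02d", j), gr, ageGroup = ages[j])
  }
  names(samples) <- vapply(samples, sampleId, character(1))
  truth <- list(hmrIntervals = design@plantedHmrs,
                pmdIntervals = design@plantedPmds,
                dmrTiles = design@plantedDmrTiles,
                groups = setNames(ages, names(samples)))
  list(samples = samples, truth = truth)
}

#' Simulate GWAS summary statistics with planted signal regions
#'
#' Variant positions are uniform over the genome. The t-statistic is
#' standard normal outside the enriched intervals and `Normal(delta, 1)`
#' inside, entering the summary statistics directly as `b = t`, `se = 1`
#' (the enrichment test consumes only `t^2`, so this is the minimal
#' faithful structure).
#'
#' @param layout a `Seqinfo`.
#' @param nVariants number of variants (>= 1).
#' @param enrichedIntervals `GRanges` of signal regions (may be empty).
#' @param delta noncentrality of the t-statistic inside the regions (>= 0).
#' @param seed integer seed.
#' @param trait trait label attached to every variant.
#' @return a list with `stats` (sorted `GRanges` with `trait`, `b`, `se`,
#'   `t2`) and `truth` (the enriched intervals as planted).
#' @export
simulateGwas <- function(layout, nVariants, enrichedIntervals = GRanges(),
                         delta = 0, seed = 1L, trait = "trait1") {
  if (nVariants < 1L) stop("nVariants must be >= 1")
  if (delta < 0) stop("delta must be >= 0")
  set.seed(seed)
  lens <- seqlengths(layout)
  chrom <- sample(seqlevels(layout), nVariants, replace = TRUE,
                  prob = lens / sum(as.numeric(lens)))
  posn <- floor(runif(nVariants, 1, lens[chrom] + 1))
  gr <- GRanges(chrom, IRanges(posn, width = 1L), seqinfo = layout)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  inside <- countOverlaps(gr, enrichedIntervals, ignore.strand = TRUE) > 0L
  t <- rnorm(nVariants) + delta * inside
  mcols(gr) <- DataFrame(trait = trait, b = t, se = 1, t2 = t^2)
  list(stats = gr, truth = list(enrichedIntervals = enrichedIntervals))
}

#' Simulate a gene annotation and GO term map
#'
#' Places non-overlapping genes of 2-50 kb by slotting the genome into
#' equal-sized, per-chromosome compartments (one gene per slot, random
#' offset and strand), then samples `genesPerTerm` genes per term without
#' replacement.
#'
#' @param layout a `Seqinfo`.
#' @param nGenes,nTerms,genesPerTerm counts.
#' @param seed integer seed.
#' @return list with `genes` (`GRanges` with `gene_id`, `tss`, strand) and
#'   `goMap` (data frame `term_id`, `gene_id`).
#' @export
simulateGeneAnnotation <- function(layout, nGenes, nTerms, genesPerTerm,
                                   seed = 1L) {
  if (genesPerTerm > nGenes) stop("genesPerTerm must not exceed nGenes")
  set.seed(seed)
  lens <- as.numeric(seqlengths(layout))
  nPer <- pmax(0L, round(nGenes * lens / sum(lens)))
  while (sum(nPer) != nGenes) { # fix rounding drift on the largest chromosome
    i <- which.max(lens / pmax(nPer, 1L))
    nPer[i] <- nPer[i] + sign(nGenes - sum(nPer))
  }
  maxLen <- 50000L; minLen <- 2000L
  out <- list()
  for (i in seq_along(lens)) {
    if (nPer[i] == 0L) next
    slot <- floor(lens[i] / nPer[i])
    if (slot < maxLen)
      stop("infeasible packing: ", nPer[i], " genes of up to ", maxLen,
           " bp do not fit chromosome ", seqlevels(layout)[i])
    glen <- floor(runif(nPer[i], minLen, maxLen + 1))
    off <- floor(runif(nPer[i], 0, slot - glen + 1))
    st <- (seq_len(nPer[i]) - 1L) * slot + off + 1
    out[[i]] <- GRanges(seqlevels(layout)[i],
                        IRanges(st, width = glen),
                        strand = sample(c("+", "-"), nPer[i], replace = TRUE),
                        seqinfo = layout)
  }
  genes <- GenomicRanges::sort(do.call(c, out[!vapply(out, is.null, TRUE)]),
                               ignore.strand = TRUE)
  mcols(genes)$gene_id <- sprintf("gene%04d", seq_along(genes))
  mcols(genes)$name <- mcols(genes)$gene_id
  mcols(genes)$tss <- ifelse(as.character(strand(genes)) == "+",
                             start(genes), end(genes))
  goMap <- do.call(rbind, lapply(seq_len(nTerms), function(k) {
    data.frame(term_id = sprintf("GO:%07d", k),
               gene_id = sample(mcols(genes)$gene_id, genesPerTerm))
  }))
  list(genes = genes, goMap = goMap)
}
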