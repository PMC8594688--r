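# Count-based window-set enrichment: among the m tested 500-bp windows,
# m_g are differential genome-wide (p < p0) and m_f map to a GO term;
# under the null of random placement the number T_count of differential
# windows in the term follows Hypergeometric(m, m_g, m_f). Tails are
# computed in log space to survive extreme enrichment.

.hyperUpperTail <- function(q, mWhite, mBlack, k) {
  # P(X >= q), X ~ Hypergeometric(white = mWhite, black = mBlack, drawn = k)
  list(p = phyper(q - 1, mWhite, mBlack, k, lower.tail = FALSE),
       log10p = phyper(q - 1, mWhite, mBlack, k, lower.tail = FALSE,
                       log.p = TRUE) / log(10))
}

#' Map tested windows to GO terms through gene overlap
#'
#' A window belongs to a term when it overlaps at least one base of any of
#' the term's genes extended by `flank` bp on both sides (to include
#' regulatory regions). Terms with fewer than `minGenes` annotated genes
#' are dropped; genes in the map but absent from the annotation are
#' skipped with a warning.
#'
#' @param tiles `GRanges` of tested windows (the universe from
#'   [testTiles()]).
#' @param genes gene `GRanges` with a `gene_id` column.
#' @param goMap data frame `term_id`, `gene_id`.
#' @param flank extension in bp (default 10000).
#' @param minGenes minimum genes per term (default 10).
#' @return a named list, term id -> integer indices into `tiles`.
#' @export
mapWindowsToTerms <- function(tiles, genes, goMap, flank = 10000L,
                              minGenes = 10L) {
  known <- goMap$gene_id %in% mcols(genes)$gene_id
  if (any(!known)) {
    warning(sum(!known), " GO-map gene(s) absent from the annotation; skipped")
    goMap <- goMap[known, , drop = FALSE]
  }
  sizes <- table(goMap$term_id)
  goMap <- goMap[goMap$term_id %in% names(sizes)[sizes >= minGenes], ,
                 drop = FALSE]
  if (!nrow(goMap)) return(list())
  ext <- genes
  start(ext) <- pmax(1L, start(ext) - flank)
  lens <- seqlengths(ext)[as.character(seqnames(ext))]
  end(ext) <- ifelse(is.na(lens), end(ext) + flank,
                     pmin(lens, end(ext) + flank))
  gi <- match(goMap$gene_id, mcols(genes)$gene_id)
  hits <- findOverlaps(ext, tiles, ignore.strand = TRUE)
  byGene <- split(subjectHits(hits), queryHits(hits))
  res <- lapply(split(gi, goMap$term_id), function(ix) {
    sort(unique(unlist(byGene[as.character(ix)], use.names = FALSE)))
  })
  res[order(names(res))]
}

#' Count-based hypergeometric window-set test
#'
#' @param tilePvalues numeric p-values of the `m` tested windows (from
#'   [testTiles()], same universe the term map was built on).
#' @param termWindows named list from [mapWindowsToTerms()].
#' @param p0 differential-window threshold (default 0.01).
#' @return a `data.frame` with one row per term: `term_id`, `m`, `mG`
#'   (windows genome-wide with `p < p0`), `mF` (windows in the term),
#'   `tCount` (differential windows in the term), `pHyper`, `log10p`,
#'   `fdr` (Benjamini-Hochberg across terms). Terms mapping to no tested
#'   window are skipped.
#' @export
countBasedTest <- function(tilePvalues, termWindows, p0 = 0.01) {
  m <- length(tilePvalues)
  sig <- tilePvalues < p0
  mG <- sum(sig)
  termWindows <- termWindows[lengths(termWindows) > 0L]
  rows <- lapply(names(termWindows), function(term) {
    ix <- termWindows[[term]]
    tail <- .hyperUpperTail(sum(sig[ix]), mG, m - mG, length(ix))
    data.frame(term_id = term, m = m, mG = mG, mF = length(ix),
               tCount = sum(sig[ix]), pHyper = tail$p, log10p = tail$log10p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), m = integer(), mG = integer(),
                      mF = integer(), tCount = integer(), pHyper = numeric(),
                      log10p = numeric(), fdr = numeric()))
  out$fdr <- p.adjust(out$pHyper, method = "BH")
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of a query gene list against a gene
#' universe for every term of a GO map, with Benjamini-Hochberg FDR
#' across terms. Used for HMR/PMD gene lists (e.g. genes whose promoters
#' intersect group-specific regions).
#'
#' @param queryGenes character vector, a subset of `universeGenes`.
#' @param universeGenes character vector of tested genes.
#' @param goMap data frame `term_id`, `gene_id`.
#' @return a `data.frame`: `term_id`, `nUniverse`, `nTerm`, `nQuery`,
#'   `overlap`, `p`, `log10p`, `fdr`.
#' @export
geneSetEnrichment <- function(queryGenes, universeGenes, goMap) {
  if (!length(queryGenes)) stop("empty query gene list")
  if (!all(queryGenes %in% universeGenes))
    stop("query genes must be a subset of the universe")
  goMap <- goMap[goMap$gene_id %in% universeGenes, , drop = FALSE]
  terms <- split(goMap$gene_id, goMap$term_id)
  nU <- length(unique(universeGenes)); nQ <- length(unique(queryGenes))
  rows <- lapply(names(terms), function(term) {
    tg <- unique(terms[[term]])
    ov <- sum(unique(queryGenes) %in% tg)
    tail <- .hyperUpperTail(ov, length(tg), nU - length(tg), nQ)
    data.frame(term_id = term, nUniverse = nU, nTerm = length(tg),
               nQuery = nQ, overlap = ov, p = tail$p, log10p = tail$log10p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), nUniverse = integer(),
                      nTerm = integer(), nQuery = integer(),
                      overlap = integer(), p = numeric(), log10p = numeric(),
                      fdr = numeric()))
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}
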