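# End-to-end deterministic pipeline: simulate (or load) inputs, segment
# HMRs and PMDs, test tiles, run both enrichment tests, integrate, and
# write every output with a checksum manifest.

#' Default pipeline configuration (synthetic study)
#'
#' Returns a fully populated configuration list for a self-contained
#' synthetic run: a small two-chromosome genome with planted
#' hypomethylated regions, partially methylated domains, differential
#' tiles and GWAS signal regions. Every field can be overridden, or a YAML
#' file with the same structure can be passed to [runPipeline()].
#'
#' @param seed integer master seed.
#' @param outDir output directory.
#' @return a named list understood by [runPipeline()].
#' @export
defaultPipelineConfig <- function(seed = 1L, outDir = tempfile("pipeline")) {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    genome = list(chroms = c("chr1", "chr2"), lengths = c(3e6, 2e6)),
    simulate = list(
      baselineMeth = 0.75, coverageMean = 10, cpgSpacingMean = 100,
      nSamplesPerGroup = 3L,
      hmrs = list(chrom = "chr1", starts = c(100001, 500001, 900001),
                  width = 2000, level = 0.05),
      pmds = list(chrom = "chr2", starts = c(200001, 1000001),
                  width = 100000, level = 0.40),
      dmrTiles = list(chrom = "chr1", starts = seq(1500001, 1539501, 500),
                      width = 500, levelGroup1 = 0.90, levelGroup2 = 0.60),
      gwas = list(nVariants = 20000L, delta = 2,
                  enriched = list(chrom = "chr1", start = 1500001,
                                  end = 1540000)),
      genes = list(nGenes = 60L, nTerms = 8L, genesPerTerm = 12L)),
    hmr = list(minCoverage = 5L),
    pmd = list(),
    dmr = list(qCutoff = 0.01, diffCutoff = 5),
    gwasEnrich = list(nPerm = 1000L),
    goEnrich = list(p0 = 0.01, flank = 10000L, minGenes = 10L),
    integrate = list(snpThreshold = 1e-5, promoterBp = 2000L,
                     snpWindowBp = 250000L))
}

.validateConfig <- function(config) {
  need <- c("seed", "outDir", "genome", "simulate")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("pipeline config lacks field(s): ", paste(miss, collapse = ", "))
  if (is.null(config$simulate$gwas) && !is.null(config$gwasEnrich))
    stop("GWAS enrichment enabled but no GWAS inputs configured")
  invisible(config)
}

.cfgRanges <- function(x, layout) {
  if (is.null(x)) return(GRanges(seqinfo = layout))
  if (!is.null(x$starts))
    GRanges(x$chrom, IRanges(x$starts, width = x$width), seqinfo = layout)
  else GRanges(x$chrom, IRanges(x$start, x$end), seqinfo = layout)
}

#' Run the full synthetic pipeline
#'
#' Chains simulation, HMR and PMD segmentation, tile testing, GWAS and GO
#' enrichment and the integration steps, writing all declared outputs to
#' `config$outDir` and a `manifest.tsv` listing every file with its md5
#' checksum. Deterministic: the same configuration and seed give
#' checksum-identical outputs. Validation happens before any computation;
#' a stage failure leaves earlier outputs in place and is reported.
#'
#' @param config a list as from [defaultPipelineConfig()], or the path of
#'   a YAML file with the same structure.
#' @return invisibly, a list with `status` (0 on success), `manifest`
#'   (data frame `file`, `md5`) and `counts` (per-stage summary numbers).
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validateConfig(config)
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  layout <- genomeLayout(config$genome$chroms, config$genome$lengths)
  counts <- list()
  emit <- local({
    files <- character()
    function(path = NULL) {
      if (is.null(path)) return(files)
      files <<- c(files, path); path
    }
  })

  # --- simulate -------------------------------------------------------------
  sc <- config$simulate
  mkLevel <- function(x, cols) {
    gr <- .cfgRanges(x, layout)
    for (cc in cols) mcols(gr)[[cc]] <- rep(x[[cc]], length(gr))
    gr
  }
  design <- simulationDesign(
    layout, baselineMeth = sc$baselineMeth, coverageMean = sc$coverageMean,
    cpgSpacingMean = sc$cpgSpacingMean,
    plantedHmrs = mkLevel(sc$hmrs, "level"),
    plantedPmds = mkLevel(sc$pmds, "level"),
    plantedDmrTiles = mkLevel(sc$dmrTiles, c("levelGroup1", "levelGroup2")),
    nSamplesPerGroup = sc$nSamplesPerGroup, seed = config$seed)
  sim <- simulateMethylomes(design)
  writeGenomeLayout(layout, emit(file.path(outDir, "layout.tsv")))
  for (s in sim$samples)
    writeCpGCalls(s, emit(file.path(outDir, paste0(sampleId(s), ".cov.tsv"))))
  gw <- simulateGwas(layout, sc$gwas$nVariants,
                     .cfgRanges(sc$gwas$enriched, layout),
                     delta = sc$gwas$delta, seed = config$seed + 1L)
  writeGwasStats(gw$stats, emit(file.path(outDir, "gwas.tsv")))
  ann <- simulateGeneAnnotation(layout, sc$genes$nGenes, sc$genes$nTerms,
                                sc$genes$genesPerTerm,
                                seed = config$seed + 2L)
  writeBedIntervals(ann$genes, emit(file.path(outDir, "genes.bed")))
  writeGoMap(ann$goMap, emit(file.path(outDir, "gomap.tsv")))
  jsonlite::write_json(
    list(hmr = as.data.frame(sim$truth$hmrIntervals),
         pmd = as.data.frame(sim$truth$pmdIntervals),
         dmr = as.data.frame(sim$truth$dmrTiles),
         gwasEnriched = as.data.frame(gw$truth$enrichedIntervals)),
    emit(file.path(outDir, "truth.json")))
  groups <- split(sim$samples, sim$truth$groups)

  # --- HMR ------------------------------------------------------------------
  hp <- do.call(hmrParams, config$hmr %||% list())
  hmrs <- lapply(groups, function(g) detectHmrs(poolGroup(g), hp))
  for (nm in names(hmrs)) {
    gr <- hmrs[[nm]]
    mcols(gr)$name <- sprintf("HMR%05d", seq_along(gr))
    mcols(gr)$score <- pmin(1000L, round(1000 * mcols(gr)$meanLevel))
    writeBedIntervals(gr, emit(file.path(outDir, paste0("hmr_", nm, ".bed"))))
  }
  counts$hmr <- lapply(hmrs, length)

  # --- PMD ------------------------------------------------------------------
  pp <- do.call(pmdParams, config$pmd %||% list())
  perSample <- lapply(sim$samples, function(s) {
    g <- calls(s); g <- g[mcols(g)$nTotal >= 5L]
    s5 <- Methylome(sampleId(s), g)
    decodePmdStates(binarizeWindows(s5, pp, layout), pp)
  })
  for (nm in names(perSample))
    writeBedIntervals(perSample[[nm]],
                      emit(file.path(outDir, paste0("pmd_", nm, ".bed"))))
  consensus <- consensusPmds(perSample, pp, layout)
  writeBedIntervals(consensus, emit(file.path(outDir, "pmd_consensus.bed")))
  counts$pmd <- list(consensus = length(consensus),
                     bp = totalBp(consensus),
                     genomeFraction = totalBp(consensus) /
                       sum(as.numeric(seqlengths(layout))))

  # --- DMR ------------------------------------------------------------------
  se <- buildTiles(sim$samples, layout)
  g1 <- names(sim$truth$groups)[sim$truth$groups == "aged"]
  g2 <- names(sim$truth$groups)[sim$truth$groups == "young"]
  res <- adjustQ(testTiles(se, g1, g2))
  dt <- data.table::data.table(
    chrom = as.character(seqnames(res)), start = start(res) - 1L,
    end = end(res), p = mcols(res)$p, q = mcols(res)$q,
    diff = mcols(res)$diff, direction = mcols(res)$direction)
  data.table::fwrite(dt, emit(file.path(outDir, "dmr_tests.tsv")), sep = "\t")
  dc <- config$dmr
  dmrs <- callDmrs(res, dc$qCutoff, dc$diffCutoff)
  for (nm in names(dmrs))
    writeBedIntervals(granges(dmrs[[nm]]),
                      emit(file.path(outDir, paste0("dmr_", nm, ".bed"))))
  counts$dmr <- lapply(dmrs, length)

  # --- GWAS enrichment ------------------------------------------------------
  featureSets <- c(lapply(dmrs, granges), list(hmr = hmrs[[1L]]))
  featureSets <- featureSets[vapply(featureSets, length, 1L) > 0L]
  panel <- enrichmentPanel(list(trait1 = gw$stats), featureSets,
                           nPerm = config$gwasEnrich$nPerm,
                           seed = config$seed + 3L)
  data.table::fwrite(panel, emit(file.path(outDir, "gwas_enrichment.tsv")),
                     sep = "\t")
  counts$gwasEnrich <- nrow(panel)

  # --- GO enrichment --------------------------------------------------------
  gc <- config$goEnrich
  termMap <- mapWindowsToTerms(res, ann$genes, ann$goMap,
                               flank = gc$flank, minGenes = gc$minGenes)
  goRes <- countBasedTest(mcols(res)$p, termMap, p0 = gc$p0)
  data.table::fwrite(goRes, emit(file.path(outDir, "go_enrichment.tsv")),
                     sep = "\t")
  counts$goEnrich <- nrow(goRes)

  # --- integration ----------------------------------------------------------
  glob <- globalMethylationTest(groups[["aged"]], groups[["young"]])
  folds <- data.frame(
    feature = names(featureSets),
    foldInGenes = vapply(featureSets, function(f)
      elementFoldEnrichment(f, ann$genes,
                            sum(as.numeric(seqlengths(layout)))), 1.0))
  data.table::fwrite(folds, emit(file.path(outDir, "fold_enrichment.tsv")),
                     sep = "\t")
  cand <- candidateGeneTable(res, res, ann$genes, list(trait1 = gw$stats),
                             qCutoff = dc$qCutoff,
                             diffCutoff = dc$diffCutoff,
                             snpThreshold = config$integrate$snpThreshold,
                             promoterBp = config$integrate$promoterBp,
                             snpWindowBp = config$integrate$snpWindowBp)
  data.table::fwrite(cand, emit(file.path(outDir, "candidate_genes.tsv")),
                     sep = "\t")
  counts$integrate <- list(globalT = glob$t, globalP = glob$p,
                           candidates = nrow(cand))

  manifest <- data.frame(file = basename(emit()),
                         md5 = unname(tools::md5sum(emit())))
  data.table::fwrite(manifest, file.path(outDir, "manifest.tsv"), sep = "\t")
  invisible(list(status = 0L, manifest = manifest, counts = counts,
                 outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
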