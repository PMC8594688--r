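#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   start<- end<- mcols mcols<- reduce findOverlaps countOverlaps coverage
#'   resize
#' @importFrom IRanges IRanges subsetByOverlaps slice ranges
#' @importFrom S4Vectors DataFrame queryHits subjectHits runValue runLength Rle
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqinfo seqinfo<-
#'   seqlevels<- sortSeqlevels keepSeqlevels
#' @importFrom stats rbinom rpois rnorm rgeom runif pchisq phyper p.adjust
#'   t.test wilcox.test qpois ppois rnbinom setNames dbinom
#' @importFrom utils head tail
NULL

#' Methylome: one sample's CpG methylation calls
#'
#' Container for a single animal's CpG-level methylation calls from
#' whole-genome bisulfite sequencing: genomic positions with methylated and
#' total read counts, plus the sample's group labels (age group and
#' sire-conception-rate group).
#'
#' @slot sampleId single character identifier.
#' @slot ageGroup one of `"aged"`, `"young"`, `"none"`.
#' @slot scrGroup one of `"low"`, `"high"`, `"none"`.
#' @slot calls a [GenomicRanges::GRanges] of width-1 CpG positions with
#'   integer metadata columns `nMeth` and `nTotal`.
#'
#' @details The methylation level of a call is `nMeth / nTotal`, a fraction
#' in `[0, 1]`. Positions are unique per chromosome and kept sorted in the
#' chromosome order of the genome layout ([GenomeInfoDb::Seqinfo]) attached
#' to `calls`. Calls on the two strands of a CpG are whatever the input file
#' provides; no destranding is performed.
#'
#' @export
setClass("Methylome",
  slots = c(sampleId = "character", ageGroup = "character",
            scrGroup = "character", calls = "GRanges"))

setValidity("Methylome", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
  if (!object@ageGroup %in% c("aged", "young", "none"))
    msg <- c(msg, "ageGroup must be 'aged', 'young' or 'none'")
  if (!object@scrGroup %in% c("low", "high", "none"))
    msg <- c(msg, "scrGroup must be 'low', 'high' or 'none'")
  mc <- mcols(object@calls)
  if (!all(c("nMeth", "nTotal") %in% colnames(mc))) {
    msg <- c(msg, "calls must carry nMeth and nTotal metadata columns")
  } else {
    nm <- mc$nMeth; nt <- mc$nTotal
    if (any(nm < 0) || any(nt < 1)) msg <- c(msg, "need nMeth >= 0 and nTotal >= 1")
    if (any(nm > nt)) msg <- c(msg, "nMeth must not exceed nTotal")
    if (any(width(object@calls) != 1L)) msg <- c(msg, "calls must be width-1 positions")
    if (anyDuplicated(paste(seqnames(object@calls), start(object@calls))))
      msg <- c(msg, "positions must be unique per chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Methylome
#'
#' @param sampleId sample identifier.
#' @param calls `GRanges` of width-1 positions with `nMeth`, `nTotal`.
#' @param ageGroup,scrGroup group labels (default `"none"`).
#' @return a [Methylome-class] object with calls sorted in layout order.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, width = 1),
#'                              nMeth = 4L, nTotal = 5L)
#' Methylome("s1", gr)
#' @export
Methylome <- function(sampleId, calls, ageGroup = "none", scrGroup = "none") {
  calls <- GenomicRanges::sort(calls, ignore.strand = TRUE)
  new("Methylome", sampleId = as.character(sampleId), ageGroup = ageGroup,
      scrGroup = scrGroup, calls = calls)
}

#' @describeIn Methylome-class number of CpG calls.
#' @param x,object a `Methylome`.
#' @export
setMethod("length", "Methylome", function(x) length(x@calls))

setMethod("show", "Methylome", function(object) {
  lv <- methLevels(object)
  cat("Methylome sample", object@sampleId,
      sprintf("(age=%s, scr=%s)\n", object@ageGroup, object@scrGroup))
  cat(sprintf("  %d CpG calls on %d chromosome(s); mean level %.3f\n",
              length(object@calls),
              length(unique(as.character(seqnames(object@calls)))),
              if (length(object@calls)) mean(lv) else NA_real_))
})

#' @rdname Methylome-class
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname Methylome-class
#' @export
setMethod("sampleId", "Methylome", function(object) object@sampleId)

#' @rdname Methylome-class
#' @export
setGeneric("calls", function(object) standardGeneric("calls"))
#' @rdname Methylome-class
#' @export
setMethod("calls", "Methylome", function(object) object@calls)

#' @rdname Methylome-class
#' @export
setGeneric("methLevels", function(object) standardGeneric("methLevels"))
#' @describeIn Methylome-class per-CpG methylation levels `nMeth/nTotal`.
#' @export
setMethod("methLevels", "Methylome", function(object) {
  mc <- mcols(object@calls)
  if (!length(object@calls)) return(numeric())
  mc$nMeth / mc$nTotal
})

#' Parameters for hypomethylated-region detection
#'
#' @slot window seed window size in bp (default 200).
#' @slot step extension step in bp (default 50).
#' @slot hypoLevel a CpG is hypomethylated when its level is strictly below
#'   this fraction (default 0.20).
#' @slot hypoFraction minimum fraction of hypomethylated CpGs a window (and
#'   every extension of it) must contain (default 0.80).
#' @slot minCpgs minimum covered CpGs for a reported region (default 5).
#' @slot minCoverage minimum pooled read depth for a CpG to count (default 5).
#' @export
setClass("HmrParams",
  slots = c(window = "integer", step = "integer", hypoLevel = "numeric",
            hypoFraction = "numeric", minCpgs = "integer",
            minCoverage = "integer"))

setValidity("HmrParams", function(object) {
  msg <- character()
  if (object@step <= 0L || object@window < object@step)
    msg <- c(msg, "need window >= step > 0")
  if (object@hypoLevel <= 0 || object@hypoLevel >= 1 ||
      object@hypoFraction <= 0 || object@hypoFraction >= 1)
    msg <- c(msg, "hypoLevel and hypoFraction must lie in (0,1)")
  if (object@minCpgs < 1L) msg <- c(msg, "minCpgs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname HmrParams-class
#' @param window,step,hypoLevel,hypoFraction,minCpgs,minCoverage see slots.
#' @return an `HmrParams` object.
#' @export
hmrParams <- function(window = 200L, step = 50L, hypoLevel = 0.20,
                      hypoFraction = 0.80, minCpgs = 5L, minCoverage = 5L) {
  new("HmrParams", window = as.integer(window), step = as.integer(step),
      hypoLevel = hypoLevel, hypoFraction = hypoFraction,
      minCpgs = as.integer(minCpgs), minCoverage = as.integer(minCoverage))
}

#' Parameters for partially-methylated-domain detection
#'
#' @slot window non-overlapping window size in bp (default 20000).
#' @slot levelThreshold windows with mean methylation strictly greater than
#'   this are labelled 1 (methylated background), otherwise 0 (default 0.60).
#' @slot minWindows minimum run length, in windows, for a domain both per
#'   sample and after consensus (default 3).
#' @slot minSupport minimum number of samples supporting a consensus base
#'   (default 3).
#' @slot maxIter,tol Baum-Welch iteration cap and log-likelihood tolerance.
#' @export
setClass("PmdParams",
  slots = c(window = "integer", levelThreshold = "numeric",
            minWindows = "integer", minSupport = "integer",
            maxIter = "integer", tol = "numeric"))

setValidity("PmdParams", function(object) {
  msg <- character()
  if (object@window <= 0L) msg <- c(msg, "window must be positive")
  if (object@levelThreshold <= 0 || object@levelThreshold >= 1)
    msg <- c(msg, "levelThreshold must lie in (0,1)")
  if (object@minWindows < 1L) msg <- c(msg, "minWindows must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname PmdParams-class
#' @param window,levelThreshold,minWindows,minSupport,maxIter,tol see slots.
#' @return a `PmdParams` object.
#' @export
pmdParams <- function(window = 20000L, levelThreshold = 0.60,
                      minWindows = 3L, minSupport = 3L,
                      maxIter = 100L, tol = 1e-6) {
  new("PmdParams", window = as.integer(window),
      levelThreshold = levelThreshold, minWindows = as.integer(minWindows),
      minSupport = as.integer(minSupport), maxIter = as.integer(maxIter),
      tol = tol)
}

#' Design of a synthetic methylome study
#'
#' Describes the genome, the baseline methylation landscape and every
#' planted feature used by [simulateMethylomes()]. Defaults reproduce the
#' statistical structure of a mammalian sperm methylome: high global
#' methylation (~75%), short hypomethylated regions (<20% level), large
#' partially methylated domains (~40% level, >= 60 kb) and group-differential
#' 500-bp tiles.
#'
#' @slot layout a [GenomeInfoDb::Seqinfo] giving chromosome names and lengths.
#' @slot baselineMeth baseline methylation fraction (default 0.75).
#' @slot coverageMean mean reads per CpG, Poisson truncated at >= 1
#'   (default 10).
#' @slot coverageDispersion negative-binomial size for overdispersed
#'   coverage; `Inf` (default) keeps the Poisson model.
#' @slot cpgSpacingMean mean CpG spacing in bp (default 100).
#' @slot cpgSpacingHmr mean CpG spacing inside planted hypomethylated
#'   blocks (default 20 bp, emulating the CpG-island-like density of real
#'   hypomethylated regions).
#' @slot plantedHmrs `GRanges` with a numeric `level` column (default 0.05).
#' @slot plantedPmds `GRanges` with `level` (default 0.40); widths must be
#'   >= 60000 bp (three 20-kb windows).
#' @slot plantedDmrTiles `GRanges` with `levelGroup1` and `levelGroup2`.
#' @slot nSamplesPerGroup samples per group (two groups are generated).
#' @slot seed integer seed; identical designs give byte-identical output.
#' @export
setClass("SimulationDesign",
  slots = c(layout = "Seqinfo", baselineMeth = "numeric",
            coverageMean = "numeric", coverageDispersion = "numeric",
            cpgSpacingMean = "numeric", cpgSpacingHmr = "numeric",
            plantedHmrs = "GRanges",
            plantedPmds = "GRanges", plantedDmrTiles = "GRanges",
            nSamplesPerGroup = "integer", seed = "integer"))

.checkPlanted <- function(gr, layout, what, levelCols) {
  msg <- character()
  if (!length(gr)) return(msg)
  if (!all(as.character(seqnames(gr)) %in% seqlevels(layout)))
    return(paste(what, "on chromosomes absent from layout"))
  lens <- seqlengths(layout)[as.character(seqnames(gr))]
  if (any(end(gr) > lens)) msg <- c(msg, paste(what, "extends beyond chromosome end"))
  for (cc in levelCols) {
    v <- mcols(gr)[[cc]]
    if (is.null(v) || any(v < 0) || any(v > 1))
      msg <- c(msg, sprintf("%s needs column %s with values in [0,1]", what, cc))
  }
  msg
}

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (object@baselineMeth < 0 || object@baselineMeth > 1)
    msg <- c(msg, "baselineMeth must lie in [0,1]")
  if (object@coverageMean <= 0) msg <- c(msg, "coverageMean must be positive")
  if (object@nSamplesPerGroup < 1L) msg <- c(msg, "nSamplesPerGroup must be >= 1")
  msg <- c(msg,
    .checkPlanted(object@plantedHmrs, object@layout, "plantedHmrs", "level"),
    .checkPlanted(object@plantedPmds, object@layout, "plantedPmds", "level"),
    .checkPlanted(object@plantedDmrTiles, object@layout, "plantedDmrTiles",
                  c("levelGroup1", "levelGroup2")))
  if (length(object@plantedPmds) && any(width(object@plantedPmds) < 60000L))
    msg <- c(msg, "planted PMDs must span >= 60 kb (three 20-kb windows)")
  lv <- seqlevels(object@layout)
  bare <- function(gr) GRanges(factor(as.character(seqnames(gr)), lv),
                               ranges(gr))
  allKnown <- all(c(as.character(seqnames(object@plantedHmrs)),
                    as.character(seqnames(object@plantedPmds)),
                    as.character(seqnames(object@plantedDmrTiles))) %in% lv)
  if (allKnown) {
    planted <- c(bare(object@plantedHmrs), bare(object@plantedPmds),
                 bare(object@plantedDmrTiles))
    kind <- rep(c("hmr", "pmd", "dmr"),
                c(length(object@plantedHmrs), length(object@plantedPmds),
                  length(object@plantedDmrTiles)))
    if (length(planted) > 1L) {
      hits <- findOverlaps(planted, planted)
      bad <- kind[queryHits(hits)] != kind[subjectHits(hits)]
      if (any(bad)) msg <- c(msg, "planted features of different kinds overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationDesign-class
#' @param layout,baselineMeth,coverageMean,coverageDispersion,cpgSpacingMean
#'   see slots.
#' @param cpgSpacingHmr see slots.
#' @param plantedHmrs,plantedPmds,plantedDmrTiles see slots; empty by default.
#' @param nSamplesPerGroup,seed see slots.
#' @return a `SimulationDesign`.
#' @export
simulationDesign <- function(layout, baselineMeth = 0.75, coverageMean = 10,
                             coverageDispersion = Inf, cpgSpacingMean = 100,
                             cpgSpacingHmr = 20,
                             plantedHmrs = GRanges(), plantedPmds = GRanges(),
                             plantedDmrTiles = GRanges(),
                             nSamplesPerGroup = 3L, seed = 1L) {
  new("SimulationDesign", layout = layout, baselineMeth = baselineMeth,
      coverageMean = coverageMean, coverageDispersion = coverageDispersion,
      cpgSpacingMean = cpgSpacingMean, cpgSpacingHmr = cpgSpacingHmr,
      plantedHmrs = plantedHmrs,
      plantedPmds = plantedPmds, plantedDmrTiles = plantedDmrTiles,
      nSamplesPerGroup = as.integer(nSamplesPerGroup), seed = as.integer(seed))
}
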