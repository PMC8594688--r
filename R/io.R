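#' Build a genome layout
#'
#' A genome layout is a [GenomeInfoDb::Seqinfo]: an ordered set of
#' chromosome names with lengths. The order is fixed and reused for every
#' position-sorted traversal, in particular the genome-wide concatenation
#' that defines the cyclical permutation of GWAS test statistics.
#'
#' @param chromNames character vector of unique chromosome names.
#' @param chromLengths positive integer lengths in bp.
#' @return a `Seqinfo`.
#' @examples
#' genomeLayout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genomeLayout <- function(chromNames, chromLengths) {
  if (anyDuplicated(chromNames)) stop("chromosome names must be unique")
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  Seqinfo(seqnames = as.character(chromNames),
          seqlengths = as.integer(chromLengths))
}

#' Read a genome layout from a two-column TSV (chrom, length)
#'
#' @param path TSV file without header: `chrom  length`.
#' @return a `Seqinfo` with chromosomes in file order.
#' @export
readGenomeLayout <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  genomeLayout(dt$chrom, dt$length)
}

#' @rdname readGenomeLayout
#' @param layout a `Seqinfo`.
#' @export
writeGenomeLayout <- function(layout, path) {
  data.table::fwrite(data.table::data.table(chrom = seqlevels(layout),
                                            length = seqlengths(layout)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

.freadChecked <- function(path, what, ncols) {
  if (file.size(path) == 0) return(NULL)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stop("failed to parse ", what, " file '", path,
                             "': ", conditionMessage(e)))
  if (!ncol(dt) %in% ncols)
    stop(what, " file '", path, "' has ", ncol(dt),
         " columns; expected ", paste(ncols, collapse = " or "))
  dt
}

#' Read per-CpG methylation calls
#'
#' Reads a Bismark-coverage-style TSV of CpG methylation counts. Two
#' dialects are accepted: the four-column form
#' `chrom  pos(1-based)  count_methylated  count_unmethylated`, and the
#' six-column Bismark coverage form
#' `chrom  start(1-based)  end  percent  count_methylated  count_unmethylated`
#' whose percentage column is ignored (counts are authoritative).
#'
#' @param path TSV file (no header).
#' @param minCoverage keep only loci with
#'   `count_methylated + count_unmethylated >= minCoverage` (default 1).
#'   The segmentation methods use 5, matching a >= 5x read-depth filter.
#' @param sampleId identifier stored in the result (default: file base name).
#' @param layout optional `Seqinfo`; when given, calls are ordered by its
#'   chromosome order and checked against chromosome bounds.
#' @param ageGroup,scrGroup group labels for the sample.
#' @return a [Methylome-class].
#' @export
readCpGCalls <- function(path, minCoverage = 1L, sampleId = NULL,
                         layout = NULL, ageGroup = "none", scrGroup = "none") {
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  dt <- .freadChecked(path, "CpG calls", c(4L, 6L))
  if (is.null(dt)) {
    gr <- GRanges()
    mcols(gr)$nMeth <- integer(); mcols(gr)$nTotal <- integer()
    if (!is.null(layout)) seqinfo(gr) <- layout
    return(Methylome(sampleId, gr, ageGroup, scrGroup))
  }
  if (ncol(dt) == 6L) dt <- dt[, c(1L, 2L, 5L, 6L), with = FALSE]
  data.table::setnames(dt, c("chrom", "pos", "nMeth", "nUnmeth"))
  for (cc in c("pos", "nMeth", "nUnmeth")) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    bad <- is.na(v) | v != floor(v)
    if (any(bad))
      stop("malformed CpG call row at line ", which(bad)[1L], " of '", path,
           "': column ", cc, " is not a non-missing integer")
    dt[[cc]] <- v
  }
  if (any(dt$nMeth < 0) || any(dt$nUnmeth < 0))
    stop("negative counts in '", path, "' (line ",
         which(dt$nMeth < 0 | dt$nUnmeth < 0)[1L], ")")
  total <- dt$nMeth + dt$nUnmeth
  keep <- total >= minCoverage
  dt <- dt[keep, ]; total <- total[keep]
  gr <- GRanges(dt$chrom, IRanges(dt$pos, dt$pos))
  mcols(gr) <- DataFrame(nMeth = as.integer(dt$nMeth),
                         nTotal = as.integer(total))
  if (!is.null(layout)) {
    if (!all(seqlevels(gr) %in% seqlevels(layout)))
      stop("chromosomes in '", path, "' absent from layout: ",
           paste(setdiff(seqlevels(gr), seqlevels(layout)), collapse = ", "))
    seqlevels(gr) <- seqlevels(layout)
    seqinfo(gr) <- layout
  }
  Methylome(sampleId, gr, ageGroup, scrGroup)
}

#' Write per-CpG methylation calls in the four-column dialect
#'
#' @param methylome a [Methylome-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeCpGCalls <- function(methylome, path) {
  gr <- calls(methylome)
  data.table::fwrite(
    data.table::data.table(chrom = as.character(seqnames(gr)),
                           pos = start(gr), nMeth = mcols(gr)$nMeth,
                           nUnmeth = mcols(gr)$nTotal - mcols(gr)$nMeth),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Reads a TSV `trait  chrom  pos(1-based)  b  se` (a sixth, precomputed
#' p-value column is tolerated and ignored; the squared t-statistic is
#' always recomputed as `(b/se)^2`). Variants are returned sorted by the
#' layout's chromosome order then position - the global genome order the
#' cyclical permutation rotates over.
#'
#' @param path TSV file (no header).
#' @param layout a `Seqinfo` defining chromosome order.
#' @return a `GRanges` of width-1 variant positions with metadata columns
#'   `trait`, `b`, `se`, `t2`.
#' @export
readGwasStats <- function(path, layout) {
  dt <- .freadChecked(path, "GWAS summary", c(5L, 6L))
  if (is.null(dt)) {
    gr <- GRanges(); seqinfo(gr) <- layout
    mcols(gr) <- DataFrame(trait = character(), b = numeric(),
                           se = numeric(), t2 = numeric())
    return(gr)
  }
  dt <- dt[, 1:5, with = FALSE]
  data.table::setnames(dt, c("trait", "chrom", "pos", "b", "se"))
  if (any(dt$se <= 0))
    stop("standard errors must be positive (line ", which(dt$se <= 0)[1L], ")")
  gr <- GRanges(dt$chrom, IRanges(dt$pos, dt$pos))
  mcols(gr) <- DataFrame(trait = dt$trait, b = dt$b, se = dt$se,
                         t2 = (dt$b / dt$se)^2)
  seqlevels(gr) <- seqlevels(layout)
  seqinfo(gr) <- layout
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname readGwasStats
#' @param stats the `GRanges` returned by `readGwasStats`.
#' @export
writeGwasStats <- function(stats, path) {
  data.table::fwrite(
    data.table::data.table(trait = mcols(stats)$trait,
                           chrom = as.character(seqnames(stats)),
                           pos = start(stats), b = mcols(stats)$b,
                           se = mcols(stats)$se),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read/write genomic intervals as BED
#'
#' Thin wrappers over [rtracklayer::import.bed()] / `export.bed` that attach
#' the genome layout. BED files are 0-based half-open on disk; the returned
#' `GRanges` uses the usual 1-based closed convention.
#'
#' @param path BED3/BED6 file.
#' @param layout optional `Seqinfo`.
#' @return a `GRanges`.
#' @export
readBedIntervals <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(layout)) {
    seqlevels(gr) <- seqlevels(layout)
    seqinfo(gr) <- layout
  }
  gr
}

#' @rdname readBedIntervals
#' @param gr a `GRanges`; metadata columns `name` and `score` are written
#'   when present.
#' @export
writeBedIntervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a gene annotation from BED6
#'
#' Genes are BED6 records with the gene identifier in the name field and a
#' strand. The transcription start site is the interval's 5' end
#' (start on `+`, end on `-`).
#'
#' @param path BED6 file.
#' @param layout optional `Seqinfo`.
#' @return a `GRanges` with metadata columns `gene_id` and `tss` (1-based).
#' @export
readGeneBed <- function(path, layout = NULL) {
  gr <- readBedIntervals(path, layout)
  if (is.null(mcols(gr)$name)) stop("gene BED must carry names (BED6)")
  if (any(strand(gr) == "*")) stop("gene BED must carry strands (BED6)")
  mcols(gr)$gene_id <- mcols(gr)$name
  mcols(gr)$tss <- ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
  gr
}

#' Read a GO term-to-gene map
#'
#' @param path two-column TSV `term_id  gene_id` (no header).
#' @return a `data.frame` with columns `term_id`, `gene_id`.
#' @export
readGoMap <- function(path) {
  dt <- .freadChecked(path, "GO map", 2L)
  if (is.null(dt))
    return(data.frame(term_id = character(), gene_id = character()))
  data.table::setnames(dt, c("term_id", "gene_id"))
  as.data.frame(dt)
}

#' @rdname readGoMap
#' @param goMap data frame with `term_id`, `gene_id`.
#' @export
writeGoMap <- function(goMap, path) {
  data.table::fwrite(goMap[, c("term_id", "gene_id")], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
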