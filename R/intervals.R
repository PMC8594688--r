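#' Interval-set arithmetic
#'
#' `mergeIntervals` collapses a set of genomic intervals into the minimal
#' sorted set of disjoint intervals covering the same bases; abutting
#' intervals (half-open adjacency on disk, e.g. BED `[0,100)` + `[100,200)`)
#' are merged. `totalBp` is the number of bases covered and `intersectBp`
#' the number of bases two sets share.
#'
#' @param gr,a,b `GRanges`; strand is ignored.
#' @return `mergeIntervals`: a sorted, disjoint `GRanges`;
#'   `totalBp`/`intersectBp`: a single number of base pairs.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 21), c(10, 30)))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 25))
#' intersectBp(a, b)  # 10
#' @export
mergeIntervals <- function(gr) {
  .checkWithinLayout(gr)
  reduce(GenomicRanges::sort(gr, ignore.strand = TRUE), ignore.strand = TRUE)
}

.checkWithinLayout <- function(gr) {
  sl <- seqlengths(gr)
  if (!length(gr) || all(is.na(sl))) return(invisible())
  lens <- sl[as.character(seqnames(gr))]
  bad <- !is.na(lens) & (end(gr) > lens | start(gr) < 1L)
  if (any(bad))
    stop("interval beyond chromosome bounds: ",
         paste0(seqnames(gr)[bad][1L], ":", start(gr)[bad][1L], "-",
                end(gr)[bad][1L]))
  invisible()
}

#' @rdname mergeIntervals
#' @export
totalBp <- function(gr) sum(as.numeric(width(reduce(gr, ignore.strand = TRUE))))

#' @rdname mergeIntervals
#' @export
intersectBp <- function(a, b) {
  ov <- GenomicRanges::intersect(reduce(a, ignore.strand = TRUE),
                                 reduce(b, ignore.strand = TRUE),
                                 ignore.strand = TRUE)
  sum(as.numeric(width(ov)))
}

#' Compare two interval sets by member overlap
#'
#' Venn-style comparison of two merged interval sets (e.g. the
#' hypomethylated regions of two animal groups): a member of one set is
#' "shared" when it overlaps at least one base of the other set, otherwise
#' it is set-specific. Counts are per input-set member, not per base, so the
#' two shared counts can differ.
#'
#' @param a,b merged `GRanges`.
#' @return a list with counts `sharedA`, `sharedB`, `aSpecific`,
#'   `bSpecific` and the corresponding `GRanges` subsets.
#' @export
compareIntervalSets <- function(a, b) {
  inB <- countOverlaps(a, b, ignore.strand = TRUE) > 0L
  inA <- countOverlaps(b, a, ignore.strand = TRUE) > 0L
  list(sharedA = sum(inB), sharedB = sum(inA),
       aSpecific = sum(!inB), bSpecific = sum(!inA),
       sharedARanges = a[inB], sharedBRanges = b[inA],
       aSpecificRanges = a[!inB], bSpecificRanges = b[!inA])
}
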