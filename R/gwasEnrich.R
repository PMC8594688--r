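# Sum-based marker-set enrichment: T_sum = sum of squared t-statistics of
# the variants inside a genomic feature, with an empirical null obtained by
# cyclically rotating the genome-ordered vector of t^2 values, which
# uncouples variants from features while preserving the local correlation
# structure of the statistics.

#' Observed sum statistic of a feature set
#'
#' `T_sum` is the sum of `t^2 = (b/se)^2` over the variants whose position
#' falls inside the merged feature set (half-open containment: a variant
#' sitting exactly on a feature's BED end coordinate is outside). `m_f`
#' is the number of such variants.
#'
#' @param stats variant `GRanges` from [readGwasStats()] or
#'   [simulateGwas()], sorted in genome (layout) order.
#' @param feature `GRanges` feature set (merged internally).
#' @return a list with `tSum`, `mF`, `testable` (`FALSE` when no variant
#'   falls inside the feature, in which case `tSum` is `NA`).
#' @export
sumStatistic <- function(stats, feature) {
  inside <- countOverlaps(stats, reduce(feature, ignore.strand = TRUE),
                          ignore.strand = TRUE) > 0L
  mF <- sum(inside)
  list(tSum = if (mF) sum(mcols(stats)$t2[inside]) else NA_real_,
       mF = mF, testable = mF > 0L)
}

.rotationSums <- function(v, idx, ks) {
  # sum over the fixed index positions of the vector rotated by each k:
  # rotation k places v[(i - k - 1) mod n + 1] at position i
  n <- length(v)
  pos <- outer(idx - 1L, ks, "-") %% n + 1L
  colSums(matrix(v[pos], nrow = length(idx)))
}

#' Cyclical-permutation test of GWAS-signal enrichment
#'
#' The squared t-statistics of all variants are ranked by physical
#' position, chromosomes concatenated in layout order. Each permutation
#' picks a random statistic to become the first and shifts the rest,
#' preserving their order - a rotation of the vector - and recomputes the
#' sum over the feature's (fixed) variant positions. The empirical p-value
#' is `(r + 1) / (n_perm + 1)` where `r` counts rotations with a statistic
#' greater than or equal to the observed one; the add-one correction keeps
#' p strictly positive. When the number of variants does not exceed
#' `nPerm`, all `n - 1` nontrivial rotations are enumerated exactly
#' instead of sampled (flagged by `exhaustive`).
#'
#' @param stats sorted variant `GRanges` (all traits' variants must share
#'   one genome order; pass one trait at a time).
#' @param feature `GRanges` feature set.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed for the sampled mode.
#' @param featureName label carried into the result.
#' @return a one-row `data.frame`: `trait`, `feature`, `mF`, `tSum`,
#'   `nPerm`, `nGe`, `pEmp`, `exhaustive`, `testable`.
#' @export
cyclicPermutationTest <- function(stats, feature, nPerm = 10000L, seed = 1L,
                                  featureName = "feature") {
  n <- length(stats)
  if (n < 2L) stop("need at least two variants")
  trait <- if (length(unique(mcols(stats)$trait)) == 1L)
    mcols(stats)$trait[1L] else "mixed"
  obs <- sumStatistic(stats, feature)
  if (!obs$testable) {
    return(data.frame(trait = trait, feature = featureName, mF = 0L,
                      tSum = NA_real_, nPerm = 0L, nGe = NA_integer_,
                      pEmp = NA_real_, exhaustive = NA, testable = FALSE))
  }
  v <- mcols(stats)$t2
  idx <- which(countOverlaps(stats, reduce(feature, ignore.strand = TRUE),
                             ignore.strand = TRUE) > 0L)
  exhaustive <- n <= nPerm
  ks <- if (exhaustive) seq_len(n - 1L) else {
    set.seed(seed)
    sample.int(n - 1L, nPerm, replace = TRUE)
  }
  # chunk the rotation-offset axis to bound the index matrix at ~1e7 cells
  chunk <- max(1L, floor(1e7 / length(idx)))
  nGe <- 0L
  for (i in seq(1L, length(ks), by = chunk)) {
    sums <- .rotationSums(v, idx, ks[i:min(i + chunk - 1L, length(ks))])
    nGe <- nGe + sum(sums >= obs$tSum)
  }
  nUsed <- length(ks)
  data.frame(trait = trait, feature = featureName, mF = obs$mF,
             tSum = obs$tSum, nPerm = nUsed, nGe = nGe,
             pEmp = (nGe + 1) / (nUsed + 1), exhaustive = exhaustive,
             testable = TRUE)
}

#' Enrichment panel over traits and feature sets
#'
#' Runs [cyclicPermutationTest()] for every combination of trait and
#' feature set, with a deterministic per-combination seed stream derived
#' from `seed`. Untestable features (no variant inside) propagate as
#' marked rows rather than errors.
#'
#' @param statsByTrait named list of sorted variant `GRanges`, one per
#'   trait.
#' @param featureSets named list of feature `GRanges`.
#' @param nPerm,seed as in [cyclicPermutationTest()].
#' @return a `data.frame`, one row per (trait, feature set).
#' @export
enrichmentPanel <- function(statsByTrait, featureSets, nPerm = 10000L,
                            seed = 1L) {
  if (!length(statsByTrait) || !length(featureSets))
    stop("need at least one trait and one feature set")
  rows <- list(); k <- 0L
  for (tr in names(statsByTrait)) for (fs in names(featureSets)) {
    k <- k + 1L
    res <- cyclicPermutationTest(statsByTrait[[tr]], featureSets[[fs]],
                                 nPerm = nPerm, seed = seed + k,
                                 featureName = fs)
    res$trait <- tr
    rows[[k]] <- res
  }
  do.call(rbind, rows)
}
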