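# Partially-methylated-domain (PMD) detection: non-overlapping 20-kb
# windows binarized at a 60% methylation threshold, decoded per chromosome
# by a two-state Bernoulli HMM (Baum-Welch fit, Viterbi decode), then a
# base-wise multi-sample consensus.

#' Binarize a methylome into fixed windows
#'
#' Tiles every chromosome from position 0 into non-overlapping windows and
#' assigns each window the pooled methylation level of its covered CpGs.
#' Symbols follow a strict-threshold rule: 1 when the level is greater than
#' `levelThreshold`, 0 when less than or equal, `NA` when the window holds
#' no covered CpG.
#'
#' @param sample a [Methylome-class]; CpGs below 5x coverage should already
#'   have been removed on read (`readCpGCalls(minCoverage = 5)`).
#' @param params a [PmdParams-class].
#' @param layout optional `Seqinfo`; defaults to the sample's.
#' @return a `GRanges` of windows with metadata columns `level` and
#'   `symbol` (integer 0/1/NA).
#' @export
binarizeWindows <- function(sample, params = pmdParams(), layout = NULL) {
  gr <- calls(sample)
  if (is.null(layout)) layout <- seqinfo(gr)
  if (any(is.na(seqlengths(layout))))
    stop("binarizeWindows needs chromosome lengths (a genome layout)")
  tiles <- GenomicRanges::tileGenome(seqlengths(layout),
                                     tilewidth = params@window,
                                     cut.last.tile.in.chrom = TRUE)
  hits <- findOverlaps(gr, tiles, ignore.strand = TRUE)
  mSum <- rep(0, length(tiles)); tSum <- rep(0, length(tiles))
  if (length(hits)) {
    mm <- rowsum(as.numeric(mcols(gr)$nMeth[queryHits(hits)]), subjectHits(hits))
    tt <- rowsum(as.numeric(mcols(gr)$nTotal[queryHits(hits)]), subjectHits(hits))
    ix <- as.integer(rownames(mm))
    mSum[ix] <- mm[, 1L]; tSum[ix] <- tt[, 1L]
  }
  level <- ifelse(tSum > 0, mSum / tSum, NA_real_)
  symbol <- ifelse(is.na(level), NA_integer_,
                   as.integer(level > params@levelThreshold))
  mcols(tiles) <- DataFrame(level = level, symbol = symbol)
  tiles
}

# --- two-state Bernoulli HMM ------------------------------------------------
# state 1 = background (emits 1 with prob eB), state 2 = PMD (emits 0 with
# prob eP). Missing symbols contribute no emission term.

.hmmEmission <- function(sym, eB, eP) {
  # returns n x 2 matrix of emission probabilities; 1 for missing symbols
  E <- matrix(1, length(sym), 2L)
  obs <- !is.na(sym)
  E[obs, 1L] <- ifelse(sym[obs] == 1L, eB, 1 - eB)
  E[obs, 2L] <- ifelse(sym[obs] == 0L, eP, 1 - eP)
  E
}

.hmmForwardBackward <- function(sym, par) {
  n <- length(sym)
  E <- .hmmEmission(sym, par$eB, par$eP)
  A <- par$A
  alpha <- matrix(0, n, 2L); beta <- matrix(0, n, 2L); scal <- numeric(n)
  a <- par$start * E[1L, ]
  scal[1L] <- sum(a); alpha[1L, ] <- a / scal[1L]
  if (n > 1L) for (t in 2:n) {
    a <- (alpha[t - 1L, ] %*% A)[1L, ] * E[t, ]
    scal[t] <- sum(a); alpha[t, ] <- a / scal[t]
  }
  beta[n, ] <- 1
  if (n > 1L) for (t in (n - 1L):1L) {
    beta[t, ] <- (A %*% (E[t + 1L, ] * beta[t + 1L, ]))[, 1L] / scal[t + 1L]
  }
  list(alpha = alpha, beta = beta, scal = scal, E = E,
       loglik = sum(log(scal)))
}

.hmmFit <- function(sym, maxIter = 100L, tol = 1e-6) {
  par <- list(eB = 0.9, eP = 0.9, A = matrix(c(0.9, 0.1, 0.1, 0.9), 2L, 2L,
                                             byrow = TRUE),
              start = c(0.5, 0.5))
  prev <- -Inf
  for (it in seq_len(maxIter)) {
    fb <- .hmmForwardBackward(sym, par)
    gamma <- fb$alpha * fb$beta
    gamma <- gamma / rowSums(gamma)
    n <- length(sym)
    if (n > 1L) {
      xi11 <- xi12 <- xi21 <- xi22 <- 0
      for (t in seq_len(n - 1L)) {
        x <- outer(fb$alpha[t, ], fb$E[t + 1L, ] * fb$beta[t + 1L, ]) *
          par$A / fb$scal[t + 1L]
        xi11 <- xi11 + x[1L, 1L]; xi12 <- xi12 + x[1L, 2L]
        xi21 <- xi21 + x[2L, 1L]; xi22 <- xi22 + x[2L, 2L]
      }
      A <- matrix(c(xi11, xi12, xi21, xi22), 2L, 2L, byrow = TRUE)
      A <- A / rowSums(A)
    } else A <- par$A
    obs <- !is.na(sym)
    eB <- sum(gamma[obs & sym == 1L, 1L]) / max(sum(gamma[obs, 1L]), 1e-12)
    eP <- sum(gamma[obs & sym == 0L, 2L]) / max(sum(gamma[obs, 2L]), 1e-12)
    clamp <- function(x) min(max(x, 1e-6), 1 - 1e-6)
    par <- list(eB = clamp(eB), eP = clamp(eP),
                A = pmin(pmax(A, 1e-6), 1 - 1e-6), start = gamma[1L, ])
    par$A <- par$A / rowSums(par$A)
    par$start <- par$start / sum(par$start)
    if (abs(fb$loglik - prev) < tol) break
    prev <- fb$loglik
  }
  par
}

.hmmViterbi <- function(sym, par) {
  n <- length(sym)
  E <- log(.hmmEmission(sym, par$eB, par$eP))
  lA <- log(par$A)
  delta <- matrix(-Inf, n, 2L); psi <- matrix(1L, n, 2L)
  delta[1L, ] <- log(par$start) + E[1L, ]
  if (n > 1L) for (t in 2:n) for (s in 1:2) {
    cand <- delta[t - 1L, ] + lA[, s]
    psi[t, s] <- which.max(cand)
    delta[t, s] <- cand[psi[t, s]] + E[t, s]
  }
  states <- integer(n)
  states[n] <- which.max(delta[n, ])
  if (n > 1L) for (t in (n - 1L):1L) states[t] <- psi[t + 1L, states[t + 1L]]
  states
}

#' Decode per-sample PMDs from a binarized window track
#'
#' Fits a two-state Bernoulli HMM per chromosome by Baum-Welch (background
#' state emitting 1 with probability 0.9, PMD state emitting 0 with
#' probability 0.9, self-transitions 0.9, uniform start; at most `maxIter`
#' iterations, log-likelihood tolerance `tol`) and decodes with Viterbi.
#' Maximal runs of the PMD state spanning at least `minWindows` windows
#' become intervals from the first window start to the last window end.
#' Missing windows contribute no emission term and do not break runs. A
#' chromosome whose observed symbols are all identical cannot identify two
#' states; it falls back to literal runs of 0 symbols (with a notice).
#'
#' @param track window `GRanges` from [binarizeWindows()].
#' @param params a [PmdParams-class].
#' @return a `GRanges` of per-sample PMD intervals.
#' @export
decodePmdStates <- function(track, params = pmdParams()) {
  out <- list()
  for (chr in seqlevels(track)) {
    w <- track[seqnames(track) == chr]
    if (!length(w)) next
    sym <- mcols(w)$symbol
    obs <- sym[!is.na(sym)]
    if (length(obs) < params@minWindows) next
    if (length(unique(obs)) < 2L) {
      message("chromosome ", chr, ": single observed symbol; ",
              "falling back to threshold runs")
      pmdState <- !is.na(sym) & sym == 0L
    } else {
      par <- .hmmFit(sym, params@maxIter, params@tol)
      states <- .hmmViterbi(sym, par)
      # identify the PMD state as the one more likely to emit 0
      pmdIdx <- if ((1 - par$eB) >= par$eP) 1L else 2L
      pmdState <- states == pmdIdx
    }
    r <- rle(pmdState)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= params@minWindows
    if (!any(keep)) next
    out[[chr]] <- GRanges(chr,
                          IRanges(start(w)[starts[keep]], end(w)[ends[keep]]),
                          seqinfo = seqinfo(track))
  }
  if (!length(out)) return(GRanges(seqinfo = seqinfo(track)))
  GenomicRanges::sort(do.call(c, unname(out)), ignore.strand = TRUE)
}

#' Form consensus PMDs across samples
#'
#' Keeps the bases covered by per-sample PMDs in at least `minSupport`
#' samples (base-wise support depth, robust to ragged per-sample
#' boundaries), then retains each resulting run only when it spans at
#' least `minWindows` complete windows of the genome-wide grid.
#'
#' @param perSample list of per-sample PMD `GRanges` from
#'   [decodePmdStates()].
#' @param params a [PmdParams-class].
#' @param layout a `Seqinfo`.
#' @return a `GRanges` of consensus PMDs.
#' @export
consensusPmds <- function(perSample, params = pmdParams(), layout = NULL) {
  if (length(perSample) < params@minSupport)
    stop("need at least minSupport (", params@minSupport, ") samples")
  grl <- GenomicRanges::GRangesList(lapply(perSample, granges))
  if (is.null(layout)) layout <- seqinfo(grl)
  cov <- coverage(grl)
  core <- GRanges(cov >= params@minSupport)
  core <- core[mcols(core)$score]
  mcols(core) <- NULL
  if (!length(core)) return(GRanges(seqinfo = layout))
  # complete grid windows (width params@window, tiled from 0) inside the run
  s0 <- start(core) - 1L; e0 <- end(core)
  nWin <- floor(e0 / params@window) - ceiling(s0 / params@window)
  core <- core[nWin >= params@minWindows]
  seqlevels(core) <- seqlevels(layout)
  seqinfo(core) <- layout
  GenomicRanges::sort(core, ignore.strand = TRUE)
}
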