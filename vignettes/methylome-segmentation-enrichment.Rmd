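---
title: "Methylome segmentation and GWAS-signal enrichment: models and design choices"
author: "methylomeGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome segmentation and GWAS-signal enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylomeGWAS)
library(GenomicRanges)
```

# Scope and data model

The package analyses CpG-resolution methylation count data from
whole-genome bisulfite sequencing: for each sample and CpG position, a
methylated read count and a total read count. Upstream read processing
(trimming, bisulfite alignment, methylation extraction) is out of scope;
the entry point is a Bismark-coverage-style table read by
`readCpGCalls()`. Genomic coordinates live in `GRanges` (1-based closed,
the Bioconductor convention); on disk, call tables are 1-based and BED
files 0-based half-open, with conversion handled by the readers and
writers. Rows of the input file are the unit of analysis: calls on the
two strands of a CpG are not merged, and no destranding option is
exposed, since CpG loci on both strands are counted as they arrive.

The chromosome order of the genome layout (`genomeLayout()`, a `Seqinfo`)
is fixed and shared by all position-sorted traversals. This matters for
one statistic in particular: the cyclical permutation of GWAS test
statistics rotates a single genome-wide vector formed by concatenating
chromosomes in layout order, so the layout is an explicit argument rather
than an implicit lexicographic sort.

# Hypomethylated regions

A CpG with pooled level strictly below `hypoLevel` (default 0.20) is
*hypomethylated*. Any 200-bp window on the 50-bp grid whose covered CpGs
are at least 80% hypomethylated (and at least one CpG) seeds a region;
the span extends rightward in 50-bp steps while the criterion holds over
the whole extended span. The sliding-window rule leaves seeding and
termination open to interpretation; the package fixes:

* seeds slide at step resolution, so every grid position is a candidate —
  extension is rightward only, because leftward growth is captured by the
  seeds that start further left;
* the failing extension step is not included;
* accepted spans are trimmed to their outermost hypomethylated CpGs, so
  reported boundaries are data-supported rather than grid-aligned;
* overlapping and abutting spans are merged before the `minCpgs` filter
  (default 5 CpGs at ≥ 5× pooled coverage).

These choices make the procedure deterministic and order-independent, and
on contiguous hypomethylated blocks they recover exactly the block's CpG
support (verified against a brute-force scan over all window placements
in the test suite). Note one deliberate non-invariant: a reported HMR's
*mean* level can exceed `hypoLevel`, because the 80% rule tolerates a
minority of methylated CpGs; the guaranteed invariant is the
hypomethylated fraction.

Group-level HMR sets are produced by pooling counts across the group's
samples (`poolGroup()`), not by intersecting per-sample calls: a single
HMR set per animal group is wanted, pooling is commutative in the sample
order, and it uses all reads at boundary CpGs. Coverage thresholds are
applied as ≥ 5× throughout.

# Partially methylated domains

Each chromosome is tiled into non-overlapping 20-kb windows; a window's
level is the pooled count ratio of its CpGs (≥ 5× coverage). Windows with
level strictly greater than 60% become symbol 1, otherwise 0; windows
without covered CpGs are missing. A two-state hidden Markov model on the
binary symbols — background emitting 1 with probability `e_B`, PMD
emitting 0 with probability `e_P` — is fitted per chromosome by
Baum–Welch from a fixed initialization (`e_B = e_P = 0.9`,
self-transitions 0.9, uniform start; at most 100 iterations, tolerance
1e-6 on the log-likelihood) and decoded with Viterbi. The emission model,
fitting and decoding are the package's own concrete choices; they are the
smallest set of decisions consistent with "an HMM on 0/1 window labels",
and decoding is oracle-tested against exhaustive enumeration of all state
paths on short chromosomes. Posterior decoding would be a defensible
alternative; Viterbi was chosen because domains are reported as intervals
and the most-likely path cannot produce sub-threshold-length state
flickers that posterior marginals can.

Three robustness details:

* missing windows contribute no emission term but do not break a run, so
  coverage gaps inside a large domain do not split it;
* after fitting, the PMD state is identified as the state more likely to
  emit 0, guarding against label switching;
* a chromosome whose observed symbols are all identical cannot identify
  two states; it falls back to literal runs of 0 symbols, with a notice.

Per-sample domains are maximal PMD-state runs spanning at least
`minWindows = 3` windows (≥ 60 kb). The multi-sample consensus keeps the
bases supported by at least `minSupport = 3` samples — a base-wise depth
rule, robust to ragged per-sample boundaries — and then re-applies the
three-window length filter to the resulting runs (intersect first, filter
second).

# Tile-based differential methylation

The genome is tiled into 500-bp windows (`unit = "cpg"` gives per-CpG
units instead) and each sample's counts are summed per tile. A tile is
tested when every sample in the comparison has at least one read and each
group's pooled depth is at least 10 reads; this gate keeps the GLM
well-posed and is applied at test time, when groups are known. The test
is the binomial logistic regression `logit(π_j) = β₀ + β₁ g_j` over
samples `j`, compared to the intercept-only null by a likelihood-ratio
χ² with one degree of freedom. Because the group covariate is binary, the
alternative model's MLE is the pair of pooled group proportions and both
log-likelihoods are evaluated in closed form from pooled counts — the
same fit the iterative GLM would reach, without per-tile IRLS. No
overdispersion correction is applied (a known limitation shared with the
default logistic test of tile-based DMR callers); between-sample
variation beyond binomial sampling will inflate the test.

Multiple testing uses Benjamini–Hochberg step-up q-values over the tested
units. Adaptive q-value estimators that rescale by an estimated null
proportion exist; BH is the standard, conservative choice, and a
π₀-scaled variant (Storey estimate at λ = 0.5) is exposed as
`adjustQ(method = "pi0")`. DMR calling is strict on both thresholds:
`q < qCutoff` and `|diff.meth| > 5` percentage points, with gain and loss
partitioning the whole set by the sign of the pooled-proportion
difference.

# GWAS marker-set enrichment

For a merged feature set, `T_sum` adds `t² = (b/se)²` over the variants
whose position lies inside the features (half-open containment, so a
variant sitting exactly on a BED end coordinate is outside). The null
rotates the genome-ordered t² vector: offset `k` is drawn uniformly from
`1 … n−1`, each variant keeps its position, and the statistic is
recomputed from the rotated values. Rotation preserves the multiset of
statistics and their local correlation while uncoupling them from the
features. The empirical p-value uses `≥` in the tail and the add-one
correction `(r + 1)/(n_perm + 1)`, so p is never zero; with a one-tailed
"proportion greater than observed" rule the only difference is at
rotation ties, where the chosen rule is the conservative one. When
`n ≤ n_perm` all `n − 1` nontrivial rotations are enumerated exactly and
the result is flagged `exhaustive`, making toy-scale analyses fully
deterministic.

# Hypergeometric set enrichment

The count-based window-set test maps each tested tile to the GO terms of
the genes it overlaps after extending genes by 10 kb on both sides
(regulatory flank); terms with fewer than 10 annotated genes are dropped.
With `m` tested windows, `m_g` of them differential (`p < p₀ = 0.01`)
genome-wide and `m_f` mapped to a term, the number of differential
windows in the term is referred to `Hyper(m, m_g, m_f)`, upper tail
(one-sided enrichment). Defining `m_g` as the number of *tested* windows
below `p₀` keeps the margins of the 2×2 table consistent — the only
reading under which the statistic is hypergeometric. Tails are computed
through `phyper(log.p = TRUE)`, so extreme enrichment survives floating
point (results carry both `p` and `log10p`). The gene-list variant
(`geneSetEnrichment`) is the ordinary upper-tail hypergeometric against a
gene universe with BH FDR across terms.

# Integration analyses

* `globalMethylationTest()` restricts to CpGs covered in every sample of
  both groups and t-tests the per-locus difference of pooled group
  levels. The test is paired across loci by default — the comparison is
  across the *common* loci, which makes the paired form natural — with an
  unpaired option. Identical groups return `t = 0, p = 1` rather than an
  error from zero variance.
* `overlapFisher()` is the one-sided Fisher exact test (hypergeometric
  upper tail, log space) that two DMR sets share more tiles of their
  common universe than expected; the direction is deliberate, since the
  claim tested is "more often than expected", and at extreme tails the
  two-sided value is numerically indistinguishable.
* `gainLossComparison()` is a two-sided Mann–Whitney test with exact
  enumeration when both panels have at most 10 untied values, otherwise
  the normal approximation with tie and continuity correction.
* `candidateGeneTable()` keeps tiles significant and *gaining* in both
  comparisons, assigns them to genes by gene-body or promoter overlap,
  and scans each trait's variants near the gene. The promoter extent
  (2 kb upstream of the TSS, strand-aware) and the variant search window
  (gene span ± 250 kb) are not dictated by the method and are exposed as
  arguments; the defaults are ordinary values for mammalian annotation,
  and the table reports one row per gene-trait pair carrying the gene's
  most significant DMR.

# The synthetic generator

`simulateMethylomes()` draws CpG positions with geometric spacing (mean
100 bp) and, per CpG and sample, a read depth from a Poisson(10)
truncated at ≥ 1 and a methylated count from a binomial at the local
level: 0.75 baseline, 0.05 in planted hypomethylated blocks, 0.40 in
planted domains, and group-specific levels in planted differential tiles.
Planted hypomethylated blocks carry denser, CpG-island-like spacing
(mean 20 bp), reflecting that real HMRs coincide with CpG-dense
regulatory elements; without this, boundary CpG sparsity — not the
detector — would dominate recovery scores. The truncated-Poisson coverage
model is deliberately simpler than a negative binomial (a dispersion knob
exists but defaults off): it is sufficient to exercise the coverage
filters, which is its purpose. GWAS statistics are simulated directly on
the t-scale (`b = t`, `se = 1`, `t ~ N(δ·1[inside], 1)`): the enrichment
test consumes only t², so genotypes and LD structure would add nothing to
what the test can see. A single seed drives all substreams.

What passing tests on this generator do **not** show about real data:
there is no linkage disequilibrium among variants, no spatial correlation
of methylation beyond the planted blocks, no between-sample biological
variability beyond binomial sampling (so the un-overdispersed tile test
is exactly calibrated here but may not be on real animals), and no
strand- or repeat-structure in CpG placement. Recovery scores are always
computed against the planted truth record, never against re-derived
features.

# Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately small
genomes chosen so each property is measured at adequate precision while
the whole suite stays fast: 100-Mb single-chromosome layouts with 10⁵
variants for the permutation calibration (200 features × 1,000 rotations)
and power (50 replicate seeds), 0.3–5-Mb layouts for segmentation and
tile-test recovery (20 replicate seeds each), and a two-chromosome 3.2-Mb
genome for the end-to-end pipeline. Empirical tolerances follow the
binomial standard error of the quantity being estimated (e.g. ±0.02 for
a rejection rate near 0.05 estimated from 200 features). Other numerical
details: binomial log-likelihoods treat `0·log 0` as 0; the
likelihood-ratio statistic is clamped at 0 against floating-point
negatives; Baum–Welch emission and transition estimates are clamped to
`[1e-6, 1 − 1e-6]`; Viterbi ties break toward the background state;
hypergeometric tails use log-gamma throughout.

# Known limitations

Binomial (not beta-binomial) tile testing; no covariate adjustment or
paired designs; BH rather than adaptive q-values by default; HMRs are
detected on pooled groups only; the GO map is a flat two-column table
with no ontology-graph propagation; and the pipeline driver is a
single-process reference implementation.
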