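---
title: "Methods: stability estimation, reference-set selection and ddCt quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability estimation, reference-set selection and ddCt quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoref)
```

# Scope and data model

`endoref` screens candidate endogenous normalizer (EN) miRNAs for RT-qPCR.
Raw data enter as tidy replicate-level Cq tables (`cq_table`); technical
replicates are collapsed by arithmetic mean of Cq (`collapse_replicates()`),
which on the linear expression scale is the geometric mean — the standard
convention for log-domain qPCR data. Cells whose replicate SD exceeds a
threshold (default 0.5 Cq) are flagged but not removed; the flag threshold
is a QC convention of this package, not an established standard, and is
configurable. Undetected (missing-Cq) wells are dropped with a warning and
the stability estimators subset to samples measured for every candidate,
reporting the retained size.

Sequencing data enter as counts-scale `expression_matrix` objects. The
expressed-gene filter keeps genes at CPM >= 1 in at least half the samples;
this is a conventional choice — abundance filters differ between studies
and the exact rule behind any particular published candidate count is
generally not recoverable, so the parameters are exposed rather than fixed.
The log transform is `log2(CPM + 1)`: CPM guards against library-size
artifacts, the pseudocount keeps zeros finite, and the log2 scale makes
count data commensurable with Cq data (one PCR cycle = one doubling, so Cq
is itself a log2 signal, up to sign and an additive constant).

# The four stability estimators

All four treat the candidate panel as a genes x samples matrix of
log2-scale signals (Cq used as-is; the efficiency-2 equivalence is assumed
throughout).

**NormFinder-style score.** The published NormFinder is a model-based
variance-decomposition estimator. We fit its core two-way additive model
`signal = gene effect + sample effect + residual` by row/column mean
centering and score each gene by the sample SD (n-1) of its residuals. This
omits the published small-sample bias correction; on well-conditioned data
the ranking is equivalent, and the simple form is exactly testable against
a brute-force oracle (the package's tests do exactly that). The grouped
variant scores `sqrt(mean intragroup residual variance + variance of the
gene's group-mean residuals)`, a documented simplification of the published
intra/intergroup combination. The default is ungrouped, matching the common
practice of assessing stability across all samples; the grouped mode is an
option.

**geNorm.** Pairwise variation `V(j,k)` is the SD across samples of the
per-sample difference `Cq_k − Cq_j` (the SD of log2 expression ratios at
efficiency 2), and `M_j` is the mean over partners. Ranking uses geNorm's
stepwise exclusion. Classic geNorm leaves the final two genes tied; we
order them by their last-round M (tie broken by gene id) so the ranking is
total — a deliberate deviation, because the comprehensive score needs a
rank for every gene.

**BestKeeper.** Descriptive statistics on *raw Cq*: per-gene dispersion
(sample SD by default — the convention of comprehensive-ranking tools — or
the original mean absolute deviation via `dispersion = "mad"`), CV%, and
Pearson correlation with the BestKeeper index (per-sample mean Cq).
BestKeeper is deliberately *not* invariant to per-sample shifts; the test
suite asserts this as a behavioural contrast with the other three methods,
which are exactly shift-invariant because shifts cancel in differences and
are absorbed by the sample effect.

**Comparative ΔCt.** The mean over partners of the SD of pairwise Cq
differences. On a full panel this coincides numerically with the geNorm M
value (asserted as a regression test); the two diverge once geNorm's
stepwise exclusion reranks genes, which is why both are kept.

**Comprehensive score.** Per-method ranks (ascending score, ties share the
minimum rank; geNorm contributes its stepwise ranking) are aggregated by
geometric mean. The score is bounded by the minimum and maximum of the four
ranks and equals 1 only for a unanimous winner. Final ties break by gene
name — an arbitrary but deterministic rule.

# Iterative reference-set selection

The greedy algorithm answers "how many ENs should be combined?". Iteration
1 selects the single most stable gene. At iteration k+1, each remaining
candidate c is averaged into the current set S_k on the log2 scale
(geometric mean of linear expression — matching the log-domain model the
scorer assumes; arithmetic-mean-of-linear averaging is available via
`average_scale = "linear"`), and the pseudo-gene is scored within a
background of all genes outside S_k ∪ {c} plus the pseudo-gene itself. The
members are removed from the background so a combination is never scored
against its own constituents, which would deflate its apparent stability;
retaining them is available as a flag (`retain_members`) for comparison
with implementations that append rather than replace. The candidate with
the lowest pseudo-gene score joins the set; ties break by gene id, so the
procedure is fully deterministic and two runs on the same input produce
identical traces.

The trace records the per-iteration minimum (the best attainable set of
that size) and the mean over candidates (the background level).
`suggest_set_size()` reports the smallest k whose relative gain in minimum
score falls below 5% (default). Two caveats, visible in the package's own
examples: the minimum score is *not* guaranteed monotone (each iteration
scores against a different background), so negative gains are clamped to
zero; and on easy synthetic data the curve can be flat from k = 1, in which
case the suggestion is 1 and the full trace — not the single number — is
the meaningful output. The default cap of 100 genes is far beyond any
practical RT-qPCR panel and exists only to bound the run.

# Standard curves, ΔΔCt and group uniformity

Efficiency comes from OLS of mean Cq on log10(dilution):
`E% = (10^(−1/slope) − 1)·100`, reported rounded to the nearest integer
(the conventional reporting precision; the raw value is retained). R² is
computed directly as 1 − SSE/SST. Efficiency is reported for QC against
the 90–110% acceptance window but deliberately *not* used to correct ΔΔCt:
quantification uses the efficiency-2 model throughout, and
efficiency-corrected ratios are out of scope.

Relative quantification aggregates references by arithmetic mean of Cq
(geometric mean of expression — the standard multi-reference convention),
normalizes per sample (`dCq`), and calibrates against the mean dCq of a
designated calibrator group. The group comparison uses a two-tailed
Student's t-test on dCq (equal variance by default; Welch via flag). When
both groups have constant dCq the test statistic is 0/0; p = 1 is reported
by convention (no evidence of a difference). Groups with fewer than two
samples skip the test with a warning rather than failing the run.

The group-uniformity screen runs a per-gene one-way ANOVA of mean Cq across
material-type groups with Benjamini–Hochberg adjustment across genes. A
gene with no variance at all has an undefined F statistic; it is reported
with p = 1 and flagged `degenerate` (the practically relevant reading: a
perfectly constant candidate is uniform across groups).

# Sequence-similarity screen

Mature miRNA sequences are globally aligned (Needleman–Wunsch, linear gap
penalty, deterministic traceback preferring diagonal over up over left).
The default scoring (+1 match / −1 mismatch / −2 gap) is this package's
own choice — published screens typically use library defaults that vary —
so the headline statistic is percent identity (matches / alignment columns,
gaps included), which is robust to the scoring parameters; the raw score
and the parameters are nevertheless exposed. Seed identity compares
positions 2–7 (1-based, inclusive) and reports only perfect matches. DNA
FASTA input is converted T to U with a warning. Expression correlation
(Pearson, log2 scale) complements the sequence evidence: a highly similar
pair whose assays also produce correlated signals is the classic signature
of cross-hybridization inflating probe-based fold changes relative to
sequencing-based ones.

# Synthetic data: what it emulates and what it does not

`simulate_cq_dataset()` generates
`Cq = baseline_g + shift_s + group effect + N(0, σ_g) + N(0, σ_tech)`:
per-gene baselines (uniform 20–27 Cq, the abundant-miRNA window),
per-sample shifts common to all genes (RNA input / RT variation), planted
stable genes (σ = 0.05, no group effect), noisy genes (σ = 0.6), and
overexpressed genes (−2 Cq, i.e. +2 log2, in the first group). The default
design uses four unbalanced groups of 34/5/4/9 samples, echoing a realistic
patients / controls / tissue / cell-line split, with 3 technical
replicates. `simulate_count_dataset()` draws negative-binomial counts with
lognormal library sizes; stable genes keep constant relative abundance and
low dispersion, other genes get lognormal per-sample abundance jitter.
DE-gene base abundances are scaled down tenfold before renormalization:
validated target miRNAs are rarely library-dominating species, and without
this the compositional nature of CPM can push a planted fold change
visibly below its nominal value. `simulate_dilution_series()` uses the
closed form `Cq(d) = intercept − log10(d)/log10(1 + E)` plus Gaussian
noise.

All generators are pure functions of (parameters, seed): the RNG state is
set locally and restored, and the ground truth is returned (and serialized
to JSON by the CLI) alongside every dataset.

For the planted-recovery acceptance scenario (3 stable genes, σ = 0.05,
among 12 noisy, σ = 0.6, 20 samples) the per-sample shift SD is set to 0.2
and the replicate SD to 0.1 — a well-controlled single-plate validation
experiment. This choice was made a priori for a specific reason: BestKeeper
scores total raw-Cq dispersion, so large loading shifts (which the other
three estimators cancel exactly) add shared variance plus gene-specific
shift-noise covariance terms that can scramble its ranking at n = 20
regardless of the planted structure. The scenario is meant to test recovery
of planted gene-level noise, not BestKeeper's known shift sensitivity —
which has its own dedicated contrast test.

What a green synthetic-recovery test does **not** establish: that the
estimators agree on real data (real candidate panels violate the additive
model through co-regulation and amplification artifacts), that the
expressed-gene filter reproduces any particular published candidate count,
or that the four methods' published software implementations would produce
identical numbers (bias corrections and tie conventions differ, as
documented above). Patient-data-dependent results are out of reach of a
synthetic harness by construction.

# Numerical conventions

- Sample SD uses the n−1 denominator everywhere; a single replicate has
  SD 0 by definition.
- Rank ties share the minimum rank; orderings that must be total
  (greedy selection, geNorm stepwise, comprehensive rank) break ties by
  gene id.
- Efficiencies are rounded half-to-even to integers for reporting only.
- Validation failures raise classed conditions
  (`endoref_validation_error`, `endoref_format_error`, ...) that the CLI
  maps to exit codes (1 validation, 2 usage).

# Known limitations

- The NormFinder score is the uncorrected two-way residual SD; the
  published bias-corrected model can reorder genes on very small panels.
- geNorm's V(n/n+1) cutoff for the number of genes is intentionally
  omitted; set size is decided by the iterative greedy trace instead.
- No efficiency-corrected (Pfaffl-type) quantification, no outlier-robust
  curve fitting, no RDML or vendor binary formats, no affine-gap
  alignment, no read-level sequencing simulation.
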