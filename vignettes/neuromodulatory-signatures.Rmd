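---
title: "Methods: type-mean signatures, delta, and the simulated world"
author: "neurosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: type-mean signatures, delta, and the simulated world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurosig)
```

# The analysis model

`neurosig` quantifies how specifically genes are expressed across a fixed
hierarchical taxonomy of neuron types. The taxonomy is an *input*: the
package deliberately performs no clustering, no differential-expression
testing and no batch correction. The pipeline is

1. **Cell curation.** Keep cells sampled from the target region (default
   `"CA1"`), then keep leaf types represented by at least
   `min_cells_per_type` such cells (default 16, *inclusive*: a type with
   exactly 16 cells is retained). Types below the minimum are dropped
   because their mean estimates are too noisy to interpret.
2. **CPM normalization.** Each cell's counts are scaled to sum to 10^6.
   The denominator is the total over *all* genes present in the supplied
   matrix; consequently any panel subsetting must happen after
   normalization. If the supplied matrix covers only part of the
   transcriptome, CPM values are inflated by the inverse of the covered
   fraction — a dependence the user must be aware of when comparing
   absolute CPM levels across datasets.
3. **Type-mean signatures.** For each gene, the vector of arithmetic mean
   CPM values across retained types. Means are *untrimmed*: outlying cells
   are flagged (below) but never removed, keeping the estimator simple and
   the diagnostics honest.
4. **Gene filter.** A gene is called expressed when its maximum type-mean
   CPM is strictly greater than `expression_threshold` (default 10).
   Strictness matters at the boundary: a peak of exactly 10 CPM is *not*
   expressed. The same strict `>` is used for per-cell co-expression
   tallies, with one shared threshold parameter.
5. **Delta.** For type means $\mu_1,\dots,\mu_n$ with maximum $\mu_{max}$:
   $$\delta = \frac{n - \sum_{i=1}^{n} \mu_i/\mu_{max}}{n-1}.$$
   $\delta = 0$ iff all means are equal; $\delta = 1$ iff exactly one mean
   is nonzero. Delta is invariant to positive rescaling and to permutation
   of the types, and equals the tissue-specificity index $\tau$. It is a
   *descriptive* index: no sampling distribution is attached to it.

## Assumptions

* Cell-type assignments are taken as given and error-free.
* CPM is an adequate normalization for the comparisons made (within-gene,
  across types of the same dataset). No gene-length correction is applied,
  so cross-gene comparisons of absolute CPM carry the usual caveat.
* Means are meaningful summaries of within-type expression; multimodal
  within-type distributions are surfaced by the diagnostics rather than
  modeled.

# Numerical and edge-case choices

* **$\mu_{max} = 0$ genes.** Delta divides by $\mu_{max}$, so a gene
  undetected in every type has no defined specificity. It is reported as
  `NA` and excluded from display ordering — never coerced to 0, which would
  confuse "undetected" with "perfectly uniform".
* **Display order.** Rows are sorted by descending delta; ties break by
  descending $\mu_{max}$, then lexicographic symbol, making figures and CSV
  outputs fully deterministic.
* **log(rowmax).** Reported as log10 of $\mu_{max}$; undefined for
  all-zero rows.
* **No pseudocounts.** Nothing is added before logs in the statistics
  themselves; the only log transform (outlier fence) uses `log2(CPM + 1)`
  explicitly as a display/robustness scale.
* **Quantiles.** All quantile-based rules use linear interpolation
  (`stats::quantile` type 7). The outlier fence depends on this choice, so
  it is fixed and tested against an independent interpolation oracle.
* **Type means are bitwise `mean()`.** `type_means()` computes each
  gene × type mean with base `mean()` on the exact cell subset, so results
  are bit-identical to a naive group-by — no clever-but-reordered summation.
* **Mode tie-break.** Co-expression histograms report the *smallest* count
  attaining the maximal frequency. Any rule would do; this one is
  deterministic and conservative.
* **Idempotence.** `to_cpm()` on an already-CPM matrix is the identity;
  re-running any stage on identical inputs writes identical outputs.

# Operational outlier definitions

Within-type distribution anomalies are often called by eye. For
testability `neurosig` fixes explicit rules, exposed as parameters of
`flag_outliers()` — these are definitions of this package, not claims about
any particular dataset:

* **High-CPM outlier**: a cell whose `log2(CPM + 1)` exceeds
  `Q3 + 3·IQR` of its gene × type subset. The factor 3 targets "evident"
  outliers (1.5 is the conventional mild fence).
* **Low-end zero anomaly**: the subset's zero fraction exceeds 0.25 while
  the median of its *nonzero* values still exceeds the expression
  threshold — i.e. the type clearly expresses the gene, yet an implausible
  share of its cells report zero (suggestive of dropout or misassignment).
* Both rules need at least `min_cells` cells (default 16, matching the
  type-curation minimum).

The displayed-type convention for within-type histograms picks the type
with the highest mean and the type whose mean is nearest 25% of that
maximum ("mid-range").

# Subsampling stability

The robustness claim worth testing is that type-mean signatures are stable
under resampling of cells. `neurosig` operationalizes this as a **half-split
design**: per replicate, the cells of each type are split into two disjoint
random halves (odd cells drop one), signatures are recomputed on each half,
and the per-gene Pearson correlation across types between halves is
recorded; `n_reps` replicates are summarized by median and IQR. A 50/50
split was chosen over bootstrap because disjointness makes the two
estimates independent given the type, so r = 1 is attainable only through
genuine signal. Constant genes have undefined correlation and are reported
as `NA` with a replicate count, never silently dropped.

# The simulated world

The generator provides a fully known ground truth so that every downstream
stage has a parameter-recovery test. Its defaults were chosen once, to
emulate the structure of a deep SMART-Seq-style regional survey, and are
not tuned to test outcomes:

* **Hierarchy 2/6/14/42** (classes/subclasses/supertypes/types), leaves
  distributed evenly; with two classes they are labelled GABAergic and
  glutamatergic.
* **Cells per type uniform on [16, 200].** Regional surveys yield uneven
  type representation from a curation minimum up to a few hundred; the
  lower edge sits exactly at the 16-cell filter boundary so the inclusive
  semantics are exercised.
* **200 genes: 84 one-type markers, 28 supertype programs, 12
  class-restricted, 76 ubiquitous.** Targets are assigned round-robin
  (markers 2 per type, programs 2 per supertype, class genes 6 per class),
  which keeps each type's total planted expression identical, so CPM
  renormalization rescales all types by one common factor and the planted
  profile shapes — hence delta — are preserved exactly. `expected_cpm()`
  returns the profile on the realized-CPM scale.
* **Baseline 50 CPM, marker fold 20.** Markers are planted far above the
  10 CPM filter; ubiquitous genes sit comfortably above it too, so the
  filter's action is governed by the data, not by borderline design.
* **Off-target marker level 0 by default** (`marker_baseline = 0`): pure
  one-hot profiles make the delta = 1 endpoint testable exactly;
  setting `marker_baseline > 0` exercises intermediate-delta regimes.
* **Negative binomial counts, dispersion 0.5** — the standard
  overdispersion model for single-cell counts, mid-range for deep
  full-length protocols; `dispersion = 0` degrades to Poisson for
  law-of-large-numbers tests.
* **Log-normal library sizes** (meanlog `log(5e5)`, sdlog 0.4) reproduce
  the counts-vs-CPM distinction so normalization is a meaningful stage.
* **Dropout 0.05**, independent Bernoulli zeroing, low as appropriate for
  deep full-length chemistry.

What the generator does *not* emulate: read-level artifacts (gene length
bias, exon/intron structure), correlated gene programs beyond the planted
block structure, doublets, ambient RNA, or assignment errors. A green
parameter-recovery test therefore establishes that the pipeline's
estimators work under a realistic noise model — not that any particular
biological dataset satisfies that model.

# Design decisions that were genuinely open

* **16-cell boundary.** Stated curation rules in this literature waver
  between "at least 16" and "more than 16"; `neurosig` uses the inclusive
  reading (≥ 16) and makes the value configurable.
* **Pairing is area-level.** An expressed NPP counts as "paired" when any
  cognate NP-GPCR is expressed anywhere in the area, matching how such
  claims are usually stated; a stricter type-resolved mode (co-expression
  required in at least one common type) is available via
  `type_resolved = TRUE` but is not the headline statistic. NPPs lacking a
  cognate-group key are excluded from the denominator as unresolvable
  rather than counted as unpaired.
* **Cognate dictionary is data.** Ligand–receptor cognate links are
  supplied in the gene panel (`cognate_group`, `;`-separated for
  promiscuous peptides), never hard-coded pharmacology.
* **Configs are YAML** (JSON accepted); stage outputs are plain CSV/JSON so
  the figure layer never needs the raw matrix.
* **SVG as the primary figure format**: rendering is deterministic, so
  tests can compare bytes.
* **CLI as a thin wrapper.** The `cmd_*()` functions are ordinary exported
  R functions; the installed `exec/neurosig` script only dispatches to
  them, so everything the CLI does is unit-testable in-process.

# Known limitations

* Delta carries no uncertainty; two genes with equal delta can have very
  different evidential support (use the stability report alongside it).
* The expression filter and co-expression tallies share one threshold
  parameter by design; analyses wanting different thresholds per stage
  must construct separate `filter_spec`s.
* CPM levels depend on the gene universe of the supplied matrix (see
  above); only within-dataset comparisons are supported.
* The outlier rules are descriptive flags, not a fitted zero-inflation
  model; they will under-flag in types with genuinely bimodal expression.
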