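---
title: "Pathway-pairwise signatures: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-pairwise signatures: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mppsig)
```

## The problem and the statistic

Blood transcriptomes of Alzheimer's disease (AD) cases and controls come from
heterogeneous platforms, and absolute expression levels do not transfer
between cohorts. `mppsig` is built around a statistic that does transfer: the
relative ordering of two pathway activities *inside one sample*. Any strictly
increasing distortion of a sample's expression values — the typical shape of
a batch or platform effect — permutes nothing, so the ordering indicator of a
pathway pair is invariant to it by construction.

The pipeline has four statistical layers.

**Pathway activity.** For one sample, genes are sorted by decreasing
expression; the gene at position $p$ of $N$ receives the rank weight
$\rho = N + 1 - p$. For gene set $G$ the score is

$$\mathrm{ES}(G) = \sum_{p=1}^{N}\Big( \frac{\sum_{g \in G,\, \mathrm{pos}(g)\le p} \rho_g^{\alpha}}{\sum_{g\in G} \rho_g^{\alpha}} \;-\; \frac{\#\{g \notin G: \mathrm{pos}(g)\le p\}}{\#\{g \notin G\}}\Big),$$

the ssGSEA running-sum statistic: the area between the weighted in-set ECDF
and the unweighted out-of-set ECDF. Ties are broken by stable input order,
which makes the score deterministic; for continuous expression, ties are a
measure-zero event and the policy is immaterial.

**Pairwise signatures.** With activities $MP_1^k,\dots,MP_m^k$ for sample
$k$, each pair $i<j$ (catalog order, fixed) yields the continuous difference
$MP_i^k - MP_j^k$ and the indicator $r_{ij}^k = I(MP_i^k - MP_j^k) \in
\{+1,-1\}$ with $I(x \ge 0) = +1$. Both are kept: the source material defines
the indicator but also refers to the subtracted values, so downstream stages
accept either representation (the screen uses the indicator; subtyping and
scoring default to the continuous difference, configurable).

**Differential screen.** For a pair, the $2\times2$ table of group ×
ordering is tested by the Pearson chi-square with 1 df and *no continuity
correction*; that choice is locked by a worked example from printed cohort
data (gender counts 288/200 vs 282/205 give $\chi^2 = 0.124$,
$p = 0.725$, which only the uncorrected statistic reproduces). Holm's
step-down adjustment runs across all testable pairs; a pair whose ordering is
constant over every sample has a zero column margin, carries no information,
and is excluded from the Holm family rather than assigned $p = 1$ — including
it would only deflate the correction for the real tests.

**Diagnostic score.** The MPPSS is the linear scorer
$\mathrm{risk}_k = \beta_0 + \sum_i \mathrm{coef}_i \cdot \mathrm{MPPS}_i^k$.
Training: stratified 70/30 split; repeated bootstrap resampling of the
training split with an L1-penalized logistic fit per draw (lambda at minimum
cross-validated deviance); signatures selected in at least `freq_threshold`
(default 0.8) of the draws enter a final penalized fit. The published
formula carries no intercept, so the bundled 13-pair reference model has
$\beta_0 = 0$ and unit signature vectors return the printed coefficients
exactly; trained models report the fitted intercept separately (AUC is
intercept-invariant).

## Subtyping by consensus NMF

Cases are clustered on the exponentiated flagged-pair submatrix: $e^x$ maps
the signed signatures to strictly positive values (the indicator to
$\{e^{-1}, e\}$) while preserving all orderings, making the matrix admissible
for NMF. Factorization uses the classical multiplicative KL updates, whose
objective provably never increases — the test suite asserts the recorded
trace at every iteration. Initialization is i.i.d. Uniform(0,1) scaled by
`mean(V)`, with a $10^{-12}$ floor keeping factors strictly positive.

Each of `nrun` (default 10) restarts assigns samples to their dominant basis
component; the consensus matrix averages run co-clustering. Rank quality per
candidate $k$: the cophenetic correlation between consensus distances
($1 - c$) and the dendrogram distances of their average-linkage clustering;
the dispersion $\frac{1}{n^2}\sum 4(c - \tfrac12)^2$ (1 for a perfectly
binary consensus); and the mean silhouette width. The chosen rank is the
smallest $k$ maximizing the cophenetic, ties broken by dispersion then
silhouette. "Final" assignments are deliberately taken from the
average-linkage tree of $1 - c$ cut at $k$ (the consensus-clustering
convention) rather than from any single run, and cluster labels are
canonicalized by decreasing size, so subtype 1 is always the larger group.

## Hub pathways

Flagged pairs form a simple undirected graph over pathways; hubs are ranked
by Maximal Clique Centrality, $\mathrm{MCC}(v) = \sum_{C \ni v} (|C|-1)!$
over *maximal* cliques, enumerated exactly (Bron–Kerbosch via igraph —
pathway graphs have at most a few dozen nodes, so the exponential worst case
is irrelevant). Edges are unweighted: the statistic is topology-only, and the
chi-square magnitudes are deliberately not used. For a triangle-free node
this reduces to its degree, one of the invariants under test.

## The synthetic world

`generate_dataset()` draws from an additive Gaussian model on the log scale:
gene baselines $\mu_g \sim N(\mu_0, \sigma_0^2)$ shared across samples,
disjoint pathway gene blocks, additive group/subtype shifts $\delta$ on the
genes of the named pathway, i.i.d. $N(0, \sigma^2)$ noise, optional per-batch
intercepts. Defaults — 10 pathways × 30 genes, 300 background genes, 60
controls, 40 + 30 cases in two subtypes, $\mu_0 = 6$, $\sigma_0 = 1$,
$\sigma = 0.5$ — are log2-microarray-like magnitudes, chosen once, small
enough for seconds-scale tests and large enough for stable chi-square counts.
Ground-truth "flipped pairs" are computed from the realized pathway-mean
expectations: a pair counts as planted-flipped only if both subtypes reverse
the control ordering.

A Gaussian rather than count model is adequate here because every downstream
statistic is rank-based within samples; what the generator does *not*
emulate is probe-level structure, platform-specific intensity response,
correlated gene noise within pathways, or realistic pathway overlap, so a
green recovery test establishes the machinery works under the assumed
additive model — not that the effect sizes in real cohorts are detectable.
Batch intercepts can be generated but no correction is implemented; they
exist to document sensitivity, and a whole-sample additive batch shift
cancels exactly in within-sample comparisons anyway.

## Numerical and design choices

- `alpha = 0.25` and global range normalization are the conventional ssGSEA
  defaults; the source protocol does not state them, so both are arguments.
  Normalization divides by one positive global factor and therefore cannot
  flip any within-sample ordering — asserted in the tests, not assumed.
- Ties in the ordering indicator map to $+1$ exactly as defined.
- Degenerate screen tables are skipped with a reason, never silently fixed.
- The AUC uses the Mann–Whitney rank form with half credit for ties; its 95%
  CI uses DeLong's placement-value variance (deterministic, standard; a
  bootstrap CI would inject simulation noise into a reporting statistic).
  Thresholded metrics (recall/precision/F1) use the Youden-optimal threshold
  from the training scores, reported alongside.
- All randomness flows from explicit integer seeds; consensus runs use
  `seed + 1000k + r` substreams, bootstrap iterations `seed + iteration`.
- "One thousand iterations" of feature selection is interpreted as bootstrap
  resampling of the fixed training split (the resampling unit is not stated
  in the source protocol; re-splitting is the other reading, and the
  frequency interpretation is unchanged). Analysis drivers and tests scale
  `n_iter` down (100 and 25) purely for runtime; the package default is 1000.
- The screen's count test needs no minimum cell expectation guard beyond the
  degeneracy rule: with the default group sizes the expected counts are
  comfortably above the usual rule-of-thumb of 5. The null calibration
  (`null_screen_calibration`) verifies the realized type-I error (raw
  fraction ≈ nominal $\alpha$; Holm FWER at the adjusted threshold) by
  Monte-Carlo.

## Known limitations

- Pathway gene sets are user input; no gene-identifier aliasing or
  probe-level collapsing is performed (identifiers are case-sensitive).
- NMF rank selection inspects a small candidate range; the wrapper truncates
  ranks that exceed the flagged-pair matrix dimensions with a warning.
- With a single selected signature the final model falls back to an
  unpenalized logistic fit, which diverges on separable data; the score
  ordering (and hence AUC) is unaffected, but the coefficient magnitude is
  then not interpretable.
- The cohort-scale headline numbers of the motivating study (its significant
  pair counts, subtype sizes and external-cohort AUCs) depend on proprietary
  cohort downloads and are out of scope; the package verifies the machinery
  on printed worked examples and planted-truth simulations instead.
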