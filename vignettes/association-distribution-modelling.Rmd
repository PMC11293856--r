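---
title: "Methods: association distribution modelling with admtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association distribution modelling with admtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admtools)
```

# The model

`admtools` models the spatial and temporal distribution of *pairwise
ecological associations*. The pipeline has five statistical layers, each
with its own assumptions.

## Compositional preprocessing

Metagenomic abundances are relative (compositional), so the package works
on centred log-ratio (CLR) values: for sample $i$,
$m_{ji} = \log x_{ji} - \frac{1}{m}\sum_{j'} \log x_{j'i}$, natural
logarithm. The log base must be fixed because it cancels in the
proportionality metric but not in raw CLR values; the natural log is the
standard CLR convention. CLR requires strictly positive input, so zeros
are first imputed multiplicatively: every zero becomes
$0.65 \times \min\{x > 0\}$, the minimum taken over the **whole table**.
The scope of that minimum (global vs per sample) is genuinely open; the
global reading is the simplest consistent one, and the factor and minimum
used are recorded in `metadata()` so the choice is auditable. Before
imputation, taxa observed in fewer than `minOccurrence` samples (default
10) are dropped — rarely-seen taxa cannot support a stable pairwise
statistic. Presence/absence, used later by the co-occurrence models, is
always taken from the **raw** table: imputation makes every entry
positive and would otherwise erase occurrence information.

## The proportionality metric and its decomposition

Association strength between CLR vectors is
$\rho = 1 - \mathrm{var}(m_j - m_k)\,/\,(\mathrm{var}(m_j) +
\mathrm{var}(m_k))$, with *population* variances (divisor $n$). The
divisor matters: the per-sample decomposition
$\alpha_i = (d_i - \bar d)^2 / \big(\sum_i (m_{ji}-\bar m_j)^2 +
\sum_i (m_{ki}-\bar m_k)^2\big)$ with $d_i = m_{ji} - m_{ki}$ satisfies
$\rho = 1 - \sum_i \alpha_i$ **exactly** only when numerator and
denominator use the same divisor. The package stores $\alpha$ in this
manifestly non-negative form (a squared deviation over a positive sum)
rather than the expanded polynomial, which is algebraically equivalent
but not term-wise non-negative under floating point. Consequences that
the test-suite asserts: each $\alpha_i \ge 0$, hence $\rho \le 1$ always;
$\rho$ is symmetric and invariant to adding a common constant; identical
vectors give exactly $1$ and sign-flipped vectors $-1$. Pairs in which
both taxa are constant have no defined $\rho$ and are excluded with a
warning, never silently set to `NaN`.

The all-pairs path uses the covariance identity
$\rho_{jk} = 2\,\mathrm{cov}(m_j, m_k) / (\mathrm{var}_j +
\mathrm{var}_k)$ so the full $m(m-1)/2$ enumeration is a single matrix
product; tests verify entry-wise agreement with the scalar formula to
$10^{-12}$.

## Significance: bootstrap-FDR thresholds

Proportionality has no parametric p-value, so signed thresholds
$(t_-, t_+)$ are calibrated against a permutation null: each replicate
permutes every taxon's sample labels independently, which preserves each
taxon's marginal distribution while destroying all pairwise covariation.
For each candidate threshold the FDR estimate is the mean null
exceedance count over the observed exceedance count (capped at 1), and
the least extreme thresholds with FDR below the level (default 0.01) are
kept. The candidate grid runs from $-1$ to $1$ in steps of $0.05$, the
granularity at which such thresholds are conventionally reported. The
detailed resampling scheme used in the original formulation of this
procedure is not fully specified, so the permutation null — the standard
choice for co-occurrence testing — is an explicit, documented decision
here.

## cADM and rADM

For each retained pair, two models are fit as functions of the
environmental predictors (defaults: temperature °C, salinity PSU,
nitrate and silicate µmol kg⁻¹):

* **cADM** classifies the per-sample state — `copresence` (both raw
  abundances $> 0$), `coabsence` (both $0$), `exclusion` (exactly one
  present, unordered). It is a single 3-class model, not three
  one-vs-rest models.
* **rADM** regresses $\alpha_i$.

Learners: random forest (`ranger`, 500 trees), gradient boosting
(`xgboost`, 100 rounds, depth 4), RBF-kernel SVM (`e1071`), all
single-threaded and seeded for bit-reproducibility, plus a `memorize`
learner (exact interpolation of training rows, nearest row otherwise)
used for diagnostics such as the $\rho^*$ round-trip test.
Hyperparameters are pinned library defaults; no tuning is performed.
Performance is estimated by 5-fold cross-validation (stratified for
cADM): balanced accuracy for the 3-class imbalanced labels, $R^2$ for the
regression. Out-of-fold predictions are pooled and scored once, rather
than averaging per-fold scores — a per-fold mean explodes when a small
fold happens to contain near-constant truth. Permutation feature
importance is the mean drop in that score over seeded permutations of one
predictor column; a constant column's importance is exactly zero, and
useless features may legitimately score slightly below zero.

## Projection and $\rho^*$

Samples are matched to gridded climatology by exact cell hit, else the
mean of valid cells within a ±2° latitude/longitude box (at 1°
resolution the difference from a great-circle disc is negligible, and
the box keeps the rule transparent); unresolvable samples are reported,
not dropped. Projections are restricted to grid cells where **every**
predictor lies within the 2.5–97.5 percentiles of the observed samples —
cells outside the observed envelope get *no* prediction rather than an
extrapolated one. The all-features-AND rule is a deliberate choice where
a per-feature treatment was conceivable.

Summing predicted $\alpha^*$ over $G$ grid cells is not commensurate
with the training identity, which sums over $n$ training samples, so the
projected strength is rescaled:
$\rho^* = 1 - (n_{\text{train}}/G)\sum_{g}\alpha^*_g$. Under this
scaling a grid that replicates the training samples reproduces the
training $\rho$ exactly (asserted to $10^{-9}$ with the memorizing
learner), and regional values computed the same way over a partition
recombine exactly into the global value when weighted by cell counts.
The scaling is explicit and central — any alternative normalization
would shift every reported $\rho^*$ — and raw $\rho^*$ values are kept
unclipped; clipping to $[-1, 1]$ is a reporting concern.

## Biogeographic clusters, graphs, responses

Present-day cADM maps are stacked into an associations × cells 0/1
co-presence matrix and clustered with k-means (Euclidean distance on the
raw binary matrix, 10 restarts per $k$, seeded); $k$ is scanned from 2
to 15 and chosen by maximum mean silhouette, ties resolving to the
smaller $k$. For large inputs the silhouette is evaluated on a seeded
subsample of at most 5000 rows. Binary states (not class probabilities)
are clustered; probability input is accepted by the same function if a
user prefers it.

Association graphs weight edges by reconstructed global $\rho^*$. Edge
betweenness is computed on the **unweighted** shortest-path structure:
$\rho^*$ is a similarity, not a distance, and any inversion rule would
be arbitrary; this also matches the default behaviour of stock
centrality routines. Two density-like metrics are deliberately kept
apart: `edgeNodeRatio()` (#edges / #nodes), the ratio used in the
association-biogeography literature this package follows, and
`graphDensity()` ($2E/(N(N-1))$), the conventional definition — naming
them differently avoids a silent unit clash. Cross-cluster metric
comparisons min–max normalize to $[0,1]$ and report the spread
$(\max-\min)/\max \times 100$; all-equal values map to all zeros with
spread 0 by convention.

Temporal analysis uses the ten canonical time points (2015, 2020, …,
2100). Associations must keep ≥ 30 % projected co-presence at **every**
time point to be analysed. OLS slopes of co-presence proportion and
$\rho^*$ against calendar year (closed form, with Pearson $r$ and $R^2$
as linearity diagnostics; constant series get slope 0 and missing
diagnostics) feed the five response groups. The "±10 % around zero"
neutral band is operationalized as `bandFraction` × the maximum absolute
slope per metric (default) — making the partition invariant to rescaling
either metric — with a `quantile` mode (central 10 % of the slope
distribution) as the documented alternative, because the band's precise
definition is ambiguous; it is a switch, not a guess baked in. An
association is neutral only if **both** slopes sit in their bands; a
half-neutral combination inherits the raw signs, since the five groups
leave no room for mixed labels (an exactly-zero slope forced to carry a
sign maps to "+", an unreachable corner under continuous slopes).

# The synthetic world

The generator is the package's study-condition definition, not a tuning
knob. Defaults: 80 samples, 50 taxa, 20 planted positive and 5 planted
negative pairs. The environment has a latitudinal temperature gradient
(28 °C at the equator, −0.28 °C per degree of |latitude|, 1 °C noise),
nitrate anticorrelated with temperature at a target Pearson of −0.9
(mirroring the strong observed temperature–nitrate coupling in ocean
climatologies), silicate anticorrelated more weakly, and near-constant
salinity (35 ± 0.3 PSU). Each taxon has a Gaussian thermal niche
(breadths 2.5–5.5 °C — deliberately narrower than the ~18 °C sampled
gradient so presence varies along it); log-abundance is a niche response
plus noise, and **structural zeros** arise where suitability falls below
0.1, so the three co-occurrence states carry environmental signal by
construction rather than by random dropout. Planted positive pairs share
their niche and all stochastic components, differing only by a smooth
environmentally driven decoupling term (amplitude 1.5 on the log scale,
growing away from the thermal optimum): association strength therefore
*varies along the gradient*, which is exactly the signal rADMs exist to
learn. Planted negative pairs get mirrored thermal optima and an
anti-coupled latent factor, making them exclusion-prone. Tables are
closed to relative abundances. Future grids warm by 0.3 °C/decade and
lose 5 %/decade of nitrate (half that for silicate), salinity flat —
a medium-emissions caricature with monotone means.

What this emulates: compositionality, environmental niche structure,
gradient-dependent association strength, climate trends. What it does
not: real taxonomic composition, spatial autocorrelation of residuals,
seasonality, multi-depth structure, or observation error models of
metagenomic quantification. Passing tests therefore demonstrate that the
machinery recovers what it is designed to recover under its own
generative assumptions — not that those assumptions describe any real
ocean.

# Numerical choices and degenerate inputs

* CLR closure enforced to $10^{-9}$ by class validity; the decomposition
  identity asserted to $10^{-9}$ (observed error is orders of magnitude
  smaller).
* k-means failures at some $k$ (e.g. duplicate-row pathologies) are
  skipped within the scan; an all-identical signature matrix is an error
  because the silhouette is undefined.
* An all-zero abundance table, a single-state cADM target, an empty
  alpha vector, a constant time axis and an empty region are all
  explicit errors; a constant alpha vector is a warning (the model fits
  and predicts the constant, with undefined $R^2$).
* Longitudes are normalized to $[-180, 180)$; no wrap-around averaging
  across the antimeridian is attempted in the grid search box.
* Every stochastic step (bootstrap, folds, forests, permutations,
  k-means restarts, generators) runs under an explicit seed through an
  RNG-state-preserving wrapper, so package calls never disturb the
  caller's RNG stream and identical seeds give identical results.

# Problem sizes in the shipped tests

The test suite favours many small, seeded replicates over single large
runs: the 1887-taxon pair enumeration (1 779 441 pairs) runs once as a
combinatorial check; FDR calibration uses 20 replicates of 30 taxa × 60
samples with 20 bootstrap replicates; detection power uses the default
80 × 50 world; driver-recovery runs 100 replicates at 60 samples;
cluster recovery 50 replicates per archetype count; the full staged
pipeline runs on a 60-sample, 20-taxon world with four time points.
These sizes were chosen so the whole suite exercises every path in
about a minute while leaving the recovery rates comfortably away from
their pass thresholds.

# Known limitations

Associations are correlational: they cannot separate direct interaction
from shared environmental preference, and the FDR null addresses only
the no-covariation hypothesis. Cross-validation is random, not spatial,
so performance estimates are optimistic under spatial autocorrelation.
Models are fit per pair with no information sharing. Region
specifications are rectangles, not province polygons. NetCDF support
requires the optional `ncdf4` package; the TSV grid dialect is always
available.
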