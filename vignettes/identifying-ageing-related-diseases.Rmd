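---
title: "Identifying ageing-related diseases from age-specific onset curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying ageing-related diseases from age-specific onset curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardkit)
```

## The problem

An ageing-related disease (ARD) is one whose rate of first onset rises with
chronological age — as distinct from an "age-related" disease that merely
concentrates in some age range. Given aggregated electronic-health-record
(EHR) counts of first recorded diagnoses, `ardkit` grades every disease's
ageing-relatedness by two independent routes and lets the analyst compare
them:

1. **unsupervised clustering** of the shapes of age-specific onset curves,
   with an explicit model-selection procedure, and
2. an **actuarial classification** based on how well each curve follows
   mortality-law-style parametric models.

The input is deliberately minimal: for each disease, the number of patients
first recorded with the disease at each integer age $x$ ($d_x$) and the
number still at risk, i.e. with no record of the disease, at that age
($l_x$).

## The age window

All computations use integer ages 21–84 (64 grid points). Diagnoses at 20
or younger are excluded because childhood and pubertal development, not
ageing, drives onset there; diagnoses at 85 or older are excluded because
the very old who remain undiagnosed are a survivor-biased, unusually robust
subset. Inputs containing other ages are rejected unless explicitly
trimmed (`trim = TRUE`) — the window is a contract, not a silent filter.

## Rates and standardised curves

The age-specific rate of disease onset is $q_x = d_x / l_x$. For shape
comparison across diseases of very different prevalence, each curve is
standardised to unit mass:

$$\hat q_x = \frac{q_x}{\sum_{i=21}^{84} q_i},$$

so a rare and a common disease with the same age profile become identical
curves. An age with $l_x = 0$ (possible only in simulation) gets $q_x = 0$
and a flag rather than being dropped, so every curve keeps the full
64-point grid that the Euclidean distances require. An all-zero curve
cannot be standardised and is reported by name; the pipeline drops it from
clustering with a warning but still lists it in the outputs.

Median onset ages are weighted quantiles of the age grid with weights
$d_x$, using the inverse-CDF convention with midpoint interpolation at
exact half-mass boundaries (equivalent to `quantile(type = 2)` on the
expanded data). The convention matters only at exact boundaries and is
fixed here once so that reported integer-year medians are reproducible.

## Clustering with model selection

Pairwise Euclidean distances between standardised curves feed a
three-stage selection procedure, each stage scored by an internal validity
criterion rather than by taste:

* **Linkage** for hierarchical agglomerative clustering is chosen by the
  cophenetic correlation — the Pearson correlation between original
  distances and dendrogram merge heights. Candidates: average, single,
  complete, weighted (McQuitty). Ties prefer average linkage, the choice
  this procedure conventionally settles on for onset curves.
* **Number of clusters** is chosen by the gap statistic: for each $k$, the
  pooled within-cluster dispersion $W_k = \sum_r D_r / (2 n_r)$ (with
  $D_r$ the sum of pairwise squared distances in cluster $r$; equivalently
  the within-cluster sum of squares) is compared against its expectation
  under $B$ reference datasets drawn uniformly over the per-feature range
  of the data. The chosen $k$ is the smallest with
  $\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$. Defaults: $B = 50$,
  $k$ searched up to 30 (capped at $n - 1$); both configurable. With
  $B = 1$ the standard error is defined as 0 and the values remain finite.
  A degenerate $W_k = 0$ (coincident curves) is floored at machine epsilon
  with a warning before taking logs.
* **Algorithm** is chosen by the Dunn index (minimum between-cluster
  distance over maximum within-cluster diameter), comparing hierarchical
  clustering against k-means, PAM and spectral clustering, each evaluated
  at its own gap-chosen $k$. If the gap statistic chooses $k = 1$ for some
  algorithm, that algorithm is Dunn-scored at $k = 2$ (the index is
  undefined for one cluster) while the gap-chosen value is kept in the
  diagnostics. A Dunn tie prefers hierarchical-average. When every cluster
  has zero diameter the index is reported as `Inf` with a warning.

Clusters with three or more diseases become "main" clusters, renumbered
1..M in descending order of the within-cluster median of their members'
median onset ages — so main cluster 1 always holds the oldest-onset
diseases. Clusters of one or two diseases are "outlier" clusters.

Implementation notes, for reproducibility of details that the criteria do
not pin down:

* Hierarchical clustering, tree cutting and cophenetic distances use
  `stats::hclust`/`cutree`/`cophenetic`; merge tie-breaks follow
  `hclust`'s deterministic internal convention.
* k-means is `stats::kmeans` (Hartigan–Wong) with 10 random restarts
  under a set seed; with well-conditioned curve data, restarts make the
  usual difference that a k-means++ initialisation would, and the standard
  implementation keeps behaviour transparent.
* PAM is classic build + swap (`cluster::pam`) on the distance matrix.
  Build + swap is a local search: on unstructured point clouds it can stop
  short of the exhaustive-search optimum, which is why its correctness
  tests use instances with genuine cluster structure.
* Spectral clustering uses a Gaussian affinity with bandwidth equal to the
  median pairwise distance, the symmetric normalised Laplacian, top-$k$
  eigenvector embedding with row normalisation, then k-means in the
  embedding. The bandwidth rule is a documented convention; the method
  name alone does not determine one.

## The actuarial route

ARDs should have onset rates that *accumulate* with age the way mortality
does. Two models are fit to $\log q_x$ by unweighted OLS over the ages
with $q_x > 0$:

* **Gompertz**: $q_x = \alpha e^{\beta x}$, i.e.
  $\log q_x = \log\alpha + \beta x$. $\beta$ (per year of age) is the
  senescent slope; $\alpha = e^{\text{intercept}}$ is the curve's level in
  this parameterisation (the extrapolation to age zero).
* **Gompertz–Makeham (exponential-quadratic form)**:
  $\log q_x = \log a + b x + c x^2$. The quadratic term lets the model
  track curves that rise then level off or dip — shapes the monotone
  Gompertz law cannot represent. This is the exponential-polynomial usage
  of the Gompertz–Makeham name, not the classical additive-constant
  hazard.

Zero-rate ages are excluded because their log is undefined; a disease
needs at least 10 positive ages (configurable) or it is flagged rather
than classified. The fits are unweighted on the log scale: the model is a
descriptive regression of curve shape, not a likelihood model of counts.
A curve with a perfectly constant rate has zero total variation on the
log scale; its slope is defined as exactly 0 and $R^2$ as 0.

Goodness of fit uses the adjusted $R^2$,
$1 - (1 - R^2)(n-1)/(n-p-1)$, which unlike the raw $R^2$ can decrease
when the quadratic term fails to earn its keep. The step-wise rule is:

1. If the Gompertz $\beta < 0$, onset falls with age: **very low**
   likelihood of being ageing-related, regardless of the quadratic fit.
   $\beta = 0$ exactly proceeds to step 2 (the rule branches only on
   "negative").
2. Otherwise the adjusted $R^2$ of the Gompertz–Makeham fit is banded at
   thresholds 0.95 / 0.90 / 0.85 / 0.80, half-open intervals closed at
   the lower threshold ($[0.95, \infty)$ is the very-high band, down to
   $(-\infty, 0.80)$ low). The endpoint convention is arbitrary but fixed
   and used consistently.

## What the synthetic generator emulates — and what it does not

Real EHR onset data for a cohort of this kind is access-restricted, so the
package carries a generator whose outputs have known ground truth. Each
disease is a binomial thinning of a parametric age hazard: the at-risk
pool starts at `cohort_size_at_21` (default $10^6$; the kind of study this
emulates pools millions of patients), $d_x \sim
\mathrm{Binomial}(l_x, p_x)$, and the pool depletes by exactly the
diagnosed, $l_{x+1} = l_x - d_x$. Death and censoring are deliberately not
modelled: $l_x$ plays the role of "patients with no record of the
disease", which is what the onset-rate denominator actually uses.

The default panel holds five hazard families — late exponential
(Gompertz, $\alpha = 10^{-7}$, $\beta = 0.12$), mid exponential
($\alpha = 2\times10^{-5}$, $\beta = 0.055$), linear rise (baseline
$2\times10^{-4}$, slope $3\times10^{-5}$/year), early-peak-and-decline
(Gaussian bump at age 28, width 16), and declining exponential (decay
0.05/year) — spanning the cluster archetypes seen in large EHR panels:
steep late ageing curves, broad adult exponentials, gradual linear rises,
young-adult-onset declining shapes. Each family's `is_ageing_related`
flag is fixed by construction: its noise-free hazard, pushed through the
classification algorithm analytically, lands in the very-high band for
the three ageing families (the linear-rise family's concave log-hazard is
captured by the quadratic model with adjusted $R^2 \approx 0.989$) and in
the very-low band ($\beta < 0$) for the two declining families. The tests
assert exactly this.

Per-disease parameter jitter produces within-family diversity:
multiplicative log-normal (sdlog 0.10) on each family's level parameter
and additive Gaussian (sd 2% of the value) on shape parameters, both
scaled by `noise_scale`. The shape-jitter default is calibrated by a
masking principle: standardised curves are unaffected by level jitter, so
the clusterable within-family spread comes from shape jitter plus
binomial sampling noise, and "low" jitter should stay clearly below the
sampling-noise floor at the default cohort size (measured, 2% puts the
jitter-only spread at roughly half the floor across families). Larger
values are legitimate — they model family boundaries dissolving into
continua, at which point label recovery is no longer a well-posed target.
Each disease draws from a private random stream keyed by a hash of its
identifier and the master seed, so adding or removing diseases never
perturbs the others — and the whole cohort is bit-reproducible from the
seed.

What the generator does *not* emulate, and therefore what green tests do
not certify about real data: diagnostic delay and under-recording,
screening-programme spikes, period and cohort effects, correlated
multimorbidity between diseases, mortality-driven censoring of the
at-risk pool, and curve families outside the panel. On real EHR data the
cluster count is an empirical question, not five, and goodness-of-fit
bands are sensitive to sparse counts (few positive ages lower the
adjusted $R^2$ for reasons of sample size, not biology).

## Problem sizes and numerical choices in the test-suite

The tests and the acceptance script run the panel at its default size
(100 diseases, cohort $10^6$), oracle checks at $n \le 10$ against
brute-force enumerations, slope-recovery at 200 simulated diseases, and
gap-statistic checks with $B$ between 10 and 50 and $k$ searched to 10 —
sizes chosen so the full suite completes in well under a minute while
keeping every statistical margin wide. Floating-point comparisons against
oracles use 1e-10; standardised curves are required to sum to 1 within
1e-9.

## Limitations

* The two routes share their input ($q_x$), so their concordance is
  evidence of robustness, not of independent measurement.
* The gap statistic with a uniform-box reference tends to over-resolve
  data with strong internal continua; on real curve panels the chosen
  $k$ should be read alongside the gap table, not as an oracle.
* Unweighted log-scale OLS treats every positive age equally; ages with
  tiny counts contribute noisy log-rates, which lowers adjusted $R^2$ for
  sparse diseases. The `min_positive_ages` guard bounds, but does not
  remove, this effect.
* Bands are point classifications without uncertainty; no confidence
  intervals are attached, and no alternative mortality laws (Weibull,
  logistic/Kannisto, additive-constant Makeham) are fit.
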