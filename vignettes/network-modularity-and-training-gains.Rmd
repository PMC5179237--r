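---
title: "Methods: baseline network modularity as a predictor of training gains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline network modularity as a predictor of training gains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`netgain` implements an individual-differences analysis for cognitive
training studies: does the modular organization of a participant's
resting-state functional brain network, measured *before* training, predict
how much they will improve? This vignette documents the models, the
numerical choices, and what the bundled synthetic cohorts can and cannot
establish.

## From time series to graphs

The entry point is one matrix of ROI-averaged BOLD time series per subject
(nodes x timepoints). Preprocessing (motion correction, nuisance
regression, bandpass filtering, parcellation) is out of scope — it is
assumed done by a standard pipeline upstream.

**Node exclusion.** Real cohorts lose ROIs to incomplete field-of-view
coverage. `exclude_missing_nodes()` flags a node whose series has zero
variance or any non-finite sample in *any* subject and drops it for *all*
subjects, so that every connectivity matrix in a cohort is defined on one
common node set. The rule is an operationalization: what counts is the
outcome (one shared node set), and the criterion is deliberately
conservative.

**Connectivity.** `compute_connectivity()` correlates every node pair
(Pearson) and applies the Fisher transform `z = atanh(r)`, which
variance-stabilizes correlations for averaging and inference. Two numerical
choices matter:

* the diagonal is stored as `NA` and never participates in any mean or
  ranking — a self-correlation is not a connection;
* `|r| = 1` (e.g., duplicated regressors in degenerate fixtures) is clipped
  to `1 - 1e-7` before `atanh` so every entry stays finite. Real data never
  reaches the clip.

**Proportional thresholding.** `threshold_by_density()` keeps the
`floor(d * P)` strongest of the `P = n(n-1)/2` pairs as edges of an
unweighted, undirected graph, for a sweep of connection densities
(default: the top 2–10% in 2% steps, the conventional range for this
parcellation scale). Ranking uses *signed* z by default: the "top"
connections of a correlation network are its most positive ones, which is
the convention of the proportional-thresholding literature this analysis
sits in. At 2–10% density a negative correlation essentially never ranks
high enough to become an edge, so the choice is invisible in practice; an
`absolute` ranking option exists for sensitivity analyses. Ties at the
cutoff (impossible for continuous data, possible in constructed fixtures)
are broken by lexicographic node-pair order, making the edge set a pure
function of the matrix. `floor` is used for the edge count so the realized
density never exceeds the requested one.

## Modularity and segregation

**Fixed-partition modularity.** Given a community partition (for real data,
the Power-style module assignments; the partition is *imposed*, identical
for every subject), `modularity_fixed_partition()` computes per module `i`

* `e_ii` — the fraction of edges with both endpoints in module `i`,
* `a_i` — the fraction of edge *ends* attached to module `i`,
* `q_i = e_ii - a_i^2`,

and `Q = sum_i q_i`. `Q` compares observed within-module connectivity to
the expectation under random wiring preserving the `a_i`; it is near 1 when
connections fall almost entirely within modules and 0 at chance. The
implementation counts unordered edges; with `a_i` defined over edge ends
the two usual counting conventions coincide, and a brute-force
edge-counting oracle in the test suite pins the arithmetic to 1e-12.

Sub-network ("group") modularity averages `q_i` over the modules of a
functional group — sensory-motor (auditory, somatomotor hand/mouth, visual)
versus association cortex (cingulo-opercular, default-mode,
dorsal/ventral-attention, fronto-parietal, salience). The mean is
unweighted: each sub-network counts equally, matching the convention of
averaging module-level values; `weights = "size"` offers the
size-weighted alternative.

**Per-subject spectral modules.** To show that results do not hinge on the
imposed partition, `spectral_partition()` finds subject-specific modules by
Newman's leading-eigenvector method: recursive bisection on the sign
pattern of the leading eigenvector of the (generalized) modularity matrix,
accepting splits only while Q increases. Two deterministic refinements
follow the bisection: greedy single-node moves between modules, and greedy
module-pair merges. The merge step matters: recursive bisection can split a
true community across two branches of the recursion and can never rejoin
it; on planted-partition benchmarks this costs up to ~0.08 in Q roughly
once in thirty graphs, and the merge pass repairs exactly this failure.
Everything is deterministic for a given graph (eigenvector signs are
canonicalized; ties break by node order), so repeated runs agree bit for
bit. A Kernighan–Lin-style within-bisection sweep is available
(`fine_tune = TRUE`) but off by default; with the final refinement in place
it rarely changes the result.

**Segregation.** `module_segregation()` implements the weighted
counterpart, computed on the *unthresholded* z matrix: per module,
`S = (Zw - Zb) / Zw` with `Zw` the mean within-module z and `Zb` the mean z
from the module's nodes to all other nodes (pooled over all such pairs, not
averaged per partner module). `S = 1` means no between-module connectivity;
`S = 0` means none in excess of within. Because no threshold is applied,
weak connections that never survive binarization still contribute. Three
sign-handling variants are computed: `all` (z as-is), `positive` (drop
z < 0 from both means; if *every* between-module z is negative `Zb` is
taken as 0, an edge case real data does not reach), and `absolute` (use
|z|, identical to `all` on non-negative matrices — asserted exactly in the
tests).

**Threshold aggregation.** Per-density metrics are combined either as the
arithmetic mean over densities (the default presentation) or as the
trapezoidal integral over the density axis (`integrate`), the standard
area-under-curve convention when a rule is not otherwise specified.

## The statistical layer

Gain is always `post - pre`. With groups of 14–15 subjects, simple
correlations are Spearman (robust to extreme values); the two-sided p uses
the t approximation on `n - 2` degrees of freedom, matching `rho(df)`-style
reporting (a seeded permutation option exists). Partial correlations —
controlling baseline score, in-scanner motion (mean framewise
displacement), or one sub-network's modularity — are Pearson on residuals
after least-squares adjustment, on `n - 2 - k` degrees of freedom, and
operate on raw values (a rank option exists).

Confidence intervals for correlations are bias-corrected and accelerated
(BCa) bootstrap intervals: subjects are resampled in pairs, `z0` comes from
the proportion of bootstrap statistics below the observed one, the
acceleration `a` from jackknife skewness, and with `z0 = a = 0` the
interval reduces to the percentile interval. The default `B = 2000`
resamples follow common practice; resamples on which the statistic is
undefined are redrawn up to a cap. Every interval is reproducible from its
seed. Empirical coverage for a bivariate-normal correlation at n = 15 is
about 95% (asserted within [0.92, 0.97] in the test suite).

Correlations are compared between independent groups by first converting
Spearman estimates to the Pearson scale with the Myers–Sirois relation
`r = 2 sin(pi * rho / 6)` (0 maps to 0, 1 to 1), then applying the Fisher-z
two-sample statistic `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`. Under the
null its type-I error at the 5% level stays within [0.03, 0.07] at the
study's group sizes.

Group-level training effects use the 2x2 mixed ANOVA (time within, group
between), reported as the interaction F on (1, N-2) with partial
eta-squared; the identity `F = t^2` against the pooled-variance t-test on
gain scores is enforced numerically as a cross-check. Baseline matching
uses the pooled t (continuous) or the uncorrected 2x2 chi-square
(categorical).

Two-sided p-values are reported throughout and **no multiple-testing
correction is applied** — the analysis mirrors a small hypothesis-driven
design; treat secondary p-values descriptively.

## What the synthetic cohorts emulate

Because no real dataset ships with the package, `sim_spec()` /
`simulate_cohort()` generate cohorts carrying the statistical structure the
analysis assumes, and the whole pipeline is validated by parameter
recovery.

Each subject gets a latent *strength* quantile `u ~ U(0,1)` (uniform: a
bounded stand-in chosen for transparent rank behaviour, since nothing is
known about the real distribution of subject-level modularity). Time series
are i.i.d. draws from a multivariate normal with unit variance,
within-module correlation `within_r + strength_range * (u - 0.5)` and
between-module correlation `between_r` (any covariance that loses positive
semi-definiteness is repaired to the nearest correlation matrix before
sampling). The defaults — 60 nodes in 6 equal modules, T = 120 timepoints
(a 4-minute scan at TR = 2 s), `within_r = 0.19`, `between_r = 0.05`,
`strength_range = 0.26` — were fixed once, for a reason worth spelling out:
at the 2–10% densities the analysis uses, a generator with strong,
homogeneous blocks (e.g., within-r 0.5) fills the entire edge budget with
within-module edges for *every* subject, so measured modularity saturates
and stops responding to strength. Realistic ROI-level resting-state data
live in a weak-connectivity regime where the within- and between-module
correlation distributions overlap at T = 120; there, the thresholded edge
set — and with it Q — varies smoothly with strength (rank correlation of
strength with measured, threshold-averaged Q: about 0.97 under the
defaults). A `preset = "paper"` layout (255 nodes, 14 modules with the
bundled sensory-motor/association grouping) reproduces the retained-ROI
scale of the emulated design at the same T.

Behaviour is planted on the Gaussian-copula scale. Three rank correlations
are controlled jointly: strength–gain in the trained group (`rho_target`,
default 0.65; the control group's gains are strength-independent by
construction), baseline-score–gain in both groups (`rho_baseline_gain`,
default -0.80 — strongly negative, the usual regression-to-the-mean
signature of difference scores), and strength–baseline
(`rho_strength_baseline`, default -0.33). The third is not decoration: with
strength and baseline independent, rank targets of 0.65 and -0.80 are
*jointly unrepresentable* (their latent correlations would require more
than unit variance), and the generator rejects such requests with a
diagnostic. Targets are converted by `rho = 2 sin(pi * rho_s / 6)`, the
exact Spearman–Pearson relation for bivariate normal variables, so the
planted population rank correlations are exact, and monotone
transformations to score scales preserve them. One calibration constant
closes the loop: since measured modularity is a noisy monotone readout of
strength, the strength–gain copula is planted at
`rho_target / attenuation`, where `attenuation = 0.974` is the rank
reliability of threshold-averaged Q under the default regime (estimated
once by simulation over 400 subjects and then fixed); the population
Spearman between *measured* modularity and gain then equals `rho_target`.

With `plant_in = "association"`, strength drives only the
association-group modules while every other module receives an independent
nuisance strength draw. The nuisance variation is deliberate: the five q_i
values share a fixed edge budget, so strengthening association modules
mechanically drains edge share from sensory-motor modules; without
independent sensory-motor variability this zero-sum coupling would
manufacture a spurious *negative* sensory-motor–gain correlation of about
-0.45. With it, a residual coupling of roughly -0.13 remains — visible in
the recovery studies and worth remembering when interpreting small
negative sub-network correlations under proportional thresholding.

What the simulations do **not** emulate: hemodynamics, autocorrelated
noise, motion artifacts (framewise displacement is drawn independently of
everything, so partial correlations controlling it are exercised but not
stressed), heterogeneous module sizes within a preset, and any real
uncertainty about the imposed partition. Passing recovery tests therefore
show that the estimator chain is consistent under the assumed generative
model — not that the model is true of any real cohort.

## Problem sizes and reproducibility

Simulation studies in the package run at the 60-node default: 200 cohorts
of 29 subjects for correlation recovery, 100 planted-partition graphs for
spectral recovery, 1000 replicates at B = 2000 for BCa coverage, 2000
simulations for the comparison test's type-I error. The acceptance script
reruns the same studies at 100 cohorts and 500 coverage replicates and
pushes one full cohort through the pipeline at the 255-node paper scale.
Every stochastic step takes an explicit seed; the pipeline is a pure
function of (inputs, configuration, seed), and identical runs produce
byte-identical result tables. The metrics stage is cached under a content
hash of the inputs and metric-relevant settings, so statistical re-analyses
skip graph recomputation.

## Known limitations

* Proportional thresholding makes q_i values compositional (they share the
  edge budget); sub-network correlations inherit the mild negative coupling
  discussed above.
* The leading-eigenvector method is a heuristic for an NP-hard problem; the
  refinement guarantees a local optimum under single moves and pair merges,
  not the global one.
* The BCa redraw cap for degenerate resamples matters only for tiny or
  heavily tied samples; at n >= 14 with continuous data it is never hit.
* Segregation requires `Zw != 0` and at least two nodes per module; both
  are validated, not patched.
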