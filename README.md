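# netgain

Does the modular organization of a person's resting-state functional brain
network, measured **before** a cognitive training intervention, predict how
much they will gain from it? `netgain` implements the complete analysis
pipeline for this question as it arises in small randomized training
studies of older adults — from ROI time series to the headline statistic: a
Spearman correlation, with a BCa bootstrap confidence interval, between
baseline network modularity and training gain, computed separately in the
trained and control groups and compared between them.

It is written for researchers running (or reanalyzing) resting-state fMRI
training studies, and for methodologists who want a fully testable,
simulation-backed reference implementation of the metrics involved.

## What it computes

Per subject, from a nodes x timepoints BOLD matrix:

* **Fisher-z connectivity**: `z_ij = atanh(cor(x_i, x_j))`, diagonal
  excluded.
* **Density-thresholded graphs**: the top `d` fraction of node pairs
  (default sweep: d = 0.02–0.10 in steps of 0.02) as unweighted,
  undirected edges.
* **Modularity** under a fixed community partition (e.g., the Power-style
  module assignments): per module `i`, `e_ii` (fraction of edges inside
  the module), `a_i` (fraction of edge ends attached to it), and

  `Q = Σ_i (e_ii − a_i²)`

  with sub-network summaries for the sensory-motor and association-cortex
  module groups, and threshold aggregation by mean or trapezoidal
  integration. A deterministic leading-eigenvector spectral method
  (`spectral_partition()`) provides subject-specific modules as a
  robustness check.
* **Segregation** on the unthresholded matrix: per module,
  `S = (Z̄w − Z̄b)/Z̄w`, the relative excess of mean within-module over
  between-module connectivity, with all/positive-only/absolute-value
  sign-handling variants.

At the cohort level: gain scores (post − pre), Spearman and partial
Pearson correlations with seeded BCa bootstrap CIs, comparison of
independent correlations via the Myers–Sirois conversion
`r = 2 sin(π·ρ/6)` and Fisher z, 2×2 mixed ANOVA with partial η², and
baseline matching tests.

A synthetic-cohort generator (`sim_spec()`, `simulate_cohort()`) plants
block-structured modular time series and copula-linked gain scores with
known rank correlations, so every stage of the pipeline is verified by
parameter recovery — no real dataset required.

## Worked example

Simulate a 29-subject cohort (14 wait-list controls, 15 trained) with a
planted modularity–gain rank correlation of 0.65 in the trained group only,
write it as a run directory, and run the full pipeline:

```r
library(netgain)

spec <- sim_spec(seed = 42)          # 60 nodes, 6 modules, T = 120
sim  <- simulate_cohort(spec)
write_cohort(sim, "demo_run")

cfg <- run_config("demo_run", "demo_run/out", B = 2000, seed = 7)
res <- run_pipeline(cfg)

subset(res$stats, analysis == "gain_correlation" & metric == "Q")
```

```
         analysis   group metric estimate  n        p  ci_lo ci_hi
 gain_correlation Control      Q    0.103 14 7.25e-01 -0.511 0.574
 gain_correlation   SMART      Q    0.875 15 1.95e-05  0.724 0.979
```

Baseline whole-brain modularity predicts training gain in the trained
(SMART) group — rho = 0.875 with a BCa 95% CI well above zero — but not in
controls (rho = 0.103, CI spanning zero). The two correlations differ
significantly (`correlation_comparison` row: p = 0.002), and the
relationship survives controlling baseline score or head motion
(`partial_gain_correlation` rows: partial r = 0.83 and 0.87 in SMART).
This single seeded cohort happens to overshoot the planted 0.65; across
many cohorts the recovered correlation centers on it (see below).

Per-subject metrics are available directly:

```r
ts  <- sim$timeseries[[1]]
cm  <- compute_connectivity(ts)
modularity_fixed_partition(threshold_by_density(cm, 0.10), spec$partition)
#> <modularity_fit> Q = 0.8047 over 6 modules, 177 edges
module_segregation(cm, spec$partition)
#> <segregation_profile> variant = all ; whole-brain S = 0.8102
```

`run_pipeline()` writes tidy `metrics.tsv` / `stats.tsv` tables, a
`summary.json`, and a provenance log; identical configuration and seed
reproduce the tables byte for byte. A thin command-line wrapper with
`simulate` / `metrics` / `stats` / `run` / `visualize` verbs ships in
`inst/cli/netgain.R`.

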