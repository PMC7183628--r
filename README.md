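# somnonet

Network neuroscience of sleep: does the brain's effective connectivity
organize differently across sleep stages — and differently in women and
men?  `somnonet` implements the full analysis chain used to ask that
question from scalp polysomnography:

* **Epoching** — select the first three artifact-free 20-s scoring epochs
  per sleep stage (pre-onset wakefulness, stages 3/4, REM) and split them
  into twelve 5-s analysis segments, with a spectral-power homogeneity
  report.
* **Effective connectivity** — fit a multivariate autoregressive (MVAR)
  model per subject × stage by pooling the segments as trials, and compute
  the 19 × 19 matrix of conditional Granger causalities
  `F(j → i | rest) = ln(Σ′ᵢᵢ / Σᵢᵢ)` for the standard 10–20 montage, in the
  time domain and resolved into the δ/θ/α/σ/β EEG bands via the Geweke
  spectral decomposition (whose integral provably recovers the time-domain
  value — the package checks this identity on every run).
* **Network topology** — binarize at fixed edge density and compute the
  bounded small-world coefficient
  `ω = L̄_rand / L − C / C̄_latt ∈ [−1, 1]`
  against degree-preserving random (Maslov–Sneppen) and lattice surrogate
  ensembles: ω ≈ 0 small-world, ω > 0 random-like, ω < 0 lattice-like.
* **Cohort statistics** — median (P25–P75) tables, exact/normal Wilcoxon
  rank-sum sex comparisons with Bonferroni correction, and Spearman
  correlations of sex and BDI-13 depression scores with network metrics.
* **Synthetic cohorts** — a fully seeded polysomnography generator
  (band-structured stable MVAR dynamics on Watts–Strogatz coupling graphs,
  sex-specific REM rewiring, copula-coupled depression scores, EDF +
  hypnogram + artifact-mask output) so the whole pipeline runs and is
  tested without clinical data.

It is aimed at researchers doing EEG/polysomnography connectivity analyses
who want a reproducible, scriptable version of this pipeline with its
statistical behaviour verified.

## Worked example

A small synthetic cohort (8 men, 8 women), REM and stage 3, with the
generator's default sex effect (women's REM coupling graphs rewired 0.15
vs men's 0.05):

```r
library(somnonet)

cfg <- pipeline_config(
  cohort  = cohort_config(n_men = 8, n_women = 8, seed = 42),
  stages  = c("3", "REM"), epochs_per_stage = 5, fs = 128,
  mvgc    = list(order = 4, reduced_order = 4, spectral = FALSE),
  network = list(density = 0.2, n_surrogates = 10),
  seed    = 2026)
res <- run_pipeline(cfg)

res$tables$table2[, c("stage", "domain", "men", "women", "p")]
#>  stage domain                    men                  women          p
#>      3   time  -0.023 (-0.086-0.036) -0.074 (-0.093--0.056) 0.31842507
#>    REM   time -0.173 (-0.183--0.114)  -0.011 (-0.093-0.108) 0.06608192

res$tables$table3
#>  stage domain        rho          p  n
#>      3   time -0.2711631 0.30969347 16
#>    REM   time  0.4880935 0.05509622 16
```

Reading the output: each `table2` row compares men's and women's
small-world coefficients (median and quartiles) for one stage and domain
with a rank-sum p-value.  Women's REM ω sits well above men's
(−0.011 vs −0.173; their REM networks are less small-world), while stage 3
shows no systematic difference — the REM-specific sex pattern the
generator encodes.  `table3` expresses the same contrast as a Spearman
correlation with sex coded woman = 1 (REM ρ = 0.49), and `table4` (not
shown) correlates BDI with ω within each sex.  At this demonstration size
(8 + 8 subjects) the p-values hover near 0.06; the effect stabilizes at
the default 28 + 16 cohort.

Lower-level entry points mirror the pipeline stages:
`make_cohort()` / `simulate_subject()`, `extract_stage_epochs()`,
`select_model_order()` / `fit_mvar()`, `gc_time_matrix()` /
`gc_spectral_matrix()` / `integrate_band()` / `check_integration()`,
`small_world_coefficient()`, and `build_report()`.  A thin CLI wrapper
(`inst/scripts/somnonet`) exposes `simulate` and `run` subcommands over a
YAML config; `vignettes/somnonet-methods.Rmd` documents the model, the
estimators and every calibration decision.

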