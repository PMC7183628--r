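---
title: "Methods: effective connectivity and small-world analysis of sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effective connectivity and small-world analysis of sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnonet)
```

# Overview

`somnonet` implements a complete analysis chain for studying the network
organization of the sleeping brain from scalp EEG:

1. **Epoch selection** — from a sleep-staged, artifact-annotated recording,
   take the first three clean 20-s scoring epochs of each stage of interest
   (pre-sleep-onset wakefulness, stages 3 and 4 of slow-wave sleep, REM)
   and divide each into four 5-s segments, giving twelve segments per
   subject and stage.
2. **Effective connectivity** — fit one multivariate autoregressive (MVAR)
   model per subject and stage by pooling the twelve segments as
   independent trials, then compute the 19 x 19 matrix of conditional
   Granger causalities between all electrode pairs, in the time domain and
   resolved into the five classical EEG bands.
3. **Network topology** — binarize each connectivity matrix at fixed edge
   density and summarize it with the bounded small-world coefficient
   computed against degree-preserving lattice and random surrogate
   ensembles.
4. **Group statistics** — median (P25--P75) summaries, two-sided Wilcoxon
   rank-sum comparisons of men and women with Bonferroni correction, and
   Spearman correlations of sex and depression scores with network metrics.

Because clinical polysomnography cannot be redistributed, the package also
contains a fully seeded synthetic cohort generator whose outputs follow a
known ground truth, so every stage of the chain is testable end to end.

# Granger causality on an MVAR model

For channels $x_t \in \mathbb{R}^{19}$ the MVAR($p$) model is
$x_t = \sum_{k=1}^{p} A_k x_{t-k} + \varepsilon_t$,
$\varepsilon_t \sim N(0, \Sigma)$.  Segments are mean-centred per channel
and treated as independent realizations; the first $p$ samples of each
segment serve only as lags.  No detrending or filtering is applied.  The
model order is chosen by BIC over $1..p_{\max}$ by default (AIC available);
both criteria use the pooled maximum-likelihood residual covariance.

Channel $j$ Granger-causes channel $i$, conditional on the remaining
channels, when removing $j$'s past degrades the prediction of $i$:

$$F_{j \to i \mid \text{rest}} = \ln
  \frac{\Sigma'_{ii}}{\Sigma_{ii}},$$

where $\Sigma'$ is the innovation covariance of the *reduced* model without
channel $j$.  The reduced subprocess of a finite-order VAR is a VARMA
process, so `somnonet` does not refit the reduced model to data: it derives
the reduced VAR from the full model's autocovariance sequence with the
Whittle (multivariate Levinson) recursion, following the state-space
semantics of the established multivariate Granger-causality toolboxes.
This choice keeps all causalities non-negative up to rounding and makes the
spectral decomposition below internally consistent.  The reduced-model
order (`reduced_order`) is an accuracy/speed knob: the package default,
`max(p, 20)`, tracks the true subprocess closely; scaled-down survey runs
may use `reduced_order = p`, which biases individual values slightly but
preserves edge ranking (we verified ranking AUC of 1.0 at the protocol
sample size).

## Spectral decomposition and band matrices

With $A(\lambda) = I - \sum_k A_k e^{-2\pi i \lambda k / f_s}$, transfer
function $H = A^{-1}$ and cross-spectrum $S = H \Sigma H^*$, the Geweke
conditional spectral causality $f_{j \to i \mid \text{rest}}(\lambda)$ is
computed by embedding the reduced model in the full innovation space:
$Q(\lambda) = A^R(\lambda) H(\lambda) P^{-1}$ (identity on channel $j$;
$P$ orthogonalizes the other innovations against channel $i$'s), and

$$f_{j \to i \mid \text{rest}}(\lambda) =
  \ln \frac{\Sigma^R_{ii}}{\,|Q_{ii}(\lambda)|^2 \Sigma_{ii}\,}.$$

Averaged over $[0, f_s/2]$ this recovers the time-domain $F$; the package
always exposes that identity as a per-subject consistency report
(`check_integration()`), and the test suite verifies a maximum relative
error below 1% at 1024 grid points over random stable models with diagonal
innovation covariance.  The restriction to diagonal innovations is
deliberate: the classical conditional decomposition's integral identity
rests on a minimum-phase premise that strong *instantaneous* innovation
correlation can break (a property of the measure itself, shared by the
standard toolboxes, not of this estimator — we verified the same rare
violations in the textbook bivariate closed form).  Fitted models on this
package's synthetic data have near-diagonal innovations and satisfy the
identity to within $10^{-8}$; on real scalp EEG, where volume conduction
induces substantial instantaneous correlation, `check_integration()` is
precisely the guard that reports when the band decomposition should not be
trusted.  Band
matrices are trapezoidal means of $f(\lambda)$ over the five bands
delta [0.25, 3), theta [3, 8), alpha [8, 12), sigma [12, 16) and
beta [16, 32) Hz.  Band edges are half-open so the printed contiguous
limits are unambiguous, and band edges falling between grid points are
linearly interpolated so the bands plus the residual ranges tile the full
integral exactly.  Values are clamped at zero from below; clamping beyond
$10^{-10}$ on a well-conditioned fit indicates a numerical problem and is
surfaced, not hidden.

Open questions in the protocol we had to resolve: whether "all pairwise
combinations" means bivariate or conditional causality (we default to
conditional, the toolbox default, because it suppresses mediated edges),
and whether one matrix per stage comes from pooling segments or averaging
per-segment matrices (we pool, the statistically efficient reading; a
per-segment fit is a one-line variation through the same functions).

# The small-world coefficient

Each matrix is symmetrized by averaging the two directions and thresholded
to a fixed edge density (default 0.2; ties broken lexicographically), which
keeps the graph comparable across subjects — a requirement for any group
comparison.  On the binary graph we compute the Watts-Strogatz mean
clustering coefficient $C$ (degree < 2 contributes 0) and the
characteristic path length $L$ over connected pairs (disconnected pairs are
excluded and counted).  The bounded small-world coefficient is

$$\omega = \frac{\bar L_{\text{rand}}}{L} - \frac{C}{\bar C_{\text{latt}}},$$

with reference terms averaged over ensembles (default 20) of
degree-preserving surrogates: Maslov-Sneppen double-edge swaps for the
random reference, and swaps accepted only when they reduce the total ring
distance of edge endpoints for the lattice reference (10 attempted swaps
per edge each).  $\omega$ is clamped to $[-1, 1]$ with the raw value
retained; values near zero indicate small-world organization, positive
values a more random and negative values a more regular topology.  This is
the published bounded coefficient matching that semantics; the original
study's network toolbox does not document its internal formula, so the
construction rule (density, binarization, surrogate counts) is exposed as
configuration rather than hidden.

A genuine small-graph limitation worth knowing: on 19 nodes with mean
degree 4, even *fully* randomized degree-preserving surrogates have mean
path length about 2.11 versus the ring lattice's 2.78, so a perfect ring
lattice cannot score below about $-0.28$ — the dynamic range of $\omega$
compresses on small, sparse graphs. The regimes remain well separated
(ring $\approx -0.24$, Watts-Strogatz $p = 0.1$ $\approx 0$, random
$\approx +0.4$), and ensemble-mean $\omega$ increases strictly with
rewiring probability.

# Group statistics

"Wilcoxon test" for a men/women contrast is read as the two-sample
rank-sum (Mann-Whitney) test — the groups are independent, so the
signed-rank test is inapplicable.  The null distribution is enumerated
exactly for pooled samples of at most 12 without ties; otherwise the
normal approximation with tie and continuity corrections is used, and the
method is recorded.  Quartiles use linear interpolation of order
statistics (type 7), recorded in the report metadata because "P25--P75"
has several conventions.  Spearman correlations are Pearson correlations
of mid-ranks with t-approximation p-values; sex is coded woman = 1 so a
positive correlation means higher values in women.  Bonferroni correction
is applied per stage to the family of five band tests (the most
conservative family consistent with the report layout); the family size is
a visible parameter, never implicit.  Zero-variance inputs yield an
explicitly flagged undefined correlation rather than a silent NA.

# The synthetic cohort generator

The generator is calibrated once, up front, to the qualitative structure
the pipeline is meant to detect; it is a study-conditions definition, not
a tuning knob.

* **Topology.** Per subject and stage, a Watts-Strogatz-style coupling
  graph on 19 nodes with mean degree 4: an undirected ring lattice rewired
  with stage- and sex-specific probability, emitted as reciprocal directed
  edges so the undirected projection keeps constant density across
  rewiring probabilities.  Rewiring probability is the one generator knob
  that provably moves $\omega$.
* **Dynamics.** Each channel carries damped-oscillator self-dynamics with
  complex pole pairs at the stage's characteristic rhythms (wake:
  alpha 10 Hz with beta; REM: theta 5 Hz with beta; stage 3/4: delta with
  a spindle-band remnant), pole radius growing with relative band power
  (0.78--0.95). Graph edges enter as lag-1 cross-coefficients (default
  0.3). If the companion spectral radius exceeds the stability margin
  (0.95) all lag-$k$ matrices are scaled by $\gamma^k$, which shrinks
  every pole by $\gamma$ and preserves sparsity; innovations are white
  with 5 uV standard deviation.
* **Sex effect.** Men's REM graphs rewire at 0.05, women's at 0.15 (around
  which individual subjects vary via a Beta distribution with
  concentration 40), so women's REM networks are reliably less
  small-world; stage-3/4 and wake parameters are identical across sexes.
  These magnitudes are calibration decisions, not empirical claims.
* **Depression scores.** Within women, the BDI-13 score is coupled to the
  subject's REM rewiring probability through a Gaussian copula with target
  Spearman rho 0.6 (the Pearson latent correlation uses the standard
  $2\sin(\pi\rho/6)$ conversion); men's scores are independent of
  topology.  Score distributions emulate healthy-cohort demographics
  (men median ~1, women median ~4).  The BDI-13 scorer itself takes 13
  items scored 0--3 (the 0--39 total range forces the 0 lower bound,
  although the instrument is sometimes described as 1--3 per item) and
  labels severity 0--4 / 5--7 / 8--15 / >= 16.
* **Recording.** Stage blocks are simulated independently with a burn-in
  of ten model orders discarded, concatenated following a block hypnogram
  template (default 16 scoring epochs of 20 s per stage; desk-scale tests
  use 3--6), at 200 Hz by default so the 32 Hz beta edge sits comfortably
  below Nyquist.  The artifact mask is independent Bernoulli per scoring
  epoch (default rate 0.1), standing in for visual artifact screening.
  Recordings round-trip through 16-bit EDF with per-channel physical
  ranges set from the signal extrema.

What the generator deliberately does **not** emulate: EEG morphology
(spindles, K-complexes, eye movements), volume conduction, non-stationary
drift within stages, menstrual-phase physiology, and realistic hypnogram
cycling.  Consequently, passing tests demonstrate that the *estimators*
recover a known ground truth under stationary linear dynamics — they do
not certify performance on real polysomnography, where artifact structure
and volume conduction add error modes this generator cannot produce.

# Numerical and reproducibility choices

* One master seed; every module and subject derives its own child seed by
  a fixed label hash (`derive_seed()`), so stages are independently
  rerunnable yet globally reproducible, and identical configurations give
  byte-identical outputs.
* Time coordinates are 0-based half-open; scoring epochs are fixed at 20 s
  so "first three 20-s epochs" aligns one-to-one with scored epochs.
* The spectral homogeneity check reports per-band coefficients of
  variation across the twelve segments (threshold 0.5 by default) and is
  informational: the original protocol checked homogeneity but stated no
  rejection criterion, so rejecting subjects here would invent one.
* Degenerate inputs fail loudly with typed conditions: too few clean
  epochs raises an `somnonet_insufficient_data` condition naming the stage
  (the pipeline records it and continues with the other stages), fully
  disconnected graphs make the path length undefined, and zero-variance
  statistics are flagged.
* Problem sizes used by the automated checks were chosen to finish a full
  run in minutes on one core: cohort survey runs use 5 scoring epochs per
  stage at 200 Hz with model order fixed at the generator's order, the
  null-calibration sweep uses 8 + 8 subjects at 100 Hz, and surrogate
  ensembles of 10--20.  All are ordinary function arguments; full-scale
  runs only change the configuration.

# Limitations

Scalp-level Granger causality is not source-level causality; volume
conduction and reference choices affect real data in ways the synthetic
benchmark cannot reveal.  The fixed-density binarization discards weight
information, and the choice of density (default 0.2, sensible range
0.05--0.5) affects absolute $\omega$ values — only comparisons at matched
density are meaningful.  On 19-node graphs $\omega$'s dynamic range is
compressed (see above), so regime labels ("more random", "more regular")
should be read relative to the surrogate references, not on an absolute
scale.
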