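---
title: "Estimating alcohol content from sensor-array smell responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating alcohol content from sensor-array smell responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcosense)
```

## The measurement and the inference problem

A membrane-type surface stress sensor (MSS) array exposes several
differently coated channels to the headspace vapour of a liquid sample.
Sample vapour and clean purge air are alternated every 10 s; the cycle is
repeated five times and the piezoresistive readout is sampled at 20 Hz.
Each coating sorbs the vapour components with its own affinities and
kinetics, so a multi-channel measurement is a fingerprint of the smell.

The inference problem is to read one chemically meaningful number — the
alcohol content in vol % — out of that fingerprint. Real drinks make this
hard deliberately: two 40 % spirits (say vodka and gin) produce clearly
different response curves because of their other volatile components, so no
single peak height maps to alcohol content. The package treats this as a
supervised regression problem on features extracted from the response
cycles.

## Feature extraction

One cycle starting at $t_a$ is summarised by anchor values $a, b, c, d$ at
$t_a$, $t_a + 1$, $t_a + 10$, $t_a + 11$ s and the cycle maximum $e$:

$$p_1 = \frac{b-a}{t_b-t_a}, \quad p_2 = \frac{c-b}{t_c-t_b}, \quad
  p_3 = \frac{d-c}{t_d-t_c}, \quad p_4 = e-a.$$

$p_1$ reflects adsorption kinetics, $p_2$ the quasi-equilibrium regime,
$p_3$ desorption, $p_4$ sorption capacity. Anchors are read at the nearest
sampling instant (the standard cycle starts lie exactly on the 20 Hz grid),
and $e$ is taken within the cycle window $[t_a, t_a + 20)$, per cycle rather
than globally, since each cycle is an independent replicate of the response.
No baseline correction is applied: a constant offset shifts all five anchors
equally and cancels in every parameter.

Features are taken from the last three cycles ($t_a = 60, 80, 100$ s with
the 20 s pre-injection baseline), because the first two cycles of a fresh
measurement are systematically unstable. With 35 samples this yields 105
observations; the 32 training samples contribute 96.

Each feature column is divided by its standard deviation (population
convention, divisor $n$) computed **over the training rows only**, and the
stored divisors are applied unchanged to held-out rows. Restricting the
statistics to training rows avoids information leaking from the held-out
samples into the scale; the divisor-$n$ convention is a fixed choice made
for determinism — at $n = 96$ the difference from divisor-$(n-1)$ is a 0.5 %
rescaling that cancels in the kernel distances after hyperparameter tuning.

## Regression and model selection

Prediction uses Gaussian-kernel ridge regression in dual form:
$A^*(x) = k(x)^\top (K + \lambda I)^{-1} A$ with
$k(X_n, X_m) = \exp(-|X_n - X_m|^2 / 2\sigma^2)$. $I$ is the $N \times N$
identity. The dual weights are obtained by a Cholesky solve of the
symmetric system (never an explicit inverse), with a generic solver as
fallback and a residual check at $10^{-8}\,\lVert A\rVert$; an exactly
singular system (e.g. duplicated rows at $\lambda = 0$) is an error that
advises a positive ridge.

Hyperparameters $(\lambda, \sigma)$ minimise the $S$-fold cross-validation
error $\Delta(\lambda, \sigma)$, the average over folds of the held-out
mean-square deviation, on a log-spaced grid: by default $9 \times 9$ points
with $\lambda \in [10^{-6}, 10^2]$ and $\sigma \in [10^{-2}, 10^2]$
(`default_grid()`), which brackets the interpolation and heavy-shrinkage
regimes for unit-variance features; `small_grid()` is the $5 \times 5$
version used for large subset searches. Ties take the first grid point in
order, so results are reproducible.

Fold assignment is random under a stated seed. The default grouping policy
keeps the three cycles of one liquid in a single fold (`grouping =
"sample"`): cycles of the same sample are near-duplicates, and splitting
them across folds lets the model memorise rather than generalise, biasing
$\Delta$ low. The literal row-wise division is available as `grouping =
"row"` for comparison; reported results always name the policy. With 96
rows and $S = 24$, row grouping gives folds of exactly 4 rows; sample
grouping balances folds at the sample level instead (one or two samples per
fold). Normalisation is computed once on the full training set, not per
fold — the package models a single published normalisation step, and at
these sizes the per-fold alternative changes scales by under a percent.

Feature subsets are labelled by bitmasks (bit $i$ set iff parameter $i$ is
used, channel-major for multi-channel matrices; the combination
$\{1, 3, 4\}$ is 1101 in binary, label 13). The search is exhaustive — all
$2^d - 1$ non-empty masks — with the per-column squared-distance matrices
precomputed once and summed per mask, so the $\sigma$-independent part of
the kernel is never recomputed. Per-mask grid searches are independent (no
warm starts): correctness and reproducibility over speed. Equal errors rank
the smaller mask first. Usage-rate tables report, for each (channel,
parameter), the percentage of the top-$k$ masks containing it.

## The synthetic generator

No public raw traces exist for this kind of measurement, so the package
generates them. The generator is first-class, tested code, and its defaults
define the study conditions used across the test-suite.

Each channel is a sum of independent first-order sorption units, one per
headspace component: during injection $\dot s_j = (S_{mj} c_j - s_j) /
\tau_{ads,mj}$, during purge $\dot s_j = -s_j / \tau_{des,mj}$. Because
each regime is linear with constant coefficients, traces are propagated
with the exact per-sample exponential update — the sampled values equal the
continuous solution, which is also what the test suite verifies against an
independent ODE integrator. Gaussian i.i.d. noise, a linear drift and a
multiplicative instability of the first two cycles complete the model;
at the start of the third cycle each component state is set to the fixed
point of its per-cycle affine map, making cycles 3–5 exactly periodic.
That reset mirrors the empirical observation that only the later cycles are
reproducible, and it is why features are extracted from cycles 3–5; the
state adjustment at the cycle-2/3 boundary is small (the per-cycle map is a
contraction) but makes the periodicity exact rather than asymptotic.

The component library is ethanol, water and six flavour components.
Ethanol concentration equals the alcohol content (a.u. = vol %); water
varies only weakly with alcohol ($90 + 0.1(100 - A)$), reflecting
near-saturated water vapour above aqueous samples; flavours are log-normal
per sample (meanlog $\log 5$, sdlog 0.8), scaled down or off for plain
waters and binary water/ethanol mixtures. The default array has two
hydrophobic channels (ethanol-to-water sensitivity ratio $\gg 1$) and two
hydrophilic ones (ratio $< 1$). Ethanol and water sorb fast
($\tau \lesssim 0.6$ s) while flavours sorb slowly ($\tau = 10$–$35$ s), so:

* $p_1$, $p_3$, $p_4$ are ethanol-dominated on hydrophobic coatings —
  moderate-to-strong alcohol correlation;
* $p_2$, the slope between $t_a + 1$ and $t_a + 10$, sees only the
  slow flavour relaxation and drift — essentially no alcohol correlation;
* hydrophilic channels respond mostly to the nearly constant water signal,
  so their best cross-validated error is far worse, reproducing the
  qualitative coating ranking.

Noise and flavour spread were set jointly so that the pipeline's held-out
error sits near 1 (vol %)² — a realistic operating point for a
well-functioning array on unseen drinks — while equal-alcohol samples still
differ by more than the noise floor in their noiseless traces (vodka vs gin:
1.2 mV vs 0.9 mV noise sd on the octadecyl archetype). Defaults: noise sd
0.81–0.99 mV per channel, drift 2–4 µV/s, instability factor 0.9.

What the generator does **not** emulate: humidity and temperature
excursions (the measurements it models were uncontrolled ambient), sensor
aging and inter-chip variability, nonlinear sorption (saturation,
competitive adsorption), diffusion-limited tailing beyond what
$\tau_{des} > \tau_{ads}$ captures, and correlated (1/f) noise. Passing
tests therefore demonstrate the correctness and statistical sanity of the
analysis chain, not instrument-grade validation on real liquors.

## Numerical choices and degenerate inputs

* Linear systems: Cholesky with residual check at $10^{-8}$ relative;
  singularities are errors, not warnings.
* Grid ties: first occurrence in grid order; mask ties: smaller mask.
* Zero-variance feature columns abort normalisation, naming the column.
* Non-uniform sampling in a trace file is refused rather than resampled.
* Constant columns yield `NA` rank correlations rather than errors.
* PCA (for smell discrimination maps) uses the same sd-scaled features as
  the regression, column-centred; each axis's sign is fixed by making its
  largest-magnitude loading positive, so scores are reproducible across
  platforms. Explained-variance fractions are nonincreasing by
  construction.

## Problem sizes

The bundled analyses and tests run the 35-sample, four-channel panel with
24-fold sample-grouped cross-validation, the full 15-mask per-channel
search, and the $5 \times 5$ hyperparameter grid; the held-out recovery
experiment repeats the whole pipeline over five seeds. The full
$2^{16}-1$-mask cross-channel search is supported
(`search_combinations()` on all 16 columns) and scales linearly in the
number of masks; with the default grid it is an overnight-scale
computation and is therefore not part of the bundled examples.

## Known limitations

* The synthetic flavour confound is linear in the features, so a
  sufficiently flexible model can partially cancel it; real flavour
  chemistry need not be so forgiving.
* The exhaustive search treats the cross-validated $\Delta$ as the model
  quality; no nested cross-validation is performed, so $\Delta^*$ of the
  winning mask is an optimistically biased estimate of generalisation
  error — the held-out samples exist precisely to measure that bias.
* Only Gaussian kernels and exhaustive (non-greedy) search are
  implemented; both are deliberate scope choices.
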