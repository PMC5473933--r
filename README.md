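# alcosense

Quantifying the alcohol content of a liquid from its *smell*: `alcosense`
implements the analysis pipeline for electronic-nose measurements made with
a nanomechanical (membrane-type surface stress) sensor array. Headspace
vapour and purge air are alternated over the coated sensor channels in 10 s
periods, five cycles per measurement, sampled at 20 Hz. Each rise–decay
response cycle is condensed into four kinetic parameters, and a
kernel-ridge-regression model maps those parameters to alcohol content
(vol %). The package is written for chemometric/machine-olfaction work where
the raw traces are available as plain-text tables — and it ships a seeded
synthetic generator of realistic multi-component sensor responses, so every
stage of the pipeline can be exercised and tested without instrument data.

## The model

From a cycle starting at time *t<sub>a</sub>* (with *t<sub>b</sub> = t<sub>a</sub>* + 1 s,
*t<sub>c</sub> = t<sub>a</sub>* + 10 s, *t<sub>d</sub> = t<sub>a</sub>* + 11 s and
anchor signal values *a, b, c, d* plus cycle maximum *e*) four features are
extracted per channel:

- p1 = (b − a)/(t_b − t_a) — initial-rise slope (adsorption)
- p2 = (c − b)/(t_c − t_b) — quasi-equilibrium slope
- p3 = (d − c)/(t_d − t_c) — initial-decay slope (desorption)
- p4 = e − a — maximum height (sorption capacity)

Features are normalised by their training-set standard deviation. Prediction
uses Gaussian-kernel ridge regression in dual form,

    A*(x) = k(x)' (K + λI)^{-1} A,      k(X_n, X_m) = exp(−|X_n − X_m|² / 2σ²),

with hyperparameters (λ, σ) chosen by minimising the S-fold cross-validation
error Δ(λ, σ) — the average over folds of the held-out mean-square deviation —
on a log-spaced grid. Which (channel, parameter) columns enter the model is
decided by exhaustive subset search: every non-empty combination (2⁴ − 1 = 15
per channel, 2¹⁶ − 1 = 65 535 for a four-channel array) is scored by its
cross-validated error Δ and ranked; usage-rate tables summarise which
features appear in the top combinations.

## Worked example

```r
library(alcosense)
report <- run_pipeline(pipeline_config(seed = 1, grid = small_grid()))
print(report)
```

```
Smell-analysis report (seed 1)
  per-channel optimal CV errors (squared vol %):
    c18_np           mask 14 (1110)  Delta = 0.9553
    phenyl_np        mask 14 (1110)  Delta = 0.7404
    aminopropyl_np   mask  8 (1000)  Delta = 237.9852
    vinyl_np         mask 14 (1110)  Delta = 98.1575
  best: channel phenyl_np, mask 14, Delta = 0.74044 (lambda = 1e-04, sigma = 100)
  held-out sample MSE: 0.7263 (vol %)^2 over 9 records
```

The run simulates the default panel — 35 liquid samples (waters, teas, beer,
wines, spirits and 9 water/ethanol mixtures, 0–45 vol %) on a four-channel
array with two hydrophobic and two hydrophilic coatings — extracts features
from the last three cycles (t_a = 60, 80, 100 s; 105 observations, 96 of them
from the 32 training samples), and searches all 15 feature combinations per
channel with 24-fold sample-grouped cross-validation. Each line reports a
channel's best combination as a bitmask (mask 14 = 1110 means parameters 2, 3
and 4) and its prediction error Δ in squared vol %. Hydrophobic coatings
(ethanol-philic) carry the alcohol signal, so their Δ is orders of magnitude
below the hydrophilic channels'. The final line is the mean-square error on
the three held-out liquors (red wine 12 %, imo-shochu 25 %, whisky 40 %; three
cycles each), predicted by the overall best model: about 0.7 (vol %)², i.e.
sub-1-% accuracy on unseen drinks. `plot(report)` draws the parity plot;
`write_report(report, "out/")` writes all tables.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/alcosense.R simulate --seed 1 --out-dir signals/
Rscript inst/cli/alcosense.R report   --seed 1 --out-dir report/
```

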