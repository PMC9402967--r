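---
title: "Decomposition-ensemble forecasting of daily air pollutants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposition-ensemble forecasting of daily air pollutants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerocast)
```

## The problem and the method

Daily concentrations of the six routinely monitored pollutants (PM2.5,
PM10, SO2, NO2, CO, O3) are non-stationary, strongly seasonal and noisy,
which makes a single recurrent network a mediocre one-step-ahead
forecaster.  aerocast implements the decomposition-ensemble strategy:

1. **Decompose** the target series with CEEMDAN (complete ensemble
   empirical mode decomposition with adaptive noise) into intrinsic mode
   functions (IMFs) plus a smooth residue.  Each component is far more
   regular than the raw series.
2. **Forecast each component** one day ahead with a small
   convolutional-recurrent network: a valid 1-D convolution (16 filters,
   kernel 2, ReLU) over a window of the last `n` days of the component
   and, optionally, the five remaining pollutant series; non-overlapping
   max pooling; an LSTM with `cells` hidden units; a linear output unit.
3. **Tune** the two hyperparameters that matter — window length `n`
   (1–20 days) and `cells` (1–100) — by particle swarm optimization
   (PSO), minimizing the validation RMSE of the reconstructed forecast.
   One shared `(n, cells)` pair is used by all component models of a
   target.
4. **Reconstruct** the concentration forecast as the sum of the
   component predictions, and evaluate with RMSE, MAE and R².

A persistence forecast (tomorrow = today) and a no-decomposition variant
of the same network serve as the reference points: the package's
headline claim is the ordering *hybrid < no-decomposition <
persistence* in test RMSE.

## Empirical mode decomposition and its ensemble variants

`emd()` implements classical sifting: cubic-spline envelopes through the
local maxima and minima, subtraction of the envelope mean until the
Cauchy criterion `sum((h_prev - h)^2) / sum(h_prev^2) < sd_threshold`
(default 0.2, Huang's convention) or 50 iterations, then extraction of
the next mode from the running residue until the residue has fewer than
two maxima or minima.  Numerical choices, all configurable:

* **Boundary handling.**  The two extrema nearest each endpoint are
  mirrored about it before spline fitting — the standard remedy for
  end swings.  Natural splines are used.
* **Plateaus.**  A run of equal values bounded by opposite slopes is a
  single extremum at the (floor) midpoint index, which keeps the
  extrema finder deterministic.
* **Degenerate input.**  A constant series yields zero IMFs and itself
  as residue; the forecasting pipeline then falls back to a
  residue-only model with a warning.

`eemd()` averages full decompositions of noise-added copies index by
index.  `ceemdan()` follows the stage-wise scheme: mode *k* is the
ensemble mean of the *first* EMD mode of (current residue + scaled
noise), where the injected noise at stage *k* is the *k*-th EMD mode of
each white-noise realization.  Because the residue is updated by
subtraction, CEEMDAN reconstruction is exact to machine precision by
construction — a property the tests assert on every run.  Defaults:
ensemble of 100 realizations, noise amplitude 0.2 of the running
residue's standard deviation (the "adaptive" scaling; a fixed-amplitude
option exists), and **paired noise** — every draw enters with + and −
signs so the injected noise cancels exactly in ensemble means.

## The component forecaster

The LSTM cell follows the gated recurrence with an output-gate peephole:

$$i_t = \sigma(W_{hi}h_{t-1} + W_{xi}x_t + b_i),\quad
  f_t = \sigma(W_{hf}h_{t-1} + W_{xf}x_t + b_f)$$
$$c_t = f_t \odot c_{t-1} + i_t \odot \tanh(W_{xc}x_t + W_{hc}h_{t-1} + b_c)$$
$$o_t = \sigma(W_{xo}x_t + W_{ho}h_{t-1} + W_{co}c_t + b_o),\quad
  h_t = o_t \odot \tanh(c_t)$$

Biases are included on every gate (some textbook statements of these
equations omit them), and the output gate keeps its dependence on the
current cell state through `W_co`.  Statements of this recurrence that
multiply `W_ho` with the previous *input* rather than the previous
hidden state circulate in the applied literature; the standard
`h_{t-1}` form is implemented.

Training minimizes mean squared one-step error with Adam (learning rate
1e-3, batch 32, 60 epochs by default — all chosen for single-CPU desk
scale and fully configurable).  No R-level automatic differentiation
toolkit is used: forward, backpropagation-through-time and Adam are
hand-written in RcppArmadillo, with the four gate multiplications fused
into single GEMMs.  Gradient *training* runs in single precision — the
minibatch gradient noise is orders of magnitude above float rounding —
while weights are stored and all *inference* is computed in double
precision.  That split is what lets the test suite assert, to 1e-8 and
better, that the trained network's forward pass equals the composition
of the exported pure-R operators `conv1d_forward()`, `max_pool()` and
`lstm_cell_step()` on the same weights: the R operators are the
specification, the C++ engine must match them.

Seeding: all stochastic training state (weight initialization, batch
shuffling) derives from a `std::mt19937` seeded from the model spec, so
fits are bit-reproducible on a fixed build; each component model offsets
the master seed by its component index.

## Windowing, scaling and splits

`make_windows()` builds `X[t] = rows t-n … t-1` of
`[component, covariates]` with target `component[t]`: every feature
predates its target, which an index-perturbation test audits.  Channels
are min-max scaled to [0, 1] with parameters fitted **on the training
rows only**; the target shares its component channel's parameters and
predictions are inverse-scaled before reconstruction.

`split_panel()` is purely chronological: the test set is the final
calendar year, the last 20% of the remaining rows are validation, no
shuffling.  One deliberate deviation from strict causality is retained
for fidelity to the decomposition-ensemble protocol this package
implements: by default the target series is decomposed **once over its
full span**, so test-period values influence the component shapes
(`decompose_mode = "full"`).  A leakage-free `"strict"` mode
re-decomposes the history before every forecast origin; it is roughly
365 times more expensive over a test year and is exercised on a short
stretch in the tests.  Covariates always enter raw, never decomposed;
only the target is decomposed (an all-IMF-channel mode was considered
and rejected because one shared `(n, cells)` pair per target matches
how the tuned pairs are reported).

## The swarm search

`pso_optimize()` is the canonical Kennedy–Eberhart optimizer: velocity
`V ← ωV + c1 r1 (pbest − x) + c2 r2 (gbest − x)`, position `x ← x + V`,
positions clipped to the box and velocities to 0.5 of each dimension's
range; defaults ω = 0.8, c1 = c2 = 2, swarm 20, 30 iterations.  A
variant form that appears in some applied papers — minus sign on the
first stochastic term, with the roles of the personal and global bests
exchanged — diverges from every standard PSO reference; it is available
behind `legacy_update = TRUE` for comparison but never used by the
pipeline.  Positions are continuous internally and rounded to integers
only at fitness evaluation and reporting, which preserves the swarm
dynamics on the integer lattice.

The fitness of a pair `(n, cells)` is the validation RMSE of the
reconstructed forecast.  Because one evaluation means training every
component model, the search uses a reduced protocol, chosen once for
desk scale and kept fixed: 15 epochs per model, training on the most
recent 250 training windows (roughly the last eight months of the
training period), a fixed per-evaluation seed, and a cache over repeated
integer pairs.  Once the pair is selected, the final models are refit
at the full epoch budget on the training **and** validation rows
together — the validation partition informs only the selection.
Refitting on all pre-test data matters here because pollutant levels
decline from year to year, so the most recent (validation) year carries
the most relevant level information; without it the final models carry
a visible positive bias into the test year.  The min-max scaler always
stays fitted on the training rows alone.

## What the synthetic generator does and does not emulate

The package ships no monitoring data; `generate_panel()` produces the
study conditions instead.  Each channel is

```
max(0, base · (1 + trend · t/365.25) + amplitude · cos(2π(t − peak)/365.25) + e_t)
```

with AR(1) noise `e_t` driven by cross-correlated Gaussian innovations
(full-rank Cholesky factor of a 6 × 6 correlation matrix).  Defaults
emulate a heavily polluted northern city over 2016–2021: winter-peaking
annual cycles for PM2.5, PM10, SO2, NO2 and CO (highest around
mid-January, "U"-shaped years), a summer-peaking cycle for O3, slow
multi-year declines for the combustion-related channels, day-to-day
autocorrelation 0.6–0.7, and positive cross-correlations among the five
winter-peak channels with O3 coupled negatively.  The cross-correlation
values are placeholders for the qualitative statement that the six
pollutants co-move — they are **not** estimates from any real network,
which publishes no such matrix.

The generator deliberately omits: meteorological drivers (wind,
humidity, temperature inversions), sandstorm spikes and other heavy
tails, missing data, instrument drift, and spatial structure across
stations.  Passing the test suite therefore demonstrates that the
pipeline recovers structure *of the kind assumed* — seasonal, trending,
autocorrelated, cross-correlated signals — not that it attains any
particular accuracy on real monitoring records.  Published accuracy
tables for real cities enter only as bundled numeric inputs to the
comparison arithmetic (`benchmark_city_models()` and friends), which the
package reproduces exactly.

## Evaluation conventions

Two R² conventions are computed side by side: the conventional
coefficient of determination `1 − SSE/SST`, and the explained-variance
ratio `Σ(f − ȳ)² / Σ(y − ȳ)²` printed in parts of the applied
literature.  They coincide for orthogonal-projection predictions (a
property test) but the ratio form can exceed 1 for biased forecasts, so
rankings and reports use the conventional form and print the ratio
alongside.  `percent_reduction(before, after) = 100(before −
after)/before` is the single primitive behind every "errors were
reduced by X%" statement in the comparison tables.

## Health-burden module

`burden_table()` converts annual-mean concentrations, a reference
standard and an exposure-response (ER) coefficient into avoidable
premature deaths.  The built-in registries carry the 2021 WHO guideline
values and China's national first- and second-class limits (18 limits)
and ER coefficients with 95% CIs per 10 µg/m³ (1 mg/m³ for CO).  The
excess-risk model is **linear** — `ER · max(0, c̄ − ref)/step` — because
the coefficients are published directly as percentage increases per
concentration step; a log-linear relative-risk form is available behind
`log_linear = TRUE` for sensitivity analysis.  Baseline annual deaths
are a required user input: absolute avoidable-death counts depend on
population data the package does not ship, so only the structure
(zero exactly at or below the reference, monotone in exceedance and in
standard strictness, CI brackets) is asserted numerically.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own desk-scale defaults: the full 2192-day
six-year panel for the end-to-end runs; a 10-particle, 10-iteration
swarm and 15 training epochs for the seeded hybrid-versus-baseline
comparisons (5 seeds, median ordering asserted); CEEMDAN ensembles of
100 for pipeline runs and 8–16 inside property loops over dozens of
short signals; unit networks of 4–32 cells elsewhere.  The full-budget
configuration (swarm 20 × 30, 60 epochs) is the exported default for
real use.

## Known limitations

* The default decomposition protocol leaks test-period information into
  the component shapes (see above); `"strict"` mode exists but is slow.
* IMF counts are data-dependent; nothing enforces a particular number
  of modes.
* One-step horizon only; no multi-day forecasting, no spatial joint
  modelling, no meteorological covariates.
* The ER-based burden model is linear in exceedance and all-cause; no
  age stratification, cause-specific rates or life-table methods.
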