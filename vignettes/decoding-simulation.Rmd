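---
title: "Simulating neuronal ensemble properties for intracortical BMI decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating neuronal ensemble properties for intracortical BMI decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the simulation answers

Intracortical brain-machine interfaces decode movement intention from the
spiking of a few dozen motor-cortical units. The recorded ensemble changes
from session to session — how many units are well tuned to direction, how
their preferred directions (PDs) are spread, how noisy each unit is, and
whether PDs drift within a session. `bmisim` synthesizes ensembles in which
each of these properties is controlled exactly, decodes 2D movement
direction with the three classical linear decoders — the population vector
algorithm (PVA), the optimal linear estimator (OLE) and the Kalman filter
(KF) — and compares their accuracy and stability with circular statistics.

The per-bin performance metric is the angle difference (AD) between the true
and decoded heading, `AD_t = |acos(D_t · d_t)|`, summarized across repeated
runs by the circular mean of the per-run mean ADs.

## Generative model

Each neuron fires according to a cosine tuning curve with additive white
Gaussian rate noise,

    z_it = b0 + b1 dx_t + b2 dy_t + eps_t,   (b1, b2) = gain (cos PD, sin PD),
    eps_t ~ N(0, sigma2),

and spike counts in 50-ms bins are Poisson with mean `max(0, z) * 0.05`.
Holding the rate constant within a bin makes one Poisson draw per bin
distribution-identical to summing fifty 1-ms draws (Poisson additivity), so
the binned counts the decoders consume are exact while simulation cost drops
fifty-fold; `spike_events()` still exports millisecond spike times when a
train is needed. One AWGN draw is taken per bin because the noise is defined
on the firing-rate scale at which the tuning model is estimated; rates are
rectified at zero before the Poisson draw since a rate cannot be negative.

### Signal-to-noise: intrinsic versus data-driven

The intrinsic SNR is set by construction:
`SNR_int = 10 log10(SP / sigma2)` with the signal power
`SP = mean (b0 + b1 dx + b2 dy)^2` (note it includes the DC baseline). What
an experimenter can actually measure is the *data-driven* SNR: refit the
tuning curve to binned rates and replace `sigma2` by the residual power,
which also absorbs Poisson counting noise. `calibrate_snr_map()` estimates
the map between the two empirically — spikes are generated over a grid of
intrinsic SNRs, the data-driven SNR is measured, and a 6th-order polynomial
is fit to the means — and `invert_calibration()` root-finds on the monotone
fit so ensembles can be composed to hit data-driven targets. Well-tuned
neurons target 2.45 dB, poorly tuned neurons -2.31 dB.

Two numerical points about this map:

* **Rate scale.** With a unit-norm tuning vector the modulation would be
  below one spike per second, which starves the Poisson process: the
  counting noise alone (about `b0 / bin_s` in rate-power units) would cap
  the data-driven SNR far below the 2.45 dB well-tuned target. The defaults
  are `b0 = 45` and `gain = 30` spikes/s (peak 75, trough 15 — a typical M1
  range), which place the calibration ceiling near 3.3 dB so both SNR
  targets are invertible with margin. SNR itself is scale-free given the
  b0 : gain ratio, since both SP and the residual power are computed in the
  same rate units.
* **Grid range.** Rectification at zero bounds the data-driven SNR from
  below (the limit is about -3 dB as `sigma2` grows), and at an intrinsic
  SNR of -10 dB the measured value is still slightly above the poorly tuned
  target. The default grid therefore extends to -14 dB; the fitted map is
  monotone over the whole grid and round-trips through its inverse to below
  1e-9 dB.

### Ensemble geometry

`assign_pds()` spaces PDs *evenly* over an arc covering `uniformity_pct` of
the circle, centered at the bias angle. Even spacing (rather than uniform
random draws) was chosen because "uniformly distributed within an angular
subspace" is ambiguous and even spacing makes a given uniformity level
exactly reproducible; the bias dimension is explored by repeating every
condition over biases evenly spaced around the circle. Poorly tuned neurons
always cover the full circle and differ from well-tuned ones only through
their noise variance.

### Preferred-direction drift

Non-stationarity follows a Gompertz sigmoid. With `t` counted in bins from
the test onset,

    y(t) = alpha * exp(-lambda * exp(-c t)),

the PD offset rises from ~0 toward the asymptotic shift `alpha` during the
test half. A literal reading with a positive exponent rate would *decay*
during the test period, contradicting the intended protocol (PDs stationary
while training, drifting afterwards), so the rising form is used.
`lambda = ln(100)` is derived, not sampled: it pins the offset at test onset
to exactly 1% of `alpha`, and evaluating the same formula at negative `t`
keeps the whole training half below that 1% leakage. Per neuron, `alpha` is
drawn uniformly from [-45, 45] degrees and `c` from [0.001, 0.004] per bin.

## Kinematics

The decoders only ever see movement *direction* at the 20-Hz bin rate, so
the generator produces unit direction vectors directly at 50-ms bins
(default 300 s, i.e. 6000 bins, split 50/50 into training and test). Heading
evolves as a smooth random walk: angular velocity is a mean-reverting AR(1)
(Ornstein-Uhlenbeck discretization) with autocorrelation time `smoothness`
(default 1 s) and stationary sd `omega_sd` (default 2 rad/s, roughly the
heading turn rate of an unhurried scribble covering a small workspace).
These defaults give full coverage of all thirty-six 10-degree heading
sectors in every 300-s session and a circular resultant length well below
0.3, i.e. headings are diverse and unconcentrated.

This synthetic trajectory emulates a human-operated random pursuit task but
does not reproduce any particular hand path: absolute AD magnitudes depend
on the heading autocorrelation (the KF, whose state model exploits temporal
continuity, is the most sensitive to it), so quantitative results carry that
caveat, while the *comparative* structure across decoders and conditions is
what the simulation is designed to establish. Speed is not modeled; only
direction is decoded.

## Decoders

All decoders are trained per session on the first half (3000 bins) of
rates (`counts / 0.05`) and evaluated on the second half.

* **PVA** — per-neuron OLS of rate on `(1, dx, dy)` gives `b0_hat` and
  `pd_hat`; the decoded vector is the sum of unit PD vectors weighted by
  baseline-centered rates.
* **OLE** — generalized least squares through the fitted tuning matrix and
  the residual covariance `Sigma`. Observations are centered by `b0_hat`
  (the PVA's centering made explicit; an uncentered mode is exposed via
  `center = FALSE`). `Sigma` is ridge-conditioned by
  `1e-8 * mean(diag(Sigma))` (floored at 1e-10) so degenerate sweeps and
  noiseless tests remain invertible.
* **KF** — observation model `z = b0 + H d + eps` (H fitted with an
  intercept because the generated rates carry a baseline that the classical
  intercept-free observation model cannot absorb; Q is the residual
  covariance), state model `d_t = A d_{t-1} + v`
  fitted by least squares on successive training directions. The state is
  the raw 2-vector direction initialized at (1, 0) with covariance `10 I`;
  estimates are unit-normalized only when ADs are computed, never inside
  the recursion. The update is implemented in information form (posterior
  precision `P^-1 + H' Q^-1 H`), algebraically identical to the textbook
  gain form — verified against a hand-worked scalar recursion — but every
  per-bin solve stays at state dimension 2 instead of ensemble dimension.

Bins where a decoder returns a zero-magnitude vector are flagged undefined,
excluded from AD averaging and counted in a diagnostic.

## Statistics

* Circular mean via the resultant vector with a quadrant-correct
  two-argument arctangent; means of per-run ADs use the circular form, with
  the arithmetic mean kept as a diagnostic (they coincide for small ADs).
* Rayleigh uniformity test, `z = n R^2`, with the standard series
  approximation for p.
* Watson's two-sample U2 on pooled circular ranks; p-values come from a
  seeded label-permutation null (999 permutations by default) rather than
  asymptotic tables, trading speed for distributional robustness. Ties are
  collapsed mid-rank style.
* Stability: the variation of AD is the mean over successive level drops
  (100 -> 80 -> ... -> 20) of `(AD_lower - AD_higher) / higher_level`,
  computed per bias run and compared across decoders with a two-way ANOVA
  (`stats::aov`) plus Bonferroni-corrected pairwise t tests.

## Experiment drivers and problem sizes

Each driver is a pure function of its configuration and base seed; every
(cell, run) derives an independent seed (polynomial hash, kept exact in
double precision) and regenerates a fresh trajectory, since a single fixed
human trajectory cannot be reproduced anyway. Four studies are provided:
SNR-by-uniformity sweep, PWTN-by-UWTN grid, stability analysis of the grid,
and the drift experiment with a stationary control run under identical
seeds.

Replicate counts are configurable. The package's reference analyses (the
acceptance script and heavyweight tests) use 100 bias runs for the
full-tuning baseline, 20 bias runs per grid cell, 5 runs per SNR-sweep cell
and 100 drift repeats — sizes at which every comparative conclusion below is
stable across seeds while a full reproduction stays in the minutes range on
one core. The qualitative orderings are preserved under further reduction
(`n_bias_runs = 10`, `n_drift_runs = 50`).

## What passing tests do and do not show

The test suite validates the machinery against independent oracles
(closed-form tuning identities, brute-force least squares and GLS, a
hand-worked Kalman recursion, resultant-vector circular means, Monte-Carlo
type-I calibration of both circular tests) and the study-level comparative
results (decoder orderings across SNR, PWTN/UWTN dominance, triangle
asymmetry, stability ordering, drift robustness of the KF). Synthetic
ensembles are independent across neurons, perfectly cosine-tuned and
Poisson; real recordings have correlated noise, non-cosine and unstable
tuning, and spike-sorting artifacts, so passing tests demonstrate properties
of the decoders under the stated model, not performance guarantees on real
arrays. Open-loop ADs also do not predict closed-loop BMI control, where
feedback lets users compensate decoder biases.

## Known limitations

* One tuning model (cosine) and one noise model (additive Gaussian on the
  rate, independent across neurons); von Mises/Gaussian tuning and
  correlated or rate-scaled noise are out of scope.
* Direction only: no position/velocity state, no speed modulation, no 3D.
* The AD magnitudes reported for the synthetic trajectory sit 2-4 degrees
  above values reported for comparable human-trajectory analyses (see the
  kinematics caveat above); comparisons between decoders and conditions are
  the intended use.
* No refractoriness, bursting or renewal-process spiking.
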