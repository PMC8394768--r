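---
title: "Heterogeneity analysis of single-particle tracks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity analysis of single-particle tracks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfbm)
```

## The model

The package treats a 2D track `r(t) = {x(t), y(t)}`, sampled at a uniform
frame interval Δt, as a realization of heterogeneous fractional Brownian
motion (hFBM): each coordinate is `sqrt(2 D) B_H(t)`, where `B_H` is FBM
with Hurst exponent `H` and `D` is a generalized diffusion coefficient
that varies *between* tracks (and, in the two-state variant, `H` varies
*along* a track). The 2D mean squared displacement of a single track is
`4 D t^(2H)`; with the conventions `l = 1` µm and `τ = 1` s all reported
coefficients are dimensionless.

Two features of live-cell tracking data drive the whole design:

1. **Duration heterogeneity.** Track durations follow a truncated power
   law `φ(T) ∝ T^(−µ_T)` (default µ_T = 1.85): slow particles stay in the
   field of view longer. Consequently `D` and `T` are anti-correlated —
   the generator couples them deterministically as `D = c T^(−µ_D)`
   (default µ_D = 0.6, c = 0.1).
2. **Survivor averaging.** The ensemble MSD at lag `t` can only average
   tracks still alive at `t`. Combined with the coupling above, long lags
   are dominated by slow tracks, and the ensemble curve bends away from —
   and below — the single-track law. This is a sampling artifact, not
   transport physics, and the package makes it reproducible: filtering by
   duration (`filter_duration()`) restores the clean `t^(2H)` growth on
   the lags where every kept track survives.

## Estimators

* `emsd()` averages `|r(t) − r(0)|²` over surviving tracks per lag and
  records the per-lag count. Zero-padding of dead tracks was rejected:
  the survivor average is the estimator whose biases we want to expose.
* `tmsd()` is the overlapping-window time average with denominator
  `n − k` at lag `k` frames; `etmsd()` averages per-track curves without
  weighting by duration. Equality of `emsd()` and `etmsd()` on
  constant-parameter FBM (ergodicity) is asserted in the tests within
  Monte-Carlo error of the *difference* of the two estimators, which is
  much smaller than either estimator's own spread because they share the
  underlying tracks.
* `fit_power_law()` fits `log10(MSD)` on `log10(t/τ)` by OLS with equal
  weight per lag (the lag grid is linear, so this mildly emphasizes the
  long-lag end; the default fit window keeps the span small enough that
  weighting is immaterial). The default window (0.2, 2) s targets the
  intermediate regime: below ~0.2 s localization noise contributes a
  `+4σ²` offset, above a few seconds survivor bias takes over. The
  coefficient is reported in the `MSD = 4 D_α (t/τ)^α` convention.
* `tvacf()`/`etvacf()` correlate finite-difference velocities
  `v(t) = (r(t+τ_v) − r(t))/τ_v`; velocities are computed only where
  `t + τ_v` lies inside the track. For FBM the normalized curve is
  `C(t)/C(0) = (|t+τ_v|^{2H} + |t−τ_v|^{2H} − 2|t|^{2H})/(2 τ_v^{2H})`
  (`fbm_vacf_reference()`), with the characteristic dip
  `2^{2H−1} − 1` at `t = τ_v` for anti-persistent motion.
* `local_series()` computes, for every window of `N` frames (default
  N = 20, advanced one frame at a time; `N > 10` is required), the TMSD
  of the windowed sub-track and fits its first 10 lags, giving
  `α_L(t)` and `D_L(t)`. Windows with non-positive TMSD values keep
  their positive lags and are skipped below 3 usable lags. Negative
  fitted exponents (pure-noise windows) are retained: truncating them
  would distort the pooled distributions.

## The splitting rules

`split_tracks()` implements both classifiers. The excursion rule marks a
track fast when `max R(t)` strictly exceeds ε (default 0.25 µm; a
maximum exactly at ε is slow). The local-exponent rule marks a track
fast when `α_L(t) > 1` for at least 5 consecutive windows ("more than
4"); tracks with fewer windows than the run length are *unclassified*
rather than forced into a class. Raising ε can only move tracks from
fast to slow — `sensitivity_report()` tabulates counts and per-class
fits across thresholds to show that conclusions do not hinge on the
exact ε.

## The simulator and what it does (not) emulate

`simulate_fgn()` draws exact fractional Gaussian noise by circulant
embedding (Davies–Harte): the target autocovariance
`γ(k) = ½(|k+1|^{2H} − 2|k|^{2H} + |k−1|^{2H}) Δt^{2H}` is embedded in a
circulant matrix diagonalized by FFT. The embedding spectrum is
non-negative for fGn in practice; should a negative eigenvalue appear,
the generator falls back to the exact O(n²) Durbin–Levinson recursion.
Both are exact in distribution; the tests pin the sample autocovariance
at lags 0–5, the Brownian limit, and the `t^{2H}` variance law.

`simulate_hfbm()` reproduces the generative structure the estimators
assume: durations from the truncated Pareto law via inverse CDF (the
pure power law is not normalizable; the default support [0.5, 200] s
brackets the lag ranges analysed and durations are rounded down to
whole frames), diffusivities deterministically coupled to the
*pre-rounding* duration, independent fGn per coordinate, optional
i.i.d. Gaussian localization noise per frame (default σ = 0), and an
optional two-state Hurst process with exponential sojourn times.
Two-state increments are generated segment-wise and concatenated, which
drops the increment correlations *across* switch points — an explicit
approximation, acceptable because sojourns are long compared to Δt.

What the generator does **not** emulate: localization-error correlations
(motion blur), detection gaps and linking errors, spatially varying
mobility within a cell, and active directed runs with well-defined
velocities. Passing recovery tests therefore shows the estimators are
correct for the hFBM data-generating process, not that real endosome
data satisfy that process.

## Superstatistical propagators

`sample_superstat_displacements()` draws `D` from a density
`∝ D^{−1−γ}` on `[d_min, d_max]` and then a Gaussian displacement with
variance `2 D lag^α`. After scaling by the pooled standard deviation,
the displacement density has an intermediate power-law tail
`|ξ|^{−1−2γ}`. Where that regime lives matters for fitting: the
conditional standard deviations at the support edges are
`sqrt(d_min/E[D])` and `sqrt(d_max/E[D])`, and numerical integration of
the exact mixture shows the log-log slope equals `−1 − 2γ` only a few
edge scales away from both ends. `superstat_tail_range()` encodes this
as `[3·sqrt(d_min/E[D]), 0.5·sqrt(d_max/E[D])]`; on the exact mixture
density this window recovers γ ∈ {0.5, 1.0, 1.7} to within 0.02,
whereas a fixed window such as |ξ| ∈ [2, 20] overlaps the Gaussian
cutoff for small γ and biases the slope. For experimental propagators,
where the diffusivity bounds are unknown, `fit_tail_exponent()` keeps a
conventional default window and always reports the range used.

Histogram bins for propagators are uniform in the core (|ξ| ≤ 1) and
logarithmic outside (20 per decade), so the Gaussian center and a heavy
tail are both resolved; densities are normalized over the binned
support. `obstructed_propagator()` supplies the obstructed-diffusion
reference `∝ |ξ|^{−0.108} exp(−|ξ|^{1.65})` (trapezoid-normalized on
the user's grid, which must exclude ξ = 0 where the prefactor
diverges) for distinguishing obstruction from hFBM by propagator shape,
and `consistency_check()` verifies the superstatistics arithmetic
`|D_L-exponent| = 1 + γ`.

## Numerical choices and known biases

* **Log-domain fits of noisy MSDs are biased low.** `E[log X] < log E[X]`,
  so window-level fits of the 10-lag L-TMSD underestimate the exponent
  slightly; on Brownian windows of 21 points the mean `α_L` sits near
  0.9 rather than 1.0, while the distribution peaks at the true value.
  The tests assert recovery within ±0.15 and the distribution mode
  within 0.2 of `2H`. This is a property of the published window
  estimator itself; "correcting" it would change the estimator.
* **Distribution fits.** Exponential rates use the closed-form MLE
  `1/mean`. Power-law PDF exponents use log-spaced histograms (20 bins
  per decade, empty bins dropped, ≥ 3 required) with a log-log OLS; a
  truncated-Pareto MLE (`fit_truncated_pareto()`, exact likelihood
  maximized numerically) serves as a cross-check. Both are exposed
  because either convention appears in the SPT literature.
* **Ties and degenerate inputs.** Tracks shorter than 2 points are
  dropped at load with a warning; non-uniform sampling and mixed frame
  intervals are rejected rather than resampled, since every estimator
  assumes uniform Δt. Stationary tracks yield zero MSDs (all local
  windows skipped) and an error where normalization is impossible
  (VACF normalization, propagator scaling).
* **Determinism.** Every stochastic function takes a `seed` argument
  applied via a local RNG scope; fixed seeds give bit-identical
  ensembles, summaries and reports.

## Problem sizes

The test-suite and validation defaults were chosen so that tolerances
sit at roughly three Monte-Carlo standard errors: 10⁵ draws for scalar
distribution fits (rates, duration exponent, fGn autocovariance), 10⁶
displacements for propagator tails, 150–500 tracks for constant-H
ensemble checks and 1200–2000 tracks for the heterogeneous-ensemble
EMSD exponent. `run_recovery_suite(scale =)` rescales all of these for
quick smoke runs, flagging underpowered experiments instead of judging
them.

## Limitations

Beyond the generator caveats above: the package does not segment fast
tracks into directed runs and passive stretches (whole-track labels
only), does not model continuous-time random walks or generalized
Langevin dynamics (FBM references only), and the local-exponent
classifier inherits the window-level noise of `α_L(t)` — on strongly
subdiffusive data it is conservative, and short tracks remain
unclassified by construction.
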