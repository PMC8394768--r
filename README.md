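# hfbm

Heterogeneous anomalous-diffusion analysis for 2D single-particle tracking
(SPT) data, with a matched heterogeneous fractional Brownian motion (hFBM)
simulator.

Trajectories of intracellular cargo such as endosomes are strongly
heterogeneous: some particles jiggle in place for their whole observation
time (passive, subdiffusive motion in the viscoelastic cytoplasm), others
are carried by molecular motors in superdiffusive bursts. On top of that,
tracking ensembles carry a survivorship structure — slow particles stay in
the field of view longer, so trajectory duration *T* is power-law
distributed and anti-correlated with diffusivity. Ensemble averages taken
over such data can show spurious trends (even *decreasing* mean squared
displacements) that reflect the sampling, not the physics. This package is
for SPT practitioners who need to take those effects apart.

## What it computes

For tracks `r(t) = {x(t), y(t)}` sampled at a uniform frame interval Δt
(CSV format `track_id,frame,t_s,x_um,y_um`):

* **Slow/fast splitting** — a track is *fast* if its maximum excursion
  `max R(t) > ε` with `R(t) = |r(t) − r(0)|` (default ε = 0.25 µm), or,
  alternatively, if its local anomalous exponent is superdiffusive
  (`α_L(t) > 1`) for more than 4 consecutive windows.
* **MSD estimators** — ensemble average `EMSD(t) = ⟨|r(t) − r(0)|²⟩` over
  survivors, per-track time average
  `TMSD(kΔt) = (1/(n−k)) Σᵢ |r_{i+k} − r_i|²`, and their combination
  E-TMSD; power-law fits `MSD(t) = 4 D_α (t/τ)^α` in log-log coordinates
  (length scale l = 1 µm, time scale τ = 1 s).
* **Local analysis** — sliding-window TMSD (window N frames, advanced one
  frame at a time), each window fitted over its first 10 lags with
  `4 D_L(t) (t′/τ)^{α_L(t)}`, giving local exponent and diffusivity series
  along every track, their pooled distributions (exponential fits for α_L,
  power-law fits for D_L) and their rank correlation.
* **Velocity autocorrelation** — `TVACF(t) = ⟨v(t′+t)·v(t′)⟩` with
  finite-difference velocities over an interval τ, ensemble averaging, and
  the analytic FBM reference
  `C(t)/C(0) = (|t+τ|^{2H} + |t−τ|^{2H} − 2|t|^{2H}) / (2τ^{2H})`.
* **Propagators** — the density of the scaled displacement `ξ = x/σ_x` at
  a fixed lag, power-law tail fits `|ξ|^{−1−2γ}`, the analytic obstructed-
  diffusion reference `∝ |ξ|^{−0.108} exp(−|ξ|^{1.65})`, and the
  superstatistical consistency check: if the diffusivity density has a
  `D^{−1−γ}` tail, the propagator tail exponent must be `1 + 2γ`.
* **Simulation** — exact fractional Gaussian noise (circulant embedding),
  constant-parameter FBM ensembles, and hFBM ensembles with durations from
  `φ(T) ∝ T^{−1.85}`, duration-coupled diffusivities `D = c·T^{−0.6}`,
  optional two-state Hurst switching and localization noise, so every
  estimator can be validated by parameter recovery.

Everything takes and returns tibbles, composes with the pipe, and exposes
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate an ensemble with the statistical structure of a live-cell
tracking experiment, condition on duration, and fit the intermediate-lag
EMSD:

```r
library(hfbm)

tracks <- simulate_hfbm(2000, hurst = 0.25, dt = 0.05, seed = 42)
sub    <- filter_duration(tracks, 2)            # keep T > 2 s: 599 tracks
fit_power_law(emsd(sub), fit_range = c(0.2, 1))
#> Power-law fit of EMSD over [0.2, 1] s (17 lags)
#>   alpha = 0.4836, D = 0.0383, R^2 = 0.9852
```

The fitted exponent ≈ 0.5 is the single-track law `t^{2H}` at H = 0.25:
conditioning on duration removes the survivorship bias, while the
unfiltered survivor average bends downward at long lags (compare
`emsd(tracks)` against `4*mean(track_params(tracks)$d_coeff)*t^0.5`).

Local analysis of the same sub-ensemble:

```r
loc <- local_series(sub, window_points = 20)    # 127,580 windows
fit_exponential(loc$alpha_local[loc$alpha_local >= 0])
#> exponential fit (mle), rate = 2.1542, n = 126245, range [3.76e-05, 1.35]
local_correlation(loc)
#> [1] 0.5137877
```

The pooled local exponents are broadly distributed around 2H with an
exponential-type tail, and α_L is positively rank-correlated with
log D_L — the heterogeneity signature that whole-track fits average away.

Splitting a mixed ensemble and checking the anti-persistent VACF dip
against the analytic FBM curve:

```r
slow  <- simulate_fbm(60, h = 0.25, d = 0.002, n_steps = 200, dt = 0.05, seed = 1)
fast  <- simulate_fbm(40, h = 0.75, d = 0.05,  n_steps = 200, dt = 0.05, seed = 2)
fast$track_id <- sub("fbm", "fast", fast$track_id)
mixed <- as_tracks(dplyr::bind_rows(slow, fast))

parts <- split_tracks(mixed, epsilon = 0.25)    # 38 slow, 62 fast
etvacf(parts$slow, tau = 0.05, normalize = TRUE)$value[2]
#> [1] -0.288
fbm_vacf_reference(0.25, 0.05, 0.05)
#> [1] -0.293

sensitivity_report(mixed, epsilons = c(0.2, 0.25), fit_range = NULL)
#> # A tibble: 2 x 3
#>   epsilon n_slow n_fast
#>     <dbl>  <int>  <int>
#> 1    0.2      14     86
#> 2    0.25     38     62
```

Propagator tails tie back to the diffusivity distribution: a
superstatistical sample built from `p(D) ∝ D^{−1−γ}` with γ = 1.7 over
four decades recovers its tail index from the `|ξ|^{−1−2γ}` fit,

```r
x <- sample_superstat_displacements(1e6, gamma = 1.7, d_min = 1, d_max = 1e4, seed = 43)
fit_tail_exponent(displacement_pdf(x), superstat_tail_range(1.7, 1, 1e4))
#> Propagator tail fit over |xi| in [1.92659, 32.1099] (49 bins)
#>   slope = -4.308, gamma = 1.654, R^2 = 0.9893
consistency_check(2.7, 1.7)$consistent
#> [1] TRUE
```

`run_pipeline()` chains simulate → split → MSD/local/VACF/propagator and
writes every table plus a JSON summary; `run_recovery_suite()` re-derives
each fitted quantity from known generating values.

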