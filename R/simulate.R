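#' Autocovariance of fractional Gaussian noise
#'
#' Autocovariance of the stationary increment process of fractional
#' Brownian motion sampled at interval `dt`:
#' \deqn{\gamma(k) = \tfrac12\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right)\,dt^{2H}.}
#'
#' @param k Integer lag(s).
#' @param h Hurst exponent in (0, 1).
#' @param dt Sampling interval in seconds.
#' @return Numeric vector of autocovariances.
#' @export
#' @examples
#' fgn_autocov(0:3, h = 0.25)
fgn_autocov <- function(k, h, dt = 1) {
  check_number(h, "h", 0, 1, strict = TRUE)
  0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h)) * dt^(2 * h)
}

#' Simulate fractional Gaussian noise
#'
#' Draws `n` stationary Gaussian increments of fractional Brownian motion
#' with Hurst exponent `h`, exact in distribution. The default method is
#' circulant embedding (Davies-Harte): the target autocovariance is
#' embedded in a circulant matrix whose eigenvalues are obtained by FFT,
#' giving O(n log n) exact sampling. In the rare case of a negative
#' eigenvalue the generator falls back to the O(n^2) Durbin-Levinson
#' recursion, which is exact for any valid autocovariance.
#'
#' The cumulative sum of the returned increments is an FBM path with
#' `Var[B_H(k dt)] = (k dt)^(2H)`.
#'
#' @inheritParams fgn_autocov
#' @param n Number of increments (at least 1).
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param method `"davies_harte"` (default, with automatic fallback) or
#'   `"durbin_levinson"`.
#' @return Numeric vector of `n` increments.
#' @export
#' @examples
#' x <- simulate_fgn(h = 0.25, n = 1000, seed = 1)
#' cor(x[-1], x[-1000]) # close to 2^(2 * 0.25 - 1) - 1
simulate_fgn <- function(h, n, dt = 1, seed = NULL,
                         method = c("davies_harte", "durbin_levinson")) {
  check_number(h, "h", 0, 1, strict = TRUE)
  check_number(dt, "dt", 0, strict = TRUE)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  method <- match.arg(method)
  with_seed_if(seed, {
    if (method == "durbin_levinson") {
      fgn_durbin_levinson(h, n, dt)
    } else {
      fgn_davies_harte(h, n, dt)
    }
  })
}

fgn_davies_harte <- function(h, n, dt) {
  if (n == 1) {
    return(rnorm(1, sd = dt^h))
  }
  g <- fgn_autocov(0:n, h, dt)
  row <- c(g, rev(g[2:n]))
  m <- 2L * n
  lam <- Re(fft(row))
  if (min(lam) < -1e-8 * max(lam)) {
    return(fgn_durbin_levinson(h, n, dt))
  }
  lam[lam < 0] <- 0
  # draw order is fixed so results are reproducible across methods of call
  z0 <- rnorm(1)
  zn <- rnorm(1)
  u <- rnorm(n - 1)
  v <- rnorm(n - 1)
  w <- complex(length.out = m)
  w[1] <- sqrt(lam[1]) * z0
  w[n + 1] <- sqrt(lam[n + 1]) * zn
  w[2:n] <- sqrt(lam[2:n] / 2) * complex(real = u, imaginary = v)
  w[m:(n + 2)] <- Conj(w[2:n])
  Re(fft(w))[1:n] / sqrt(m)
}

fgn_durbin_levinson <- function(h, n, dt) {
  g <- fgn_autocov(0:(n - 1), h, dt)
  x <- numeric(n)
  z <- rnorm(n)
  x[1] <- z[1] * sqrt(g[1])
  if (n == 1) {
    return(x)
  }
  phi <- numeric(n)
  v <- g[1]
  for (k in 1:(n - 1)) {
    if (k == 1) {
      phi_new <- g[2] / g[1]
      phi[1] <- phi_new
    } else {
      phi_new <- (g[k + 1] - sum(phi[1:(k - 1)] * g[k:2])) / v
      phi[1:(k - 1)] <- phi[1:(k - 1)] - phi_new * phi[(k - 1):1]
      phi[k] <- phi_new
    }
    v <- v * (1 - phi_new^2)
    mu <- sum(phi[1:k] * x[k:1])
    x[k + 1] <- mu + sqrt(v) * z[k + 1]
  }
  x
}

#' Sample trajectory durations from a truncated power law
#'
#' Trajectory durations of tracked intracellular particles follow a
#' power-law distribution: slow particles stay in the field of view
#' longer, so long tracks are rare but present. Draws are i.i.d. from the
#' truncated Pareto density proportional to `T^-mu_t` on
#' `[t_min, t_max]`, sampled by inverse-CDF.
#'
#' @param n Number of draws.
#' @param mu_t Power-law exponent (> 1); the default 1.85 matches the
#'   duration statistics of live-cell endosome ensembles.
#' @param t_min,t_max Truncation bounds in seconds, `0 < t_min < t_max`.
#'   A pure `T^-mu_t` law is not normalizable, so finite bounds are part
#'   of the model.
#' @param seed Optional integer seed.
#' @return Numeric vector of durations in seconds.
#' @export
#' @examples
#' t <- sample_durations(1000, seed = 1)
#' fit_truncated_pareto(t, t_min = 0.5, t_max = 200)
sample_durations <- function(n, mu_t = 1.85, t_min = 0.5, t_max = 200, seed = NULL) {
  check_number(mu_t, "mu_t", 1, strict = TRUE)
  check_number(t_min, "t_min", 0, strict = TRUE)
  if (t_max <= t_min) abort("`t_max` must exceed `t_min`")
  stopifnot(n >= 1)
  with_seed_if(seed, {
    u <- runif(n)
    a <- 1 - mu_t # CDF ~ (T^a - t_min^a) / (t_max^a - t_min^a)
    (t_min^a + u * (t_max^a - t_min^a))^(1 / a)
  })
}

#' Maximum-likelihood exponent of a truncated Pareto sample
#'
#' Estimates the exponent `mu` of a density proportional to `x^-mu` on
#' the known support `[t_min, t_max]` by one-dimensional maximization of
#' the exact truncated-Pareto log-likelihood.
#'
#' @param x Positive sample, all values within `[t_min, t_max]`.
#' @param t_min,t_max Known truncation bounds.
#' @param interval Search interval for the exponent.
#' @return The MLE of the exponent (a single number).
#' @export
fit_truncated_pareto <- function(x, t_min, t_max, interval = c(1.0001, 10)) {
  stopifnot(length(x) >= 10)
  if (any(x < t_min) || any(x > t_max)) abort("sample outside [t_min, t_max]")
  s <- sum(log(x))
  n <- length(x)
  nll <- function(mu) {
    a <- 1 - mu
    logz <- log((t_max^a - t_min^a) / a)
    mu * s + n * logz
  }
  optimize(nll, interval = interval)$minimum
}

#' Simulate an ensemble of FBM tracks with fixed parameters
#'
#' Generates `n_traj` independent 2D fractional Brownian motion tracks of
#' equal length with a single Hurst exponent and a single generalized
#' diffusion coefficient. Each coordinate is `sqrt(2 * d) * B_H(t)` plus
#' optional i.i.d. Gaussian localization noise per frame, so the 2D MSD
#' of the noiseless path is `4 * d * t^(2H)` (in micrometer and second
#' units with the dimensionless convention `l = 1` um, `tau = 1` s).
#'
#' @param n_traj Number of tracks.
#' @param h Hurst exponent in (0, 1).
#' @param d Generalized diffusion coefficient (dimensionless, `l = 1` um,
#'   `tau = 1` s convention).
#' @param n_steps Number of increments per track (tracks have
#'   `n_steps + 1` points).
#' @param dt Frame interval in seconds.
#' @param noise_sigma Standard deviation of static localization noise in
#'   micrometers, added independently to every coordinate of every frame.
#' @param seed Optional integer seed.
#' @return A `hfbm_tracks` table; `meta` holds the simulation parameters
#'   and a per-track parameter tibble (see [track_params()]).
#' @export
simulate_fbm <- function(n_traj, h = 0.25, d = 0.1, n_steps = 1024, dt = 0.05,
                         noise_sigma = 0, seed = NULL) {
  check_number(h, "h", 0, 1, strict = TRUE)
  check_number(d, "d", lower = 0)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  stopifnot(n_traj >= 1, n_steps >= 1)
  params <- tibble::tibble(
    track_id = sprintf("fbm_%04d", seq_len(n_traj)),
    n_steps = as.integer(n_steps),
    duration_s = n_steps * dt,
    d_coeff = d,
    hurst = h
  )
  with_seed_if(seed, {
    build_ensemble(params, dt, noise_sigma, meta = list(
      source = "simulate_fbm", h = h, d = d, n_steps = n_steps, dt = dt,
      noise_sigma = noise_sigma, seed = seed
    ))
  })
}

#' Simulate a heterogeneous-FBM ensemble
#'
#' Generates an ensemble of 2D fractional Brownian motion tracks whose
#' durations follow a truncated power law `phi(T) ~ T^-mu_t` and whose
#' generalized diffusion coefficients are deterministically coupled to
#' duration, `D = c * T^-mu_d`. This reproduces the heterogeneity of
#' live-cell tracking ensembles, where slowly moving particles remain in
#' the field of view longer: duration and diffusivity are anti-correlated,
#' which biases long-lag ensemble averages over survivors.
#'
#' The Hurst exponent is either a single constant for all tracks or a
#' two-state telegraph process per track (see [hurst_two_state()]): `H`
#' switches between a persistent (> 0.5) and an anti-persistent (< 0.5)
#' value with exponentially distributed sojourn times, and increments are
#' generated segment-wise (correlations across segment boundaries are
#' neglected, an explicit approximation).
#'
#' @param n_traj Number of tracks.
#' @param hurst A single Hurst exponent in (0, 1), or the result of
#'   [hurst_two_state()].
#' @param dt Frame interval in seconds.
#' @param mu_t,t_min,t_max Duration-law parameters, see
#'   [sample_durations()]. Durations are rounded down to whole frames.
#' @param coupling_c,mu_d Coupling `D = coupling_c * T^-mu_d` between the
#'   generalized diffusion coefficient and the duration (seconds) of each
#'   track.
#' @param noise_sigma Localization noise s.d. in micrometers (0 = none).
#' @param seed Optional integer seed.
#' @return A `hfbm_tracks` table with per-track parameters in
#'   `meta$params` (see [track_params()]).
#' @export
#' @examples
#' tr <- simulate_hfbm(20, seed = 1)
#' track_params(tr)
simulate_hfbm <- function(n_traj, hurst = 0.25, dt = 0.05,
                          mu_t = 1.85, t_min = 0.5, t_max = 200,
                          coupling_c = 0.1, mu_d = 0.6,
                          noise_sigma = 0, seed = NULL) {
  stopifnot(n_traj >= 1)
  check_number(coupling_c, "coupling_c", 0, strict = TRUE)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  if (t_min < 2 * dt) {
    abort("`t_min` must be at least 2 * dt so every track has >= 2 points")
  }
  with_seed_if(seed, {
    durations <- sample_durations(n_traj, mu_t = mu_t, t_min = t_min, t_max = t_max)
    n_steps <- pmax(1L, as.integer(floor(durations / dt)))
    params <- tibble::tibble(
      track_id = sprintf("hfbm_%05d", seq_len(n_traj)),
      n_steps = n_steps,
      duration_s = n_steps * dt,
      d_coeff = coupling_c * durations^(-mu_d),
      hurst = if (is.numeric(hurst)) hurst else NA_real_
    )
    build_ensemble(params, dt, noise_sigma, hurst_process = hurst, meta = list(
      source = "simulate_hfbm", hurst = hurst, dt = dt,
      mu_t = mu_t, t_min = t_min, t_max = t_max,
      coupling_c = coupling_c, mu_d = mu_d,
      noise_sigma = noise_sigma, seed = seed
    ))
  })
}

#' Two-state Hurst exponent process
#'
#' Describes a telegraph switch of the Hurst exponent between a
#' persistent and an anti-persistent value with exponential sojourn
#' times, for use as the `hurst` argument of [simulate_hfbm()].
#'
#' @param h_persistent Hurst value > 0.5 (directed, persistent motion).
#' @param h_antipersistent Hurst value < 0.5 (viscoelastic caging).
#' @param mean_sojourn Mean sojourn time in each state, seconds.
#' @return An object of class `hfbm_hurst_two_state`.
#' @export
hurst_two_state <- function(h_persistent = 0.75, h_antipersistent = 0.25,
                            mean_sojourn = 1) {
  check_number(h_persistent, "h_persistent", 0.5, 1, strict = TRUE)
  check_number(h_antipersistent, "h_antipersistent", 0, 0.5, strict = TRUE)
  check_number(mean_sojourn, "mean_sojourn", 0, strict = TRUE)
  structure(
    list(
      h_persistent = h_persistent, h_antipersistent = h_antipersistent,
      mean_sojourn = mean_sojourn
    ),
    class = "hfbm_hurst_two_state"
  )
}

# generate the tracks for a per-track parameter table (RNG already seeded)
build_ensemble <- function(params, dt, noise_sigma, meta, hurst_process = NULL) {
  n_traj <- nrow(params)
  per_track <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    n <- params$n_steps[i]
    amp <- sqrt(2 * params$d_coeff[i])
    if (inherits(hurst_process, "hfbm_hurst_two_state")) {
      inc_x <- switching_fgn(hurst_process, n, dt)
      inc_y <- switching_fgn(hurst_process, n, dt)
    } else {
      h <- if (!is.null(hurst_process)) hurst_process else params$hurst[i]
      inc_x <- fgn_davies_harte(h, n, dt)
      inc_y <- fgn_davies_harte(h, n, dt)
    }
    x <- c(0, cumsum(amp * inc_x))
    y <- c(0, cumsum(amp * inc_y))
    if (noise_sigma > 0) {
      x <- x + rnorm(n + 1, sd = noise_sigma)
      y <- y + rnorm(n + 1, sd = noise_sigma)
    }
    per_track[[i]] <- tibble::tibble(
      track_id = params$track_id[i],
      frame = 0:n,
      t_s = (0:n) * dt,
      x_um = x,
      y_um = y
    )
  }
  meta$params <- params
  new_tracks(dplyr::bind_rows(per_track), dt = dt, meta = meta)
}

# fGn with a two-state Hurst exponent: exponential sojourns, segment-wise
# exact generation, segments concatenated (cross-segment correlations
# are dropped by construction)
switching_fgn <- function(hp, n, dt) {
  out <- numeric(0)
  state <- sample(c(TRUE, FALSE), 1) # TRUE = persistent
  while (length(out) < n) {
    sojourn_steps <- max(1L, as.integer(ceiling(rexp(1, rate = 1 / hp$mean_sojourn) / dt)))
    sojourn_steps <- min(sojourn_steps, n - length(out))
    h <- if (state) hp$h_persistent else hp$h_antipersistent
    out <- c(out, fgn_davies_harte(h, sojourn_steps, dt))
    state <- !state
  }
  out
}

#' Per-track simulation parameters
#'
#' Returns the generating parameters (duration, diffusion coefficient,
#' Hurst exponent) of each track of a simulated ensemble, as recorded in
#' the ensemble's `meta`.
#'
#' @param tracks A simulated track table.
#' @return A tibble with one row per track.
#' @export
track_params <- function(tracks) {
  p <- tracks_meta(tracks)$params
  if (is.null(p)) abort("this track table carries no simulation parameters")
  p
}

#' Sample superstatistical displacements
#'
#' Draws displacements from a Gaussian mixture over a power-law
#' distributed diffusivity: `D` has density proportional to
#' `D^(-1 - gamma)` on `[d_min, d_max]` and, conditional on `D`, the
#' displacement is Gaussian with variance `2 * D * lag^alpha`. After
#' scaling by the pooled standard deviation, the displacement density
#' develops an intermediate power-law tail proportional to
#' `|xi|^(-1 - 2 gamma)` over the range of scales set by the diffusivity
#' bounds; see [superstat_tail_range()] for where that regime lies.
#'
#' @param n Number of draws.
#' @param gamma Diffusivity tail index (> 0).
#' @param d_min,d_max Diffusivity bounds, `0 < d_min < d_max`.
#' @param lag Lag time in seconds at which displacements are taken.
#' @param alpha Anomalous exponent entering the conditional variance.
#' @param seed Optional integer seed.
#' @return Numeric vector of displacements (micrometers).
#' @export
#' @examples
#' x <- sample_superstat_displacements(1e4, gamma = 0.5, d_min = 1e-2, d_max = 1e2, seed = 1)
sample_superstat_displacements <- function(n, gamma, d_min, d_max,
                                           lag = 1, alpha = 1, seed = NULL) {
  check_number(gamma, "gamma", 0, strict = TRUE)
  check_number(d_min, "d_min", 0, strict = TRUE)
  if (d_max < d_min) abort("`d_max` must be >= `d_min`")
  check_number(lag, "lag", 0, strict = TRUE)
  stopifnot(n >= 1)
  with_seed_if(seed, {
    if (d_max == d_min) {
      d <- rep(d_min, n)
    } else {
      # inverse CDF of density ~ D^(-1-gamma) on [d_min, d_max]
      u <- runif(n)
      d <- (d_min^(-gamma) + u * (d_max^(-gamma) - d_min^(-gamma)))^(-1 / gamma)
    }
    rnorm(n, sd = sqrt(2 * d * lag^alpha))
  })
}

#' Mean diffusivity and tail window of a superstatistical sample
#'
#' `superstat_mean_d()` is the exact mean of the truncated power-law
#' diffusivity density proportional to `D^(-1 - gamma)` on
#' `[d_min, d_max]`. `superstat_tail_range()` converts the diffusivity
#' bounds into the window of scaled displacements `xi = x / sigma_x`
#' where the `|xi|^(-1 - 2 gamma)` regime holds: the conditional standard
#' deviations at the support edges are `sqrt(d_min / E[D])` and
#' `sqrt(d_max / E[D])`, and the power law is clean a few conditional
#' standard deviations above the lower edge and below the Gaussian
#' cutoff of the upper edge.
#'
#' @inheritParams sample_superstat_displacements
#' @param lo_mult,hi_mult Multipliers applied to the edge scales to set
#'   the fit window (defaults 3 and 0.5).
#' @return `superstat_mean_d()` a number; `superstat_tail_range()` a
#'   length-2 numeric vector `c(lo, hi)` in units of `xi`.
#' @export
superstat_mean_d <- function(gamma, d_min, d_max) {
  check_number(gamma, "gamma", 0, strict = TRUE)
  if (abs(gamma - 1) < 1e-12) {
    log(d_max / d_min) / (1 / d_min - 1 / d_max)
  } else {
    ((d_max^(1 - gamma) - d_min^(1 - gamma)) / (1 - gamma)) /
      ((d_min^(-gamma) - d_max^(-gamma)) / gamma)
  }
}

#' @rdname superstat_mean_d
#' @export
superstat_tail_range <- function(gamma, d_min, d_max, lo_mult = 3, hi_mult = 0.5) {
  ed <- superstat_mean_d(gamma, d_min, d_max)
  c(lo_mult * sqrt(d_min / ed), hi_mult * sqrt(d_max / ed))
}
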