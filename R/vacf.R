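#' Velocity autocorrelation functions
#'
#' Finite-difference velocities over the interval `tau` are
#' `v(t) = (r(t + tau) - r(t)) / tau`, defined wherever `t + tau` lies
#' inside the track. `tvacf()` computes the time-averaged autocorrelation
#' of one or more tracks,
#' `TVACF(t) = < v(t' + t) . v(t') >_{t'}` (full 2D dot product), and
#' `etvacf()` averages the per-track curves over the ensemble at each
#' lag, skipping and counting tracks that are too short.
#'
#' For anti-persistent motion (fractional Brownian motion with Hurst
#' exponent below 1/2) the normalized curve dips negative at `t = tau`
#' and approaches zero from below; persistent motion keeps it positive.
#' Compare against the analytic reference [fbm_vacf_reference()].
#'
#' @param tracks A track table.
#' @param tau Velocity-differencing interval in seconds; must be an
#'   integer multiple of the frame interval.
#' @param max_lag Largest lag in seconds (default: for each track the
#'   largest lag with at least one admissible velocity pair, capped at
#'   half the duration for `tvacf()`; for `etvacf()` half the longest
#'   duration).
#' @param normalize If `TRUE`, each track's curve is divided by its
#'   value at lag 0 (the time-averaged squared speed) before any
#'   ensemble averaging.
#' @return `tvacf()`: a tibble `track_id`, `lag_s`, `value` (lag 0
#'   included). `etvacf()`: a `hfbm_lagcurve` tibble `lag_s`, `value`,
#'   `n`.
#' @export
#' @examples
#' tr <- as_tracks(data.frame(track_id = "a", t_s = 0:9, x_um = 0:9, y_um = 0))
#' tvacf(tr, tau = 1)$value # ballistic: 1 at every lag
tvacf <- function(tracks, tau, max_lag = NULL, normalize = FALSE) {
  tl <- track_list(tracks)
  if (length(tl$ids) == 0) abort("empty track table")
  dt <- tracks_dt(tracks)
  m <- tau / dt
  if (abs(m - round(m)) > 1e-6) abort("`tau` must be an integer multiple of dt")
  m <- as.integer(round(m))
  if (m < 1) abort("`tau` must be at least one frame interval")
  out <- vector("list", length(tl$ids))
  for (i in seq_along(tl$ids)) {
    x <- tl$x[[i]]
    y <- tl$y[[i]]
    n <- length(x)
    nv <- n - m # number of velocity samples
    if (nv < 1) {
      abort(sprintf(
        "track '%s' has %d points; needs more than %d for tau = %g s",
        tl$ids[i], n, m, tau
      ))
    }
    vx <- (x[(1 + m):n] - x[1:nv]) / tau
    vy <- (y[(1 + m):n] - y[1:nv]) / tau
    k_cap <- if (is.null(max_lag)) min(nv - 1L, (n - 1L) %/% 2L) else {
      as.integer(floor(max_lag / dt + 1e-9))
    }
    k_cap <- min(k_cap, nv - 1L)
    ks <- 0:max(k_cap, 0L)
    vals <- vapply(ks, function(k) {
      idx <- 1:(nv - k)
      mean(vx[idx + k] * vx[idx] + vy[idx + k] * vy[idx])
    }, numeric(1))
    if (normalize) {
      if (vals[1] == 0) abort(sprintf("track '%s' has zero squared speed; cannot normalize", tl$ids[i]))
      vals <- vals / vals[1]
    }
    out[[i]] <- tibble::tibble(track_id = tl$ids[i], lag_s = ks * dt, value = vals)
  }
  dplyr::bind_rows(out)
}

#' @rdname tvacf
#' @export
etvacf <- function(tracks, tau, max_lag = NULL, normalize = FALSE) {
  dt <- tracks_dt(tracks)
  durs <- track_durations(tracks)
  if (is.null(max_lag)) max_lag <- max(durs$duration_s) / 2
  # a track admits lag k if it has at least one velocity pair there
  min_pts <- ceiling(tau / dt) + 1 + 1 # >= 2 velocity samples for lag >= 1
  keep <- durs$track_id[durs$n_points >= min_pts]
  if (length(keep) == 0) abort("no track is long enough for this tau")
  sub <- new_tracks(
    tibble::as_tibble(tracks)[tracks$track_id %in% keep, , drop = FALSE],
    dt = dt, meta = tracks_meta(tracks)
  )
  per <- tvacf(sub, tau = tau, max_lag = max_lag, normalize = normalize)
  agg <- dplyr::summarise(
    dplyr::group_by(per, .data$lag_s),
    value = mean(.data$value), n = dplyr::n(), .groups = "drop"
  )
  agg <- dplyr::arrange(agg, .data$lag_s)
  new_lagcurve(agg$lag_s, agg$value, agg$n,
    kind = if (normalize) "E-TVACF (normalized)" else "E-TVACF"
  )
}

#' Analytic velocity autocorrelation of fractional Brownian motion
#'
#' Normalized VACF of FBM increments over a differencing interval `tau`:
#' \deqn{C(t)/C(0) = \frac{|t+\tau|^{2H} + |t-\tau|^{2H} - 2|t|^{2H}}{2\tau^{2H}}.}
#' At `t = tau` this equals `2^(2H - 1) - 1` (about -0.293 for
#' `H = 0.25`); for `H = 1/2` it vanishes for all `t >= tau`.
#'
#' @param h Hurst exponent in (0, 1).
#' @param tau Velocity-differencing interval in seconds.
#' @param lags Numeric vector of lag times in seconds.
#' @return Numeric vector of normalized autocorrelations.
#' @export
#' @examples
#' fbm_vacf_reference(0.25, tau = 1, lags = 0:3)
fbm_vacf_reference <- function(h, tau, lags) {
  check_number(h, "h", 0, 1, strict = TRUE)
  check_number(tau, "tau", 0, strict = TRUE)
  (abs(lags + tau)^(2 * h) + abs(lags - tau)^(2 * h) - 2 * abs(lags)^(2 * h)) /
    (2 * tau^(2 * h))
}
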