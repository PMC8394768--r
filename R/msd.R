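#' Ensemble-averaged mean squared displacement
#'
#' EMSD at lag `t = k * dt` is the average of
#' `(x_i(t) - x_i(0))^2 + (y_i(t) - y_i(0))^2` over all tracks still
#' alive at that lag (a survivor average: a track contributes at lag `t`
#' only if its duration is at least `t`). Values are normalized by `l^2`
#' with the default length scale `l = 1` micrometer, making the curve
#' dimensionless.
#'
#' The survivor average matters: when diffusivity and duration are
#' coupled, long lags are dominated by long-lived (slow) tracks and the
#' EMSD bends away from the single-track law. Use [filter_duration()]
#' first to study that effect on sub-ensembles.
#'
#' @param tracks A track table.
#' @param max_lag Largest lag in seconds; defaults to the longest track
#'   duration. If it exceeds the longest duration the curve is truncated
#'   with a warning.
#' @param l Length scale in micrometers used for nondimensionalization.
#' @return A `hfbm_lagcurve` tibble with columns `lag_s`, `value`,
#'   `n` (tracks contributing per lag).
#' @export
#' @examples
#' tr <- simulate_fbm(20, h = 0.5, d = 1, n_steps = 100, seed = 1)
#' fit_power_law(emsd(tr), fit_range = c(0.1, 2))
emsd <- function(tracks, max_lag = NULL, l = 1) {
  tl <- track_list(tracks)
  if (length(tl$ids) == 0) abort("empty track table")
  dt <- tracks_dt(tracks)
  check_number(l, "l", 0, strict = TRUE)
  n_pts <- lengths(tl$x)
  k_longest <- max(n_pts) - 1L
  k_max <- if (is.null(max_lag)) k_longest else as.integer(floor(max_lag / dt + 1e-9))
  if (k_max > k_longest) {
    warn(sprintf(
      "max_lag %.3g s exceeds the longest duration %.3g s; curve truncated",
      max_lag, k_longest * dt
    ))
    k_max <- k_longest
  }
  if (k_max < 1) abort("max_lag is below one frame interval")
  sums <- numeric(k_max)
  counts <- integer(k_max)
  for (i in seq_along(tl$x)) {
    x <- tl$x[[i]]
    y <- tl$y[[i]]
    kk <- min(length(x) - 1L, k_max)
    if (kk < 1) next
    sd2 <- (x[1 + 1:kk] - x[1])^2 + (y[1 + 1:kk] - y[1])^2
    sums[1:kk] <- sums[1:kk] + sd2
    counts[1:kk] <- counts[1:kk] + 1L
  }
  keep <- counts > 0
  new_lagcurve(
    lag_s = (1:k_max)[keep] * dt,
    value = (sums[keep] / counts[keep]) / l^2,
    n = counts[keep],
    kind = "EMSD"
  )
}

#' Time-averaged mean squared displacement
#'
#' `tmsd()` computes, for each track, the overlapping-window time average
#' \deqn{\mathrm{TMSD}(k\Delta t) = \frac{1}{n-k} \sum_{i=0}^{n-1-k}
#'   (x_{i+k}-x_i)^2 + (y_{i+k}-y_i)^2,}
#' normalized by `l^2`. `etmsd()` averages the per-track TMSD curves over
#' the ensemble at each lag (tracks too short for a lag are skipped and
#' the per-lag count reported).
#'
#' @inheritParams emsd
#' @param max_lag Largest lag in seconds; per track, lags with no
#'   admissible pair are dropped. Defaults to half of each track's
#'   duration for `tmsd()` and to half the longest duration for
#'   `etmsd()`.
#' @return `tmsd()`: a tibble `track_id`, `lag_s`, `value`, `n_pairs`.
#'   `etmsd()`: a `hfbm_lagcurve` tibble (`lag_s`, `value`, `n`).
#' @export
#' @examples
#' tr <- as_tracks(data.frame(
#'   track_id = "a", t_s = 0:3, x_um = c(0, 1, 2, 3), y_um = 0
#' ))
#' tmsd(tr, max_lag = 3) # 1, 4, 9 at lags 1, 2, 3
tmsd <- function(tracks, max_lag = NULL, l = 1) {
  tl <- track_list(tracks)
  if (length(tl$ids) == 0) abort("empty track table")
  dt <- tracks_dt(tracks)
  check_number(l, "l", 0, strict = TRUE)
  out <- vector("list", length(tl$ids))
  for (i in seq_along(tl$ids)) {
    x <- tl$x[[i]]
    y <- tl$y[[i]]
    n <- length(x)
    k_max <- if (is.null(max_lag)) max(1L, (n - 1L) %/% 2L) else as.integer(floor(max_lag / dt + 1e-9))
    k_max <- min(k_max, n - 1L)
    if (k_max < 1) next
    vals <- vapply(1:k_max, function(k) {
      dx <- x[(1 + k):n] - x[1:(n - k)]
      dy <- y[(1 + k):n] - y[1:(n - k)]
      mean(dx^2 + dy^2)
    }, numeric(1))
    out[[i]] <- tibble::tibble(
      track_id = tl$ids[i],
      lag_s = (1:k_max) * dt,
      value = vals / l^2,
      n_pairs = n - (1:k_max)
    )
  }
  dplyr::bind_rows(out)
}

#' @rdname tmsd
#' @export
etmsd <- function(tracks, max_lag = NULL, l = 1) {
  dt <- tracks_dt(tracks)
  if (is.null(max_lag)) {
    durs <- track_durations(tracks)
    max_lag <- max(durs$duration_s) / 2
  }
  per <- tmsd(tracks, max_lag = max_lag, l = l)
  if (nrow(per) == 0) abort("no track long enough for the requested lags")
  agg <- dplyr::summarise(
    dplyr::group_by(per, .data$lag_s),
    value = mean(.data$value), n = dplyr::n(), .groups = "drop"
  )
  agg <- dplyr::arrange(agg, .data$lag_s)
  new_lagcurve(agg$lag_s, agg$value, agg$n, kind = "E-TMSD")
}

new_lagcurve <- function(lag_s, value, n, kind) {
  structure(
    tibble::tibble(lag_s = lag_s, value = value, n = as.integer(n)),
    kind = kind,
    class = c("hfbm_lagcurve", class(tibble::tibble()))
  )
}

#' @export
print.hfbm_lagcurve <- function(x, ...) {
  cat(sprintf("# Lag curve (%s), %d lags\n", attr(x, "kind") %||% "?", nrow(x)))
  NextMethod()
}

#' Fit a power law to a lag curve
#'
#' Ordinary least squares of `log10(value)` against `log10(lag / tau)`
#' over the lags inside `fit_range`, weighting all lags equally in log
#' space. With the MSD convention `MSD(t) = 4 D (t / tau)^alpha` the
#' fitted slope is the anomalous exponent `alpha` and the generalized
#' diffusion coefficient is `D = 10^intercept / 4`. Non-positive values
#' inside the range are excluded; at least 3 usable lags are required.
#'
#' @param curve A lag-curve tibble (`lag_s`, `value`), e.g. from
#'   [emsd()] or [etmsd()].
#' @param fit_range Length-2 numeric, lag window in seconds (inclusive).
#'   The default (0.2, 2) s targets the intermediate time scale between
#'   localization-noise-dominated short lags and survivor-biased long
#'   lags.
#' @param tau Time scale in seconds making the lag dimensionless.
#' @return An object of class `hfbm_power_fit` with elements `exponent`,
#'   `coefficient`, `fit_range`, `r_squared`, `n_lags`, `kind`. Has
#'   [tidy()] and [glance()] methods.
#' @export
fit_power_law <- function(curve, fit_range = c(0.2, 2), tau = 1) {
  stopifnot(length(fit_range) == 2, fit_range[1] < fit_range[2])
  check_number(tau, "tau", 0, strict = TRUE)
  sel <- curve$lag_s >= fit_range[1] & curve$lag_s <= fit_range[2] & curve$value > 0
  if (sum(sel) < 3) {
    abort(sprintf(
      "need >= 3 lags with positive values in [%g, %g] s (found %d)",
      fit_range[1], fit_range[2], sum(sel)
    ))
  }
  fit <- loglog_ls(curve$lag_s[sel] / tau, curve$value[sel])
  structure(
    list(
      exponent = unname(fit["slope"]),
      coefficient = unname(10^fit["intercept"] / 4),
      fit_range = fit_range,
      r_squared = unname(fit["r2"]),
      n_lags = sum(sel),
      kind = attr(curve, "kind") %||% "curve"
    ),
    class = "hfbm_power_fit"
  )
}

#' @export
print.hfbm_power_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit of %s over [%g, %g] s (%d lags)\n  alpha = %.4f, D = %.4g, R^2 = %.4f\n",
    x$kind, x$fit_range[1], x$fit_range[2], x$n_lags,
    x$exponent, x$coefficient, x$r_squared
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hfbm_power_fit <- function(x, ...) {
  tibble::tibble(
    term = c("exponent", "coefficient"),
    estimate = c(x$exponent, x$coefficient)
  )
}

#' @exportS3Method generics::glance
glance.hfbm_power_fit <- function(x, ...) {
  tibble::tibble(
    exponent = x$exponent, coefficient = x$coefficient,
    r_squared = x$r_squared, n_lags = x$n_lags,
    fit_min_s = x$fit_range[1], fit_max_s = x$fit_range[2], kind = x$kind
  )
}
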