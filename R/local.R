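#' Sliding-window local MSD analysis
#'
#' Estimates the local anomalous exponent `alpha_local(t)` and the local
#' generalized diffusion coefficient `d_local(t)` along each track. For
#' every window of `window_points` frames centered at time `t` (the full
#' window must lie inside the track), the time-averaged MSD of the
#' windowed sub-track is computed and its first `n_fit_lags` lag points
#' are fitted with `4 * D_L * (t' / tau)^alpha_L` by least squares in
#' log-log coordinates. The window then advances by a single frame.
#'
#' Windows whose local MSD contains non-positive values keep only the
#' positive lags; windows with fewer than 3 usable lags are skipped.
#' A spectrum of `alpha_local` values (rather than a single number) is
#' the signature of heterogeneous transport; negative fitted exponents
#' occur in noise-dominated windows and are retained.
#'
#' @param tracks A track table.
#' @param window_points Window size `N` in frames (`W = N * dt`); must
#'   exceed 10 because the first 10 lags are fitted. Tracks shorter than
#'   `window_points + 1` points yield no windows.
#' @param n_fit_lags Number of leading L-TMSD lag points entering each
#'   fit (default 10).
#' @param tau Time scale in seconds (dimensionless-lag convention).
#' @return A `hfbm_local` tibble with columns `track_id`, `t_s` (window
#'   center), `alpha_local`, `d_local`; the window size is carried as
#'   attribute `window_points`.
#' @export
#' @examples
#' tr <- simulate_fbm(2, h = 0.5, d = 1, n_steps = 200, seed = 1)
#' ls <- local_series(tr)
#' summary(ls$alpha_local)
local_series <- function(tracks, window_points = 20, n_fit_lags = 10, tau = 1) {
  stopifnot(window_points > 10, n_fit_lags >= 3)
  tl <- track_list(tracks)
  if (length(tl$ids) == 0) abort("empty track table")
  dt <- tracks_dt(tracks)
  half <- window_points %/% 2L
  out <- vector("list", length(tl$ids))
  log_lags <- log10((1:n_fit_lags) * dt / tau)
  for (i in seq_along(tl$ids)) {
    x <- tl$x[[i]]
    y <- tl$y[[i]]
    n <- length(x)
    centers <- seq.int(1L + half, n - half)
    if (n < window_points + 1L || length(centers) == 0) next
    # rolling local TMSD: for lag k, window mean of the squared-step
    # series over start indices [c - half, c + half - k]
    msd_mat <- matrix(NA_real_, nrow = n_fit_lags, ncol = length(centers))
    for (k in seq_len(n_fit_lags)) {
      dx <- x[(1 + k):n] - x[1:(n - k)]
      s <- dx^2 + (y[(1 + k):n] - y[1:(n - k)])^2
      cs <- c(0, cumsum(s))
      lo <- centers - half # first start index of the window, 1-based in s
      hi <- centers + half - k # last start index
      msd_mat[k, ] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    }
    fits <- fit_window_loglines(log_lags, msd_mat)
    keep <- is.finite(fits$slope)
    if (!any(keep)) next
    out[[i]] <- tibble::tibble(
      track_id = tl$ids[i],
      t_s = tl$t0[[i]] + (centers[keep] - 1L) * dt,
      alpha_local = fits$slope[keep],
      d_local = 10^fits$intercept[keep] / 4
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(
      track_id = character(), t_s = double(),
      alpha_local = double(), d_local = double()
    )
  }
  structure(
    res,
    window_points = window_points,
    n_fit_lags = n_fit_lags,
    class = c("hfbm_local", class(tibble::tibble()))
  )
}

# per-column log-log line fits of msd_mat (rows = lags) against log_lags;
# columns with all values positive share one closed-form OLS, others are
# refitted on their positive lags (>= 3 required, else NA)
fit_window_loglines <- function(log_lags, msd_mat) {
  nc <- ncol(msd_mat)
  slope <- rep(NA_real_, nc)
  intercept <- rep(NA_real_, nc)
  pos <- msd_mat > 0
  all_pos <- colSums(pos) == nrow(msd_mat)
  if (any(all_pos)) {
    ly <- log10(msd_mat[, all_pos, drop = FALSE])
    mx <- mean(log_lags)
    cx <- log_lags - mx
    sxx <- sum(cx^2)
    b <- colSums(cx * ly) / sxx
    a <- colMeans(ly) - b * mx
    slope[all_pos] <- b
    intercept[all_pos] <- a
  }
  for (j in which(!all_pos)) {
    ok <- pos[, j]
    if (sum(ok) < 3) next
    f <- lm(log10(msd_mat[ok, j]) ~ log_lags[ok])
    slope[j] <- unname(coef(f)[2])
    intercept[j] <- unname(coef(f)[1])
  }
  list(slope = slope, intercept = intercept)
}

#' Pool local exponents and diffusion coefficients
#'
#' Concatenates `alpha_local` and `d_local` values across tracks and
#' window centers, the raw material for the distribution fits of
#' [fit_exponential()] and [fit_power_law_pdf()].
#'
#' @param local A `hfbm_local` tibble from [local_series()] (or several
#'   row-bound together).
#' @return A list with vectors `alpha`, `d` and the pooled count `n`.
#' @export
pool_local_values <- function(local) {
  if (is.null(local) || nrow(local) == 0) abort("no local series to pool")
  list(alpha = local$alpha_local, d = local$d_local, n = nrow(local))
}

#' Fit an exponential distribution by maximum likelihood
#'
#' The MLE of the exponential rate is the reciprocal sample mean. Used
#' for the distribution of local anomalous exponents, which for
#' heterogeneous tracking ensembles is exponential with a rate that
#' differs between slow and fast particles.
#'
#' @param x Non-negative sample (at least 100 values for a meaningful
#'   distribution fit; fewer raise an error).
#' @param min_n Minimum sample size.
#' @return A `hfbm_dist_fit` object (`family = "exponential"`, `rate`).
#' @export
#' @examples
#' fit_exponential(rexp(1000, rate = 1.86))
fit_exponential <- function(x, min_n = 100) {
  if (length(x) < min_n) abort(sprintf("need >= %d samples (got %d)", min_n, length(x)))
  if (any(x < 0)) abort("exponential fit requires non-negative samples")
  structure(
    list(
      family = "exponential", rate = 1 / mean(x), n = length(x),
      method = "mle", fit_range = range(x)
    ),
    class = "hfbm_dist_fit"
  )
}

#' Fit a power-law probability density on log-spaced bins
#'
#' Histograms the sample on logarithmically spaced bins inside
#' `[x_min, x_max]` (about `bins_per_decade` bins per decade), converts
#' counts to densities by bin width, and fits `log10(density)` against
#' `log10(bin center)` by least squares. Returns the exponent magnitude
#' `mu` of `p(x) ~ x^-mu`. Empty bins are dropped; at least 3 non-empty
#' bins are required. A cross-check against the truncated-Pareto MLE
#' (see [fit_truncated_pareto()]) is recommended for clean samples.
#'
#' @param x Positive sample.
#' @param x_min,x_max Fit window; defaults to the central 98% of the
#'   sample (the extreme bins of a finite sample are noisy and, for
#'   window-fitted diffusivities, boundary-distorted).
#' @param bins_per_decade Bin resolution of the log-spaced histogram.
#' @param min_n Minimum number of samples inside the window.
#' @return A `hfbm_dist_fit` object (`family = "power_law"`, `exponent`).
#' @export
#' @examples
#' x <- sample_durations(5000, mu_t = 1.5, t_min = 0.1, t_max = 1000, seed = 1)
#' fit_power_law_pdf(x, x_min = 0.1, x_max = 100)
fit_power_law_pdf <- function(x, x_min = NULL, x_max = NULL,
                              bins_per_decade = 20, min_n = 100) {
  x <- x[is.finite(x) & x > 0]
  if (is.null(x_min)) x_min <- stats::quantile(x, 0.01, names = FALSE)
  if (is.null(x_max)) x_max <- stats::quantile(x, 0.99, names = FALSE)
  if (x_max <= x_min) abort("`x_max` must exceed `x_min`")
  inside <- x[x >= x_min & x <= x_max]
  if (length(inside) < min_n) {
    abort(sprintf("need >= %d samples in [%g, %g] (got %d)", min_n, x_min, x_max, length(inside)))
  }
  n_bins <- max(4L, ceiling(log10(x_max / x_min) * bins_per_decade))
  breaks <- 10^seq(log10(x_min), log10(x_max), length.out = n_bins + 1)
  counts <- graphics::hist(inside, breaks = breaks, plot = FALSE)$counts
  widths <- diff(breaks)
  centers <- sqrt(breaks[-1] * breaks[-length(breaks)])
  dens <- counts / (length(inside) * widths)
  nonzero <- counts > 0
  if (sum(nonzero) < 3) abort("fewer than 3 non-empty bins in the fit window")
  fit <- loglog_ls(centers[nonzero], dens[nonzero])
  structure(
    list(
      family = "power_law", exponent = -unname(fit["slope"]),
      n = length(inside), method = "loglog_ls",
      fit_range = c(x_min, x_max), r_squared = unname(fit["r2"]),
      bins_per_decade = bins_per_decade
    ),
    class = "hfbm_dist_fit"
  )
}

#' @export
print.hfbm_dist_fit <- function(x, ...) {
  par <- if (x$family == "exponential") {
    sprintf("rate = %.4f", x$rate)
  } else {
    sprintf("exponent = %.4f", x$exponent)
  }
  cat(sprintf(
    "%s fit (%s), %s, n = %d, range [%.3g, %.3g]\n",
    x$family, x$method, par, x$n, x$fit_range[1], x$fit_range[2]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hfbm_dist_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    term = if (x$family == "exponential") "rate" else "exponent",
    estimate = if (x$family == "exponential") x$rate else x$exponent,
    n = x$n, method = x$method
  )
}

#' Rank correlation between local exponent and local diffusivity
#'
#' Spearman correlation between the pooled `alpha_local` values and
#' `log10(d_local)`. A positive value indicates that locally faster
#' growing windows also carry larger local diffusion coefficients.
#'
#' @param local A `hfbm_local` tibble.
#' @param min_pairs Minimum number of pooled pairs.
#' @return A single correlation coefficient.
#' @export
local_correlation <- function(local, min_pairs = 10) {
  ok <- is.finite(local$alpha_local) & is.finite(local$d_local) & local$d_local > 0
  a <- local$alpha_local[ok]
  d <- log10(local$d_local[ok])
  if (length(a) < min_pairs) abort(sprintf("need >= %d pairs (got %d)", min_pairs, length(a)))
  if (sd(a) == 0 || sd(d) == 0) abort("correlation undefined for constant input")
  cor(a, d, method = "spearman")
}
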