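#' Scaled-displacement propagator
#'
#' The propagator at a fixed lag is the probability density of the
#' scaled x-displacement `xi = x / sigma_x`, where `sigma_x` is the
#' standard deviation of all pooled displacements
#' `x(t' + lag) - x(t')` at that lag. A Gaussian propagator indicates
#' homogeneous diffusion; heavy power-law tails `|xi|^(-1 - 2 gamma)`
#' arise when the diffusivity itself is power-law distributed
#' (superstatistics).
#'
#' `propagator_pdf()` pools displacements from a track table;
#' `displacement_pdf()` builds the same density directly from a numeric
#' displacement sample (e.g. from
#' [sample_superstat_displacements()]). Bins are symmetric about zero:
#' uniform in the core (`|xi| <= 1`) and logarithmically spaced outside
#' it, so both the Gaussian center and a heavy tail are resolved; the
#' density is normalized to unit integral over the binned support.
#'
#' @param tracks A track table.
#' @param lag Lag time in seconds (integer multiple of the frame
#'   interval).
#' @param x A numeric vector of displacements.
#' @param core_bins Number of uniform bins on `(-1, 1)` of scaled
#'   displacement.
#' @param bins_per_decade Log-bin resolution of each tail.
#' @param min_samples Minimum number of pooled displacements.
#' @return A `hfbm_propagator` tibble with columns `xi` (bin centers),
#'   `density`, `count`; attributes `sigma_x` (micrometers), `lag`,
#'   `n_samples`, `breaks`.
#' @export
#' @examples
#' x <- rnorm(1e4)
#' p <- displacement_pdf(x)
#' attr(p, "sigma_x")
propagator_pdf <- function(tracks, lag, core_bins = 40, bins_per_decade = 20,
                           min_samples = 100) {
  tl <- track_list(tracks)
  if (length(tl$ids) == 0) abort("empty track table")
  dt <- tracks_dt(tracks)
  k <- lag / dt
  if (abs(k - round(k)) > 1e-6) abort("`lag` must be an integer multiple of dt")
  k <- as.integer(round(k))
  if (k < 1) abort("`lag` must be at least one frame interval")
  disp <- unlist(lapply(tl$x, function(x) {
    n <- length(x)
    if (n <= k) return(numeric(0))
    x[(1 + k):n] - x[1:(n - k)]
  }), use.names = FALSE)
  displacement_pdf(disp,
    core_bins = core_bins, bins_per_decade = bins_per_decade,
    min_samples = min_samples, lag = lag
  )
}

#' @rdname propagator_pdf
#' @export
displacement_pdf <- function(x, core_bins = 40, bins_per_decade = 20,
                             min_samples = 100, lag = NA_real_) {
  x <- x[is.finite(x)]
  if (length(x) < min_samples) {
    abort(sprintf("need >= %d displacement samples (got %d)", min_samples, length(x)))
  }
  sigma_x <- sd(x)
  if (!is.finite(sigma_x) || sigma_x == 0) abort("displacements have zero spread; sigma_x = 0")
  xi <- x / sigma_x
  xi_max <- max(abs(xi))
  pos_breaks <- if (xi_max > 1) {
    n_log <- max(1L, ceiling(log10(xi_max) * bins_per_decade))
    10^seq(0, log10(xi_max) + 1e-9, length.out = n_log + 1)
  } else {
    numeric(0)
  }
  half <- c(seq(0, 1, length.out = core_bins %/% 2 + 1), pos_breaks[-1])
  breaks <- c(-rev(half[-1]), half)
  counts <- hist(xi, breaks = breaks, plot = FALSE)$counts
  widths <- diff(breaks)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dens <- counts / (length(xi) * widths)
  structure(
    tibble::tibble(xi = centers, density = dens, count = as.integer(counts)),
    sigma_x = sigma_x, lag = lag, n_samples = length(xi), breaks = breaks,
    class = c("hfbm_propagator", class(tibble::tibble()))
  )
}

#' Fit the power-law tail of a propagator
#'
#' Least-squares fit of `log(density)` against `log(|xi|)` over the bins
#' whose centers fall in `xi_range`, pooling both tails (the density is
#' assumed symmetric). For a superstatistical propagator with tail
#' `|xi|^(-1 - 2 gamma)` the fitted slope `s` maps to the diffusivity
#' tail index as `gamma = (-s - 1) / 2`, which is what is returned.
#'
#' The choice of `xi_range` matters: the power-law regime lives between
#' the Gaussian core and the cutoff set by the largest diffusivities.
#' For synthetic superstatistical samples the window can be computed
#' from the generating bounds with [superstat_tail_range()]; for
#' experimental propagators inspect the curve. The range used is stored
#' in the result.
#'
#' @param pdf A `hfbm_propagator` tibble.
#' @param xi_range Length-2 numeric: fit window in `|xi|`.
#' @param min_bins Minimum number of non-empty bins in the window.
#' @return A `hfbm_tail_fit` object with elements `gamma`, `slope`,
#'   `xi_range`, `n_bins`, `r_squared`.
#' @export
fit_tail_exponent <- function(pdf, xi_range = c(2, 20), min_bins = 3) {
  stopifnot(length(xi_range) == 2, xi_range[1] > 0, xi_range[1] < xi_range[2])
  sel <- abs(pdf$xi) >= xi_range[1] & abs(pdf$xi) <= xi_range[2] & pdf$density > 0
  if (sum(sel) < min_bins) {
    abort(sprintf(
      "need >= %d non-empty bins with |xi| in [%g, %g] (found %d)",
      min_bins, xi_range[1], xi_range[2], sum(sel)
    ))
  }
  fit <- loglog_ls(abs(pdf$xi[sel]), pdf$density[sel])
  structure(
    list(
      gamma = (-unname(fit["slope"]) - 1) / 2,
      slope = unname(fit["slope"]),
      xi_range = xi_range,
      n_bins = sum(sel),
      r_squared = unname(fit["r2"])
    ),
    class = "hfbm_tail_fit"
  )
}

#' @export
print.hfbm_tail_fit <- function(x, ...) {
  cat(sprintf(
    "Propagator tail fit over |xi| in [%g, %g] (%d bins)\n  slope = %.3f, gamma = %.3f, R^2 = %.4f\n",
    x$xi_range[1], x$xi_range[2], x$n_bins, x$slope, x$gamma, x$r_squared
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hfbm_tail_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", "slope"),
    estimate = c(x$gamma, x$slope)
  )
}

#' Analytic propagator of obstructed diffusion in two dimensions
#'
#' Reference density proportional to
#' `|xi|^(-0.108) * exp(-|xi|^1.65)`, normalized numerically (trapezoid
#' rule) to unit integral over the supplied grid. The weak power-law
#' prefactor diverges at zero, so the grid must exclude `xi = 0`.
#' Obstructed (percolation-like) diffusion shares many properties with
#' anti-persistent FBM but has this distinctive stretched-exponential
#' propagator, making the propagator shape a useful discriminator.
#'
#' @param xi Numeric grid of scaled displacements, not containing 0.
#' @return Numeric vector of density values on `xi`.
#' @export
#' @examples
#' xi <- seq(-6, 6, by = 0.01)
#' xi <- xi[xi != 0]
#' d <- obstructed_propagator(xi)
obstructed_propagator <- function(xi) {
  if (any(xi == 0)) abort("grid must exclude xi = 0 (the prefactor diverges there)")
  f <- abs(xi)^(-0.108) * exp(-abs(xi)^1.65)
  o <- order(xi)
  xs <- xi[o]
  fs <- f[o]
  z <- sum(diff(xs) * (fs[-1] + fs[-length(fs)]) / 2)
  f / z
}

#' Superstatistical consistency of diffusivity and propagator tails
#'
#' For heterogeneous FBM with diffusivity density `p(D) ~ D^(-1 - gamma)`
#' the propagator tail is `|xi|^(-1 - 2 gamma)`, so the magnitude of the
#' diffusivity PDF exponent must equal `1 + gamma`. This check compares
#' a fitted diffusivity exponent (e.g. from [fit_power_law_pdf()] on
#' local diffusion coefficients) with a propagator tail index (e.g. from
#' [fit_tail_exponent()]) and reports whether they agree within
#' `tolerance`.
#'
#' @param d_exponent Magnitude of the diffusivity PDF exponent, or a
#'   `hfbm_dist_fit` of family `"power_law"`.
#' @param gamma Propagator tail index, or a `hfbm_tail_fit`.
#' @param tolerance Allowed absolute difference.
#' @return A one-row tibble with `d_exponent`, `gamma`, `expected`
#'   (`1 + gamma`), `difference` and `consistent`.
#' @export
#' @examples
#' consistency_check(2.7, 1.7)$consistent # TRUE
#' consistency_check(2.0, 0.2)$consistent # FALSE
consistency_check <- function(d_exponent, gamma, tolerance = 0.2) {
  if (inherits(d_exponent, "hfbm_dist_fit")) {
    if (d_exponent$family != "power_law") abort("`d_exponent` fit must be a power law")
    d_exponent <- d_exponent$exponent
  }
  if (inherits(gamma, "hfbm_tail_fit")) gamma <- gamma$gamma
  expected <- 1 + gamma
  tibble::tibble(
    d_exponent = d_exponent,
    gamma = gamma,
    expected = expected,
    difference = d_exponent - expected,
    consistent = abs(d_exponent - expected) <= tolerance
  )
}
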