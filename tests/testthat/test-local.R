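test_that("local exponents recover deterministic power-law paths", {
  # ballistic: local TMSD is exactly quadratic, alpha_local = 2 everywhere
  tr <- make_tracks(ballistic_track(0.5, 60, dt = 0.05))
  ls <- local_series(tr, window_points = 20)
  expect_gt(nrow(ls), 0)
  expect_true(all(abs(ls$alpha_local - 2) < 0.01))
  # stationary track: all windows have zero MSD and are skipped
  tr0 <- make_tracks(one_track(rep(0, 60), rep(0, 60)))
  expect_equal(nrow(local_series(tr0, window_points = 20)), 0)
  # too-short track yields an empty series
  trs <- make_tracks(one_track(0:10, 0:10))
  expect_equal(nrow(local_series(trs, window_points = 20)), 0)
})

test_that("local series of Brownian motion center on alpha = 1, D = true D", {
  tr <- simulate_fbm(10, h = 0.5, d = 1, n_steps = 600, dt = 0.05, seed = 12)
  ls <- local_series(tr, window_points = 20)
  # fitting logs of a noisy windowed MSD biases the mean slope slightly
  # below the true exponent (Jensen effect at 21-point windows)
  expect_lt(abs(mean(ls$alpha_local) - 1), 0.15)
  expect_lt(abs(mean(ls$d_local) - 1), 0.15)
  expect_lt(abs(stats::median(ls$alpha_local) - 1), 0.15)
})

test_that("windows advance one frame and values pool across tracks", {
  tr <- simulate_fbm(2, h = 0.5, d = 0.5, n_steps = 50, dt = 0.1, seed = 13)
  ls <- local_series(tr, window_points = 20)
  per <- split(ls$t_s, ls$track_id)
  for (t in per) expect_equal(diff(t), rep(0.1, length(t) - 1))
  pooled <- pool_local_values(ls)
  expect_equal(pooled$n, sum(lengths(per)))
  expect_equal(length(pooled$alpha), pooled$n)
  # pooled mean equals the count-weighted mean of per-track means
  m <- tapply(ls$alpha_local, ls$track_id, mean)
  w <- tapply(ls$alpha_local, ls$track_id, length)
  expect_equal(mean(pooled$alpha), sum(m * w) / sum(w))
  expect_error(pool_local_values(ls[0, ]), "pool")
})

test_that("exponential rates are recovered by maximum likelihood", {
  expect_equal(fit_exponential(rep(2, 200))$rate, 0.5)
  x <- withr::with_seed(14, rexp(1e5, 1.86))
  expect_lt(abs(fit_exponential(x)$rate - 1.86), 0.02)
  y <- withr::with_seed(15, rexp(1e5, 4.3))
  expect_lt(abs(fit_exponential(y)$rate - 4.3), 0.05)
  expect_error(fit_exponential(c(x[1:200], -1)), "non-negative")
  expect_error(fit_exponential(x[1:50]), "100")
  # invariance to order and duplication
  expect_equal(fit_exponential(rev(x))$rate, fit_exponential(x)$rate)
  expect_equal(fit_exponential(c(x, x))$rate, fit_exponential(x)$rate)
})

test_that("power-law densities are recovered on log-spaced bins", {
  x <- sample_durations(1e5, mu_t = 1.5, t_min = 1e-4, t_max = 1, seed = 16)
  f <- fit_power_law_pdf(x, x_min = 1e-4, x_max = 0.1)
  expect_lt(abs(f$exponent - 1.5), 0.1)
  y <- sample_durations(1e5, mu_t = 2.7, t_min = 1e-4, t_max = 1, seed = 17)
  f2 <- fit_power_law_pdf(y, x_min = 1e-4, x_max = 0.1)
  expect_lt(abs(f2$exponent - 2.7), 0.15)
  # cross-check against the truncated-Pareto MLE on the same sample
  expect_lt(abs(f2$exponent - fit_truncated_pareto(y, 1e-4, 1)), 0.15)
  # invariance to order and duplication
  expect_equal(
    fit_power_law_pdf(rev(y), x_min = 1e-4, x_max = 0.1)$exponent,
    f2$exponent
  )
  expect_equal(
    fit_power_law_pdf(c(y, y), x_min = 1e-4, x_max = 0.1)$exponent,
    f2$exponent
  )
})

test_that("alpha-D correlation is rank-based and detects the null", {
  d <- 10^seq(-3, 1, length.out = 200)
  ls <- structure(
    tibble::tibble(
      track_id = "a", t_s = seq_along(d),
      alpha_local = log10(d), d_local = d
    ),
    class = c("hfbm_local", class(tibble::tibble()))
  )
  expect_equal(local_correlation(ls), 1)
  withr::with_seed(18, {
    ls$alpha_local <- sample(ls$alpha_local)
    ls$d_local <- sample(ls$d_local)
  })
  null_rho <- local_correlation(ls)
  expect_lt(abs(null_rho), 0.15) # n = 200 null
  ls$alpha_local <- rep(1, 200)
  expect_error(local_correlation(ls), "constant")
  # fit-noise coupling on Brownian windows is positive and matches a
  # direct recomputation
  tr <- simulate_fbm(5, h = 0.5, d = 0.5, n_steps = 400, dt = 0.05, seed = 19)
  lsb <- local_series(tr, window_points = 20)
  rho <- local_correlation(lsb)
  ok <- lsb$d_local > 0
  expect_equal(rho, cor(lsb$alpha_local[ok], log10(lsb$d_local[ok]), method = "spearman"))
  expect_gt(rho, 0)
})

test_that("pooled local exponents of constant-H FBM peak near 2H", {
  tr <- simulate_fbm(30, h = 0.25, d = 0.1, n_steps = 200, dt = 0.05, seed = 20)
  ls <- local_series(tr, window_points = 20)
  dens <- stats::density(ls$alpha_local)
  mode <- dens$x[which.max(dens$y)]
  expect_lt(abs(mode - 0.5), 0.2)
})
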