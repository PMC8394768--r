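test_that("ensemble MSD reproduces closed forms and the N = 1 identity", {
  # two identical ballistic tracks at 1 um/s: EMSD(t) = t^2
  tr <- make_tracks(ballistic_track(1, 10, id = "b1"), ballistic_track(1, 10, id = "b2"))
  e <- emsd(tr)
  expect_equal(e$value, e$lag_s^2)
  expect_equal(e$n, rep(2L, 9))
  # single track: EMSD equals its own squared displacement from the start
  withr::with_seed(5, tr1 <- make_tracks(random_track(30)))
  e1 <- emsd(tr1)
  expect_equal(
    e1$value,
    (tr1$x_um[-1] - tr1$x_um[1])^2 + (tr1$y_um[-1] - tr1$y_um[1])^2
  )
  expect_warning(emsd(tr1, max_lag = 100), "truncated")
})

test_that("time-averaged MSD matches hand computation and the O(n^2) oracle", {
  tr <- make_tracks(one_track(c(0, 1, 2, 3), rep(0, 4)))
  expect_equal(tmsd(tr, max_lag = 3)$value, c(1, 4, 9))
  trc <- make_tracks(one_track(rep(2, 10), rep(-1, 10)))
  expect_true(all(tmsd(trc)$value == 0))
  withr::with_seed(6, trr <- make_tracks(random_track(30)))
  got <- tmsd(trr, max_lag = 29)
  want <- vapply(1:29, function(k) tmsd_brute(trr$x_um, trr$y_um, k), numeric(1))
  expect_equal(got$value, want)
  expect_equal(got$n_pairs, 30 - (1:29))
  # lag-1 value is the mean squared single-frame step
  steps2 <- diff(trr$x_um)^2 + diff(trr$y_um)^2
  expect_equal(got$value[1], mean(steps2))
})

test_that("ensemble averaging of TMSDs is an unweighted per-lag mean", {
  withr::with_seed(7, tr1 <- make_tracks(random_track(40, id = "a")))
  expect_equal(etmsd(tr1)$value, tmsd(tr1)$value)
  # two constant-velocity tracks with TMSD(k) = k^2 and (2k)^2 average to 2.5 k^2
  tr2 <- make_tracks(ballistic_track(1, 12, id = "v1"), ballistic_track(2, 12, id = "v2"))
  e <- etmsd(tr2, max_lag = 4)
  expect_equal(e$value, 2.5 * e$lag_s^2)
  expect_equal(e$n, rep(2L, 4))
})

test_that("power-law fits invert exact curves and recover Brownian motion", {
  lags <- seq(0.1, 5, by = 0.1)
  curve <- tibble::tibble(lag_s = lags, value = 4 * 0.5 * lags^0.5)
  f <- fit_power_law(curve, fit_range = c(0.1, 5))
  expect_equal(f$exponent, 0.5, tolerance = 1e-10)
  expect_equal(f$coefficient, 0.5, tolerance = 1e-10)
  f2 <- fit_power_law(tibble::tibble(lag_s = lags, value = 4 * lags), fit_range = c(0.1, 5))
  expect_equal(f2$exponent, 1, tolerance = 1e-10)
  expect_equal(f2$coefficient, 1, tolerance = 1e-10)
  expect_error(fit_power_law(curve, fit_range = c(10, 20)), "3 lags")
  # 200 Brownian tracks with D = 1
  tr <- simulate_fbm(200, h = 0.5, d = 1, n_steps = 200, dt = 0.05, seed = 8)
  fb <- fit_power_law(emsd(tr, max_lag = 5), fit_range = c(0.2, 2))
  expect_lt(abs(fb$exponent - 1), 0.05)
  expect_lt(abs(fb$coefficient - 1), 0.1)
  expect_equal(tidy(fb)$estimate, c(fb$exponent, fb$coefficient))
  expect_equal(glance(fb)$n_lags, fb$n_lags)
})

test_that("ensemble and time averages agree for constant-H FBM (ergodicity)", {
  tr <- simulate_fbm(150, h = 0.25, d = 0.1, n_steps = 256, dt = 0.05, seed = 9)
  e <- emsd(tr, max_lag = 2)
  et <- etmsd(tr, max_lag = 2)
  # compare at a few lags within 3 ensemble standard errors
  per <- tmsd(tr, max_lag = 2)
  tl <- hfbm:::track_list(tr)
  for (k in c(4, 10, 20, 40)) {
    sq <- vapply(seq_along(tl$x), function(i) {
      (tl$x[[i]][1 + k] - tl$x[[i]][1])^2 + (tl$y[[i]][1 + k] - tl$y[[i]][1])^2
    }, numeric(1))
    tavg <- per$value[per$lag_s == k * 0.05]
    se_diff <- sd(sq - tavg) / sqrt(length(sq))
    expect_lt(abs(e$value[k] - et$value[k]), 3 * se_diff)
  }
})

test_that("duration-coupled ensembles bend the long-lag EMSD downwards", {
  tr_coupled <- simulate_hfbm(600, seed = 10)
  d_ref <- mean(track_params(tr_coupled)$d_coeff)
  e <- emsd(tr_coupled, max_lag = 30)
  long <- e$lag_s >= 5 & e$n >= 10
  # survivors at long lags are long-duration, low-D tracks: the curve falls
  # below the constant-D FBM law 4 D t^0.5 computed at the mean diffusivity
  frac_below <- mean(e$value[long] < 4 * d_ref * e$lag_s[long]^0.5)
  expect_gte(frac_below, 0.9)
  # survivor counts can only shrink with lag
  expect_true(all(diff(e$n) <= 0))
  # filtering by duration lowers short-lag EMSD (smaller D survives)
  f_all <- fit_power_law(e, fit_range = c(0.2, 1))
  f_long <- fit_power_law(emsd(filter_duration(tr_coupled, 8), max_lag = 2),
    fit_range = c(0.2, 1)
  )
  expect_lt(f_long$coefficient, f_all$coefficient)
})
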