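test_that("fractional noise has the analytic increment correlations", {
  n <- 1e5
  # Brownian limit: increments uncorrelated
  g <- simulate_fgn(0.5, n, seed = 1)
  expect_lt(abs(cor(g[-1], g[-n])), 0.02)
  # anti-persistent: lag-1 autocorrelation 2^(2H-1) - 1
  g <- simulate_fgn(0.25, n, seed = 2)
  expect_lt(abs(cor(g[-1], g[-n]) - (2^(2 * 0.25 - 1) - 1)), 0.02)
  # sample autocovariance matches the closed form at lags 0..5 within 3 SE
  for (h in c(0.25, 0.75)) {
    g <- simulate_fgn(h, n, seed = 3)
    for (k in 0:5) {
      est <- mean(g[1:(n - k)] * g[(1 + k):n])
      se <- sd(g[1:(n - k)] * g[(1 + k):n]) / sqrt(n - k)
      expect_lt(abs(est - fgn_autocov(k, h)), 3.5 * se + 1e-4)
    }
  }
})

test_that("cumulated noise obeys the FBM variance law", {
  # Var[B_H(t)] = t^(2H): estimate over independent short paths
  h <- 0.75
  reps <- 300
  withr::with_seed(7, {
    ends <- replicate(reps, {
      b <- cumsum(simulate_fgn(h, 128))
      c(b[32], b[128])
    })
  })
  for (i in 1:2) {
    t_i <- c(32, 128)[i]
    ratio <- mean(ends[i, ]^2) / t_i^(2 * h)
    expect_equal(ratio, 1, tolerance = 4 / sqrt(reps) * sqrt(2))
  }
})

test_that("Durbin-Levinson fallback matches the circulant sampler statistically", {
  n <- 60
  reps <- 400
  withr::with_seed(11, {
    acov1 <- rowMeans(replicate(reps, {
      g <- hfbm:::fgn_durbin_levinson(0.3, n, 1)
      c(mean(g^2), mean(g[-1] * g[-n]))
    }))
  })
  expect_lt(abs(acov1[1] - fgn_autocov(0, 0.3)), 0.02)
  expect_lt(abs(acov1[2] - fgn_autocov(1, 0.3)), 0.02)
})

test_that("duration sampling follows the truncated power law", {
  # degenerate support collapses to t_min
  d <- sample_durations(50, t_min = 1, t_max = 1 + 1e-9, seed = 1)
  expect_true(all(abs(d - 1) < 1e-6))
  # empirical CDF matches the analytic inverse-CDF construction
  d <- sample_durations(1e5, mu_t = 1.85, t_min = 0.5, t_max = 200, seed = 2)
  expect_true(all(d >= 0.5 & d <= 200))
  ks <- suppressWarnings(stats::ks.test(d, pareto_cdf, mu = 1.85, t_min = 0.5, t_max = 200))
  expect_lt(unname(ks$statistic), 0.01)
  # MLE recovers the generating exponent
  expect_lt(abs(fit_truncated_pareto(d, 0.5, 200) - 1.85), 0.02)
  expect_error(sample_durations(10, t_min = 5, t_max = 2), "t_max")
})

test_that("heterogeneous ensembles encode the duration-diffusivity coupling", {
  tr <- simulate_hfbm(300, seed = 4)
  p <- track_params(tr)
  # D is a deterministic function of the raw duration: log-log slope -0.6
  # (recomputed on the pre-rounding durations implied by D = c T^-mu)
  t_raw <- (p$d_coeff / 0.1)^(-1 / 0.6)
  slope <- unname(coef(lm(log10(p$d_coeff) ~ log10(t_raw)))[2])
  expect_equal(slope, -0.6, tolerance = 1e-10)
  # frame-rounded durations still give the slope to first order
  slope2 <- unname(coef(lm(log10(p$d_coeff) ~ log10(p$duration_s)))[2])
  expect_equal(slope2, -0.6, tolerance = 0.02)
  expect_error(simulate_hfbm(5, dt = 0.05, t_min = 0.05), "t_min")
})

test_that("zero-diffusivity track stays at the origin and seeds reproduce bits", {
  tr <- simulate_fbm(1, h = 0.25, d = 0, n_steps = 20, seed = 1)
  expect_true(all(tr$x_um == 0) && all(tr$y_um == 0))
  a <- simulate_hfbm(30, seed = 99)
  b <- simulate_hfbm(30, seed = 99)
  expect_identical(a, b)
  x1 <- sample_superstat_displacements(100, 0.5, 1, 10, seed = 12)
  x2 <- sample_superstat_displacements(100, 0.5, 1, 10, seed = 12)
  expect_identical(x1, x2)
})

test_that("localization noise lifts the short-lag EMSD by about 4 sigma^2", {
  sigma <- 0.1
  clean <- simulate_fbm(600, h = 0.25, d = 0.1, n_steps = 64, dt = 0.05, seed = 31)
  noisy <- simulate_fbm(600, h = 0.25, d = 0.1, n_steps = 64, dt = 0.05,
                        noise_sigma = sigma, seed = 32)
  e0 <- emsd(clean, max_lag = 0.05)$value[1]
  e1 <- emsd(noisy, max_lag = 0.05)$value[1]
  expect_lt(abs((e1 - e0) - 4 * sigma^2), 0.01)
})

test_that("two-state Hurst switching produces valid, distinct tracks", {
  tr <- simulate_hfbm(
    20,
    hurst = hurst_two_state(0.75, 0.25, mean_sojourn = 0.5),
    seed = 8
  )
  expect_equal(dplyr::n_distinct(tr$track_id), 20)
  expect_true(all(is.finite(tr$x_um)))
  expect_identical(
    tr,
    simulate_hfbm(20, hurst = hurst_two_state(0.75, 0.25, mean_sojourn = 0.5), seed = 8)
  )
})

test_that("single-diffusivity superstatistical sample is plain Gaussian", {
  x <- sample_superstat_displacements(2e5, gamma = 0.5, d_min = 2, d_max = 2, seed = 5)
  kurt <- mean((x - mean(x))^4) / var(x)^2 - 3
  expect_lt(abs(kurt), 0.05)
  expect_equal(sd(x), sqrt(2 * 2), tolerance = 0.02)
})
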