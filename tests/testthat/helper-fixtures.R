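# fixtures and independent brute-force oracles used across test files

make_tracks <- function(..., dt = NULL) {
  as_tracks(dplyr::bind_rows(...), dt = dt)
}

one_track <- function(x, y, id = "a", dt = 1) {
  tibble::tibble(
    track_id = id, t_s = (seq_along(x) - 1) * dt, x_um = x, y_um = y
  )
}

ballistic_track <- function(v = 1, n = 20, id = "b", dt = 1) {
  t <- (0:(n - 1)) * dt
  tibble::tibble(track_id = id, t_s = t, x_um = v * t, y_um = 0)
}

random_track <- function(n = 50, id = "r", dt = 1, sd = 1) {
  tibble::tibble(
    track_id = id, t_s = (0:(n - 1)) * dt,
    x_um = cumsum(c(0, rnorm(n - 1, sd = sd))),
    y_um = cumsum(c(0, rnorm(n - 1, sd = sd)))
  )
}

# O(n^2) oracles, written independently of the package internals

tmsd_brute <- function(x, y, k) {
  n <- length(x)
  acc <- 0
  for (i in 1:(n - k)) {
    acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
  }
  acc / (n - k)
}

tvacf_brute <- function(x, y, dt, m, k) {
  n <- length(x)
  nv <- n - m
  vx <- vy <- numeric(nv)
  for (i in 1:nv) {
    vx[i] <- (x[i + m] - x[i]) / (m * dt)
    vy[i] <- (y[i + m] - y[i]) / (m * dt)
  }
  acc <- 0
  cnt <- 0
  for (i in 1:(nv - k)) {
    acc <- acc + vx[i + k] * vx[i] + vy[i + k] * vy[i]
    cnt <- cnt + 1
  }
  acc / cnt
}

# truncated-Pareto CDF on [t_min, t_max] with density ~ x^-mu
pareto_cdf <- function(q, mu, t_min, t_max) {
  a <- 1 - mu
  (q^a - t_min^a) / (t_max^a - t_min^a)
}
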