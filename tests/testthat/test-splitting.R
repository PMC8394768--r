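test_that("distance from origin matches direct recomputation", {
  tr <- make_tracks(one_track(c(0, 3, 0), c(0, 4, 0)))
  expect_equal(distance_from_origin(tr)$r_um, c(0, 5, 0))
  tr0 <- make_tracks(one_track(rep(1, 5), rep(-2, 5)))
  expect_equal(distance_from_origin(tr0)$r_um, rep(0, 5))
  withr::with_seed(3, tr_rand <- make_tracks(random_track(50)))
  r <- distance_from_origin(tr_rand)$r_um
  brute <- sqrt((tr_rand$x_um - tr_rand$x_um[1])^2 + (tr_rand$y_um - tr_rand$y_um[1])^2)
  expect_equal(r, brute)
})

test_that("maximum-excursion rule is strict at the threshold", {
  fast <- one_track(c(0, 5, 0), c(0, 0, 0), id = "far")
  still <- one_track(rep(0, 5), rep(0, 5), id = "still")
  border <- one_track(c(0, 0.25, 0), c(0, 0, 0), id = "border")
  tr <- make_tracks(fast, still, border)
  lab <- classify_tracks(tr, epsilon = 0.25)
  expect_equal(lab$label[lab$track_id == "far"], "fast")
  expect_equal(lab$label[lab$track_id == "still"], "slow")
  # max R exactly at the threshold is slow (fast requires strict >)
  expect_equal(lab$label[lab$track_id == "border"], "slow")
})

test_that("run rule requires more than four consecutive superdiffusive windows", {
  expect_equal(classify_by_run(rep(0.4, 30)), "slow")
  expect_equal(classify_by_run(c(rep(0.4, 5), rep(1.5, 6), rep(0.4, 5))), "fast")
  # a run of exactly 4 does not qualify
  expect_equal(classify_by_run(c(rep(0.4, 5), rep(1.5, 4), rep(0.4, 5))), "slow")
  expect_equal(classify_by_run(rep(1.5, 3)), "unclassified")
})

test_that("splitting partitions the ensemble and reacts monotonically to epsilon", {
  withr::with_seed(9, {
    slow_part <- lapply(1:6, function(i) {
      df <- random_track(30, id = paste0("s", i), dt = 0.05, sd = 0.02)
      df
    })
    fast_part <- lapply(1:5, function(i) ballistic_track(1, 30, id = paste0("f", i), dt = 0.05))
  })
  tr <- as_tracks(dplyr::bind_rows(c(slow_part, fast_part)))
  parts <- split_tracks(tr, epsilon = 0.25)
  n_all <- dplyr::n_distinct(tr$track_id)
  expect_equal(
    dplyr::n_distinct(parts$slow$track_id) + dplyr::n_distinct(parts$fast$track_id) +
      dplyr::n_distinct(parts$discarded$track_id),
    n_all
  )
  expect_equal(nrow(parts$discarded), 0) # excursion method never discards
  # ballistic tracks at 1 um/s for 1.45 s are all fast at 0.25 um
  expect_true(all(startsWith(unique(parts$fast$track_id), "f")))
  # raising epsilon can only move tracks from fast to slow
  labs <- lapply(c(0.1, 0.25, 0.5, 2), function(e) classify_tracks(tr, epsilon = e))
  n_slow <- vapply(labs, function(l) sum(l$label == "slow"), numeric(1))
  expect_true(all(diff(n_slow) >= 0))
  for (i in 2:4) {
    was_slow <- labs[[i - 1]]$label == "slow"
    expect_true(all(labs[[i]]$label[was_slow] == "slow"))
  }
})

test_that("the excursion and local-exponent classifiers agree on a separated ensemble", {
  # slow: anti-persistent FBM with a tiny diffusivity; fast: near-ballistic
  slow_part <- simulate_fbm(8, h = 0.25, d = 5e-4, n_steps = 79, dt = 0.05, seed = 41)
  withr::with_seed(42, {
    fast_part <- lapply(1:8, function(i) {
      t <- (0:79) * 0.05
      tibble::tibble(
        track_id = paste0("f", i), t_s = t,
        x_um = 0.6 * t + cumsum(c(0, rnorm(79, sd = 0.002))),
        y_um = 0.6 * t
      )
    })
  })
  tr <- as_tracks(dplyr::bind_rows(c(list(tibble::as_tibble(slow_part)), fast_part)))
  by_r <- classify_tracks(tr, method = "max_distance", epsilon = 0.25)
  by_a <- classify_tracks(tr, method = "local_exponent", window_points = 20)
  joined <- dplyr::inner_join(by_r, by_a, by = "track_id", suffix = c("_r", "_a"))
  judged <- joined[joined$label_a != "unclassified", , drop = FALSE]
  agreement <- mean(judged$label_r == judged$label_a)
  # cross-check against a hand-built confusion matrix
  cm <- table(judged$label_r, judged$label_a)
  expect_equal(agreement, sum(diag(cm)) / sum(cm))
  expect_gte(agreement, 0.8)
})
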