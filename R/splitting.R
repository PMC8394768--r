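#' Distance from the starting point
#'
#' For each localization, the Euclidean distance
#' `R(t) = sqrt((x(t) - x(0))^2 + (y(t) - y(0))^2)` from the track's
#' first position, in micrometers. Tracks undergoing active (motor-driven)
#' transport show episodes of rapid growth of `R`, while passively
#' jiggling particles keep `R` small for their whole duration — the basis
#' of the maximum-excursion classifier.
#'
#' @param tracks A track table.
#' @return A tibble `track_id`, `frame`, `t_s`, `r_um`.
#' @export
#' @examples
#' tr <- as_tracks(data.frame(
#'   track_id = "a", t_s = 0:2, x_um = c(0, 3, 0), y_um = c(0, 4, 0)
#' ))
#' distance_from_origin(tr)$r_um # 0, 5, 0
distance_from_origin <- function(tracks) {
  df <- tibble::as_tibble(tracks)
  df <- dplyr::group_by(df, .data$track_id)
  df <- dplyr::mutate(
    df,
    r_um = sqrt((.data$x_um - .data$x_um[1])^2 + (.data$y_um - .data$y_um[1])^2)
  )
  dplyr::ungroup(df)[, c("track_id", "frame", "t_s", "r_um")]
}

#' Classify tracks as slow or fast movers
#'
#' Two classifiers of whole tracks:
#'
#' * `method = "max_distance"`: a track is **fast** if its maximum
#'   excursion from the start strictly exceeds `epsilon` micrometers
#'   (`max R(t) > epsilon`), otherwise **slow**. A maximum exactly equal
#'   to the threshold is slow.
#' * `method = "local_exponent"`: a track is **fast** if its local
#'   anomalous exponent series (see [local_series()]) contains a run of
#'   at least `run_length` consecutive superdiffusive values
#'   (`alpha_local > alpha_threshold`), otherwise **slow**. Tracks whose
#'   series is shorter than `run_length` windows cannot be judged and
#'   are labeled **unclassified** (short tracks are typically discarded
#'   from this analysis).
#'
#' @param tracks A track table.
#' @param method `"max_distance"` or `"local_exponent"`.
#' @param epsilon Excursion threshold in micrometers (default 0.25 um;
#'   results are robust to small changes, see [sensitivity_report()]).
#' @param run_length Number of consecutive superdiffusive windows
#'   required (default 5, i.e. more than 4).
#' @param alpha_threshold Superdiffusion boundary for the local exponent
#'   (default 1).
#' @param window_points Window size passed to [local_series()] when
#'   `method = "local_exponent"`.
#' @return `classify_tracks()`: a tibble `track_id`, `label` with label
#'   levels `slow`, `fast`, `unclassified`.
#' @export
#' @examples
#' tr <- simulate_hfbm(20, seed = 1)
#' table(classify_tracks(tr)$label)
classify_tracks <- function(tracks, method = c("max_distance", "local_exponent"),
                            epsilon = 0.25, run_length = 5, alpha_threshold = 1,
                            window_points = 20) {
  method <- match.arg(method)
  check_number(epsilon, "epsilon", 0, strict = TRUE)
  stopifnot(run_length >= 1)
  ids <- unique(tracks$track_id)
  if (length(ids) == 0) abort("empty track table")
  if (method == "max_distance") {
    r <- distance_from_origin(tracks)
    mx <- dplyr::summarise(
      dplyr::group_by(r, .data$track_id),
      max_r = max(.data$r_um), .groups = "drop"
    )
    lab <- ifelse(mx$max_r > epsilon, "fast", "slow")
    out <- tibble::tibble(track_id = mx$track_id, label = lab)
  } else {
    ls <- local_series(tracks, window_points = window_points)
    lab <- vapply(ids, function(id) {
      a <- ls$alpha_local[ls$track_id == id]
      classify_by_run(a,
        run_length = run_length,
        alpha_threshold = alpha_threshold
      )
    }, character(1))
    out <- tibble::tibble(track_id = ids, label = unname(lab))
  }
  out[match(ids, out$track_id), , drop = FALSE]
}

#' Run-based superdiffusion rule on a local exponent series
#'
#' Applies the decision rule of the local-exponent classifier to one
#' series: `"fast"` if `alpha` holds a run of at least `run_length`
#' consecutive values above `alpha_threshold`, `"slow"` otherwise, and
#' `"unclassified"` if the series has fewer than `run_length` values.
#'
#' @param alpha Numeric series of local anomalous exponents.
#' @inheritParams classify_tracks
#' @return One of `"fast"`, `"slow"`, `"unclassified"`.
#' @export
#' @examples
#' classify_by_run(c(0.4, 1.5, 1.5, 1.5, 1.5, 0.3)) # run of 4 -> "slow"
#' classify_by_run(rep(1.5, 6)) # run of 6 -> "fast"
classify_by_run <- function(alpha, run_length = 5, alpha_threshold = 1) {
  alpha <- alpha[is.finite(alpha)]
  if (length(alpha) < run_length) {
    return("unclassified")
  }
  r <- rle(alpha > alpha_threshold)
  if (any(r$values & r$lengths >= run_length)) "fast" else "slow"
}

#' Split an ensemble into slow, fast and unclassified sub-ensembles
#'
#' Partitions a track table using [classify_tracks()]. Every track lands
#' in exactly one of the three sub-ensembles; with the maximum-excursion
#' method the `discarded` set is always empty. Each returned table's
#' `meta` records the method and thresholds.
#'
#' @inheritParams classify_tracks
#' @return A list of `hfbm_tracks` tables: `slow`, `fast`, `discarded`.
#' @export
split_tracks <- function(tracks, method = c("max_distance", "local_exponent"),
                         epsilon = 0.25, run_length = 5, alpha_threshold = 1,
                         window_points = 20) {
  method <- match.arg(method)
  labels <- classify_tracks(
    tracks,
    method = method, epsilon = epsilon,
    run_length = run_length, alpha_threshold = alpha_threshold,
    window_points = window_points
  )
  dt <- tracks_dt(tracks)
  meta <- tracks_meta(tracks)
  meta$split <- list(
    method = method, epsilon = epsilon,
    run_length = run_length, alpha_threshold = alpha_threshold
  )
  pick <- function(lab) {
    ids <- labels$track_id[labels$label == lab]
    m <- meta
    m$split$class <- lab
    new_tracks(
      tibble::as_tibble(tracks)[tracks$track_id %in% ids, , drop = FALSE],
      dt = dt, meta = m
    )
  }
  list(
    slow = pick("slow"),
    fast = pick("fast"),
    discarded = pick("unclassified")
  )
}
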