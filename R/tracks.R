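#' Track tables
#'
#' A track table is a tibble with one row per localization and columns
#' `track_id` (character), `frame` (0-based integer), `t_s` (time in
#' seconds), `x_um` and `y_um` (positions in micrometers), carrying the
#' common frame interval `dt` and a provenance list `meta` as attributes.
#' All tracks in one table share the same frame interval; estimators in
#' this package assume uniform sampling.
#'
#' `as_tracks()` validates and normalizes a plain data frame: rows are
#' sorted by id and time, frames are (re)derived from time, tracks with
#' fewer than two points are dropped with a warning, and tracks whose
#' sampling deviates from the common frame interval are rejected.
#'
#' @param x A data frame with columns `track_id`, `t_s`, `x_um`, `y_um`
#'   (and optionally `frame`), or names mapped via `dialect`.
#' @param dt Frame interval in seconds. If `NULL`, inferred as the modal
#'   consecutive time difference across all tracks.
#' @param meta Named list of provenance information stored as an attribute.
#' @param dialect Optional named character vector mapping the canonical
#'   column names to the names used in `x`, e.g.
#'   `c(track_id = "particle", t_s = "time", x_um = "x", y_um = "y")`.
#' @param dt_tol Relative tolerance for deviations of consecutive time
#'   differences from `dt` before a track is rejected as non-uniform.
#'
#' @return A `hfbm_tracks` tibble.
#' @export
#' @examples
#' df <- data.frame(
#'   track_id = rep(c("a", "b"), each = 3),
#'   t_s = rep(c(0, 0.05, 0.1), 2),
#'   x_um = rnorm(6), y_um = rnorm(6)
#' )
#' tr <- as_tracks(df)
#' tracks_dt(tr)
as_tracks <- function(x, dt = NULL, meta = list(), dialect = NULL, dt_tol = 1e-3) {
  df <- tibble::as_tibble(x)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(df)) {
        names(df)[names(df) == dialect[[canon]]] <- canon
      }
    }
  }
  needed <- c("track_id", "t_s", "x_um", "y_um")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "missing track columns: ", paste(missing_cols, collapse = ", "),
      " (use `dialect` to map your column names)"
    ))
  }
  df$track_id <- as.character(df$track_id)
  if (!all(vapply(df[c("t_s", "x_um", "y_um")], is.numeric, logical(1)))) {
    abort("`t_s`, `x_um` and `y_um` must be numeric")
  }
  if (anyNA(df[needed]) || !all(is.finite(df$t_s) & is.finite(df$x_um) & is.finite(df$y_um))) {
    abort("track table contains missing or non-finite values")
  }
  df <- dplyr::arrange(df, .data$track_id, .data$t_s)

  n_by_id <- table(df$track_id)
  short <- names(n_by_id)[n_by_id < 2]
  if (length(short) > 0) {
    warn(sprintf("dropped %d track(s) with fewer than 2 points", length(short)))
    df <- df[!(df$track_id %in% short), , drop = FALSE]
  }
  if (nrow(df) == 0) {
    out <- tibble::tibble(
      track_id = character(), frame = integer(),
      t_s = double(), x_um = double(), y_um = double()
    )
    return(new_tracks(out, dt = dt %||% NA_real_, meta = meta))
  }

  diffs <- unlist(lapply(split(df$t_s, df$track_id), diff), use.names = FALSE)
  if (any(diffs <= 0)) abort("duplicate or non-increasing time stamps within a track")
  if (is.null(dt)) dt <- modal_value(diffs)
  check_number(dt, "dt", lower = 0, strict = TRUE)

  bad <- vapply(
    split(df$t_s, df$track_id),
    function(t) any(abs(diff(t) - dt) > dt_tol * dt),
    logical(1)
  )
  if (any(bad)) {
    abort(sprintf(
      "%d track(s) are not uniformly sampled at dt = %g s (first: '%s'); mixed or irregular frame intervals are not supported",
      sum(bad), dt, names(bad)[bad][1]
    ))
  }

  df <- dplyr::group_by(df, .data$track_id)
  df <- dplyr::mutate(df, frame = as.integer(round((.data$t_s - .data$t_s[1]) / dt)))
  df <- dplyr::ungroup(df)
  df <- df[, c("track_id", "frame", "t_s", "x_um", "y_um")]
  new_tracks(df, dt = dt, meta = meta)
}

new_tracks <- function(df, dt, meta = list()) {
  structure(
    df,
    dt = dt,
    meta = meta,
    class = c("hfbm_tracks", class(tibble::tibble()))
  )
}

#' @rdname as_tracks
#' @param tracks A track table (or any data frame in the canonical layout).
#' @export
tracks_dt <- function(tracks) {
  dt <- attr(tracks, "dt", exact = TRUE)
  if (!is.null(dt) && is.finite(dt)) {
    return(dt)
  }
  diffs <- unlist(lapply(split(tracks$t_s, tracks$track_id), diff), use.names = FALSE)
  if (length(diffs) == 0) abort("cannot infer dt from an empty track table")
  modal_value(diffs)
}

#' @rdname as_tracks
#' @export
tracks_meta <- function(tracks) {
  attr(tracks, "meta", exact = TRUE) %||% list()
}

#' @export
print.hfbm_tracks <- function(x, ...) {
  n_tr <- dplyr::n_distinct(x$track_id)
  cat(sprintf(
    "# Track table: %d track(s), %d points, dt = %s s\n",
    n_tr, nrow(x), format(attr(x, "dt", exact = TRUE))
  ))
  NextMethod()
}

#' Read and write track tables as CSV
#'
#' The on-disk format is a plain CSV with header
#' `track_id,frame,t_s,x_um,y_um`, comma separated, `.` decimal mark,
#' frames 0-based, rows ordered by id then frame. `read_tracks()` accepts
#' files with renamed columns through `dialect` and infers the frame
#' interval from the time stamps (a `frame` column is optional on input).
#'
#' @inheritParams as_tracks
#' @param path Path to a CSV file.
#'
#' @return `read_tracks()` returns a `hfbm_tracks` tibble;
#'   `write_tracks()` invisibly returns `path`.
#' @export
read_tracks <- function(path, dialect = NULL, dt = NULL, dt_tol = 1e-3) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_tracks(df, dt = dt, meta = list(source = path), dialect = dialect, dt_tol = dt_tol)
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  if (nrow(tracks) == 0) abort("refusing to write an empty track table")
  out <- dplyr::arrange(
    tibble::as_tibble(tracks)[, c("track_id", "frame", "t_s", "x_um", "y_um")],
    .data$track_id, .data$frame
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-track summary and duration filtering
#'
#' `track_durations()` tabulates the number of points and the duration
#' `T = (n - 1) * dt` of every track. `filter_duration()` keeps tracks
#' strictly longer than `t_min` seconds; slow particles stay in the field
#' of view longer, so conditioning on duration changes ensemble averages
#' whenever diffusivity and duration are coupled.
#'
#' @param tracks A track table.
#' @param t_min Minimum duration in seconds (strict; `t_min = 0` keeps all).
#'
#' @return `track_durations()` a tibble with `track_id`, `n_points`,
#'   `duration_s`; `filter_duration()` a filtered `hfbm_tracks` table whose
#'   `meta` records the filter.
#' @export
track_durations <- function(tracks) {
  dt <- tracks_dt(tracks)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(tracks), .data$track_id),
    n_points = dplyr::n(), .groups = "drop"
  )
  out$duration_s <- (out$n_points - 1) * dt
  out
}

#' @rdname track_durations
#' @export
filter_duration <- function(tracks, t_min) {
  check_number(t_min, "t_min", lower = 0)
  durs <- track_durations(tracks)
  keep <- durs$track_id[durs$duration_s > t_min]
  meta <- tracks_meta(tracks)
  meta$duration_filter_s <- max(t_min, meta$duration_filter_s %||% 0)
  new_tracks(
    tibble::as_tibble(tracks)[tracks$track_id %in% keep, , drop = FALSE],
    dt = tracks_dt(tracks), meta = meta
  )
}

# split a track table into per-track lists of x/y/n once, for estimators
track_list <- function(tracks) {
  df <- tibble::as_tibble(tracks)
  ids <- unique(df$track_id)
  f <- factor(df$track_id, levels = ids)
  list(
    ids = ids,
    x = split(df$x_um, f),
    y = split(df$y_um, f),
    t0 = vapply(split(df$t_s, f), function(t) t[1], numeric(1))
  )
}
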