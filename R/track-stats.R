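#' Mean track velocity
#'
#' Total path length (sum of successive segment lengths) divided by elapsed
#' time, per track — the "cell velocity" readout of manual tracking.
#'
#' @param x a `track_set` (returns a named per-track vector) or a single
#'   track's data.frame with columns `t_min`, `x_um`, `y_um`.
#' @return velocity in um/min (named vector for a `track_set`).
#' @examples
#' d <- data.frame(track_id = "a", t_min = c(0, 2, 4),
#'                 x_um = c(0, 0, 0), y_um = c(0, 10, 20))
#' mean_track_velocity(track_set(d, 2))  # 5 um/min
#' @export
mean_track_velocity <- function(x) {
  if (inherits(x, "track_set"))
    return(vapply(track_split(x), mean_track_velocity, numeric(1)))
  t <- x$t_min
  if (length(t) < 2L) abort_data("a track needs at least 2 points")
  elapsed <- t[length(t)] - t[1]
  if (elapsed <= 0) abort_data("zero elapsed time in track")
  path <- sum(sqrt(diff(x$x_um)^2 + diff(x$y_um)^2))
  path / elapsed
}

#' Group mean squared displacement curve
#'
#' Per cell, MSD at lag `tau` is the mean of `|r(t + tau) - r(t)|^2` over
#' all overlapping start points; the group curve is the unweighted mean
#' over cells whose track supports at least one interval of that lag, so
#' cells tracked for different lengths contribute only to the lags they
#' support (the per-lag cell count is reported alongside).
#'
#' @param trackset a `track_set` with regularly sampled tracks.
#' @param max_lag largest lag in minutes (defaults to the longest track
#'   duration); must be at least one frame interval.
#' @param weight `"cells"` (default; unweighted mean over cells) or
#'   `"intervals"` (cells weighted by their number of overlapping
#'   intervals at that lag).
#' @return An `msd_curve` data.frame with columns `lag_min`, `msd` (um^2),
#'   `sem` (um^2, across cells) and `n_cells`; the row at lag 0 is 0 by
#'   definition.
#' @export
msd_curve <- function(trackset, max_lag = NULL,
                      weight = c("cells", "intervals")) {
  stopifnot(inherits(trackset, "track_set"))
  weight <- match.arg(weight)
  dt <- trackset$frame_interval
  tracks <- track_split(trackset)
  durations <- vapply(tracks, function(d) max(d$t_min) - min(d$t_min),
                      numeric(1))
  if (is.null(max_lag)) max_lag <- max(durations)
  check_scalar(max_lag, "max_lag", lower = 0)
  if (max_lag < dt)
    abort_param("`max_lag` must be at least one frame interval")
  n_lags <- floor(max_lag / dt + 1e-9)

  per_cell <- lapply(tracks, function(d) {
    steps <- diff(d$t_min)
    if (any(abs(steps - dt) > 1e-6 * dt))
      abort_data(sprintf("track %s is not sampled at the frame interval",
                         d$track_id[1]))
    np <- nrow(d)
    ks <- seq_len(min(n_lags, np - 1L))
    msd <- vapply(ks, function(k) {
      i <- seq_len(np - k)
      mean((d$x_um[i + k] - d$x_um[i])^2 + (d$y_um[i + k] - d$y_um[i])^2)
    }, numeric(1))
    nint <- np - ks
    cbind(k = ks, msd = msd, nint = nint)
  })

  lags <- seq_len(n_lags)
  rows <- lapply(lags, function(k) {
    vals <- vapply(per_cell, function(m) {
      i <- match(k, m[, "k"])
      if (is.na(i)) NA_real_ else m[i, "msd"]
    }, numeric(1))
    wts <- vapply(per_cell, function(m) {
      i <- match(k, m[, "k"])
      if (is.na(i)) 0 else m[i, "nint"]
    }, numeric(1))
    keep <- !is.na(vals)
    vals <- vals[keep]; wts <- wts[keep]
    nc <- length(vals)
    m <- if (weight == "cells") mean(vals) else sum(vals * wts) / sum(wts)
    s <- if (nc > 1L) stats::sd(vals) / sqrt(nc) else NA_real_
    c(msd = m, sem = s, n_cells = nc)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- rbind(data.frame(msd = 0, sem = 0, n_cells = length(per_cell)), out)
  out <- data.frame(lag_min = c(0, lags * dt), out)
  out <- out[out$n_cells > 0L, , drop = FALSE]
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Euclidean displacement after a fixed tracking horizon
#'
#' Straight-line distance between a cell's starting position and its
#' position at the first sample at or beyond the horizon (default 60 min
#' of tracking). Tracks shorter than the horizon are excluded and counted.
#'
#' @param trackset a `track_set`.
#' @param horizon tracking horizon in minutes (default 60).
#' @param relative_to optional reference `track_set` or
#'   `displacement_summary`; if given, the ratio of group means
#'   (test / reference) is reported as `relative`.
#' @return A `displacement_summary`: list with `per_track` (data.frame of
#'   `track_id`, `t_star`, `distance_um`), `mean`, `sem`, `n_excluded`,
#'   `horizon` and optionally `relative`.
#' @export
euclidean_displacement <- function(trackset, horizon = 60,
                                   relative_to = NULL) {
  stopifnot(inherits(trackset, "track_set"))
  check_scalar(horizon, "horizon", lower = 1e-12)
  tracks <- track_split(trackset)
  rows <- lapply(tracks, function(d) {
    t0 <- d$t_min[1]
    i <- which(d$t_min - t0 >= horizon - 1e-9)[1]
    if (is.na(i)) return(NULL)
    data.frame(track_id = d$track_id[1], t_star = d$t_min[i] - t0,
               distance_um = sqrt((d$x_um[i] - d$x_um[1])^2 +
                                  (d$y_um[i] - d$y_um[1])^2))
  })
  n_excluded <- sum(vapply(rows, is.null, logical(1)))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    abort_data(sprintf("no track reaches the %g min horizon", horizon))
  if (n_excluded > 0L)
    message(sprintf("%d track(s) shorter than the %g min horizon excluded",
                    n_excluded, horizon))
  per_track <- do.call(rbind, rows)
  rownames(per_track) <- NULL
  out <- list(per_track = per_track,
              mean = mean(per_track$distance_um),
              sem = if (nrow(per_track) > 1L)
                stats::sd(per_track$distance_um) / sqrt(nrow(per_track))
                else NA_real_,
              n_excluded = n_excluded, horizon = horizon)
  if (!is.null(relative_to)) {
    ref <- if (inherits(relative_to, "displacement_summary")) relative_to
           else euclidean_displacement(relative_to, horizon = horizon)
    out$relative <- out$mean / ref$mean
  }
  class(out) <- "displacement_summary"
  out
}

#' @export
print.displacement_summary <- function(x, ...) {
  cat(sprintf("<displacement_summary> horizon %g min: %d tracks, mean %.2f +/- %.2f um",
              x$horizon, nrow(x$per_track), x$mean, x$sem))
  if (!is.null(x$relative)) cat(sprintf(", relative %.3f", x$relative))
  cat("\n")
  invisible(x)
}

#' Translate every track to start at the origin
#'
#' Used for spider-style trajectory plots; displacement vectors, MSD and
#' all kinematic statistics are unchanged by the translation.
#'
#' @param trackset a `track_set`.
#' @return A `track_set` with each track's first point at (0, 0).
#' @export
center_tracks <- function(trackset) {
  stopifnot(inherits(trackset, "track_set"))
  parts <- lapply(track_split(trackset), function(d) {
    d$x_um <- d$x_um - d$x_um[1]
    d$y_um <- d$y_um - d$y_um[1]
    d
  })
  trackset$data <- do.call(rbind, parts)
  rownames(trackset$data) <- NULL
  trackset
}
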