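#' Construct a set of cell migration tracks
#'
#' A `track_set` is the labelled container used by every kinematic and
#' chemotaxis analysis: a long-format table of time-stamped planar positions
#' in micrometres, one group of tracks per object (e.g. one condition of one
#' donor). Track coordinates are y-up Cartesian in um; raster images use the
#' opposite (row-down) convention and the two never mix implicitly.
#'
#' @param data data.frame with columns `track_id`, `t_min` (minutes, strictly
#'   increasing within a track) and `x_um`, `y_um` (micrometres). Extra
#'   columns are preserved.
#' @param frame_interval acquisition interval in minutes, shared by all
#'   tracks in the set.
#' @param condition,donor optional group labels.
#' @param calibration optional pixel calibration (um/px) recorded at import.
#' @return A `track_set` object.
#' @details Tracks with fewer than 2 points are dropped with a warning;
#'   non-increasing times within a track are an error, as are non-finite
#'   coordinates.
#' @examples
#' d <- data.frame(track_id = "a", t_min = c(0, 2, 4),
#'                 x_um = c(0, 1, 2), y_um = c(0, 0, 1))
#' ts <- track_set(d, frame_interval = 2)
#' n_tracks(ts)
#' @export
track_set <- function(data, frame_interval, condition = NA_character_,
                      donor = NA_character_, calibration = NA_real_) {
  required <- c("track_id", "t_min", "x_um", "y_um")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    abort_format(sprintf("track data is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  check_scalar(frame_interval, "frame_interval", lower = 1e-12)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$track_id <- as.character(data$track_id)
  if (any(!is.finite(data$x_um)) || any(!is.finite(data$y_um)) ||
      any(!is.finite(data$t_min)))
    abort_data("track coordinates and times must be finite")

  data <- data[order(data$track_id, data$t_min), , drop = FALSE]
  npts <- table(data$track_id)
  short <- names(npts)[npts < 2L]
  if (length(short)) {
    warning(sprintf("dropped %d track(s) with fewer than 2 points", length(short)),
            call. = FALSE)
    data <- data[!data$track_id %in% short, , drop = FALSE]
  }
  if (nrow(data) == 0L)
    abort_data("track set is empty after dropping single-point tracks")

  bad <- vapply(split(data$t_min, data$track_id),
                function(t) any(diff(t) <= 0), logical(1))
  if (any(bad))
    abort_data(sprintf("non-increasing times within track(s): %s",
                       paste(names(bad)[bad], collapse = ", ")))

  structure(
    list(data = data, frame_interval = frame_interval,
         condition = condition, donor = donor, calibration = calibration),
    class = "track_set")
}

#' Number of tracks in a track set
#' @param x a `track_set`.
#' @return integer count.
#' @export
n_tracks <- function(x) {
  stopifnot(inherits(x, "track_set"))
  length(unique(x$data$track_id))
}

#' Split a track set into per-track data frames
#' @param x a `track_set`.
#' @return named list of data.frames, one per track, ordered by time.
#' @export
track_split <- function(x) {
  stopifnot(inherits(x, "track_set"))
  split(x$data, x$data$track_id)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d points, frame interval %g min\n",
              n_tracks(x), nrow(x$data), x$frame_interval))
  if (!is.na(x$condition)) cat("  condition:", x$condition, "\n")
  if (!is.na(x$donor))     cat("  donor:    ", x$donor, "\n")
  invisible(x)
}

#' @export
as.data.frame.track_set <- function(x, ...) x$data

# Apply a function (n x 2 matrix -> n x 2 matrix) to all positions.
transform_positions <- function(ts, f) {
  xy <- f(cbind(ts$data$x_um, ts$data$y_um))
  ts$data$x_um <- xy[, 1]
  ts$data$y_um <- xy[, 2]
  ts
}
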