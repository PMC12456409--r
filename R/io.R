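#' Read manually tracked cell paths from CSV
#'
#' Reads a manual-tracking-style export (comma-separated, header required):
#' columns `track_id`, `frame` and either pixel coordinates `x_px`, `y_px`
#' (converted with `calibration`) or pre-calibrated `x_um`, `y_um`. Extra
#' columns are ignored by name, not position. Times are `frame *
#' frame_interval` minutes. Tracks with fewer than 2 points are dropped
#' with a warning.
#'
#' @param path CSV file path.
#' @param frame_interval acquisition interval in minutes (microscope-
#'   specific; always required).
#' @param calibration pixel size in um/px; required when the file holds
#'   pixel coordinates.
#' @param condition,donor optional labels attached to the set.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, frame_interval, calibration = NULL,
                        condition = NA_character_, donor = NA_character_) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("track_id", "frame"))
    if (!col %in% names(d))
      abort_format(sprintf("missing required column '%s'", col))
  if (all(c("x_um", "y_um") %in% names(d))) {
    x <- d$x_um; y <- d$y_um
    calib <- if (is.null(calibration)) NA_real_ else calibration
  } else if (all(c("x_px", "y_px") %in% names(d))) {
    if (is.null(calibration))
      abort_config("pixel coordinates require a `calibration` (um/px)")
    check_scalar(calibration, "calibration", lower = 1e-12)
    x <- d$x_px * calibration
    y <- d$y_px * calibration
    calib <- calibration
  } else {
    abort_format("missing coordinate columns: need x_px/y_px or x_um/y_um")
  }
  if (!is.numeric(d$frame) || any(!is.finite(d$frame)))
    abort_data("column 'frame' must be numeric and finite")
  bad <- vapply(split(d$frame, d$track_id),
                function(f) any(diff(f) <= 0), logical(1))
  if (any(bad))
    abort_data(sprintf("non-monotone frames within track(s): %s",
                       paste(names(bad)[bad], collapse = ", ")))
  track_set(
    data.frame(track_id = as.character(d$track_id),
               t_min = d$frame * frame_interval, x_um = x, y_um = y),
    frame_interval = frame_interval, condition = condition, donor = donor,
    calibration = calib)
}

#' Write a track set to CSV
#'
#' Columns `track_id`, `frame`, `t_min`, `x_um`, `y_um`; a lossless
#' round trip with [read_tracks()] on the micrometre columns.
#'
#' @param trackset a `track_set`.
#' @param path output CSV path (written atomically).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trackset, path) {
  stopifnot(inherits(trackset, "track_set"))
  d <- trackset$data
  out <- data.frame(track_id = d$track_id,
                    frame = d$t_min / trackset$frame_interval,
                    t_min = d$t_min, x_um = d$x_um, y_um = d$y_um)
  write_atomic_csv(out, path)
}

write_atomic_csv <- function(d, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(d, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read single-molecule localizations from CSV
#'
#' Expects columns `x_nm`, `y_nm` (extra columns ignored). Points outside
#' the window are dropped with a message reporting the count.
#'
#' @param path CSV file path.
#' @param window `c(xmin, xmax, ymin, ymax)` in nm; if `NULL`, the
#'   sidecar written by [write_localizations()] is read.
#' @param cell_id optional cell identifier.
#' @return A [point_pattern()].
#' @export
read_localizations <- function(path, window = NULL,
                               cell_id = NA_character_) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  if (is.null(window)) {
    side <- paste0(path, ".window.txt")
    if (!file.exists(side))
      abort_config("no `window` given and no window sidecar found")
    kv <- read_sidecar(side)
    window <- as.numeric(kv[c("xmin", "xmax", "ymin", "ymax")])
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("x_nm", "y_nm"))
    if (!col %in% names(d))
      abort_format(sprintf("missing required column '%s'", col))
  inside <- d$x_nm >= window[1] & d$x_nm <= window[2] &
    d$y_nm >= window[3] & d$y_nm <= window[4]
  if (any(!inside))
    message(sprintf("%d localization(s) outside the window dropped",
                    sum(!inside)))
  if (!any(inside)) abort_data("no localizations inside the window")
  point_pattern(d$x_nm[inside], d$y_nm[inside], window = window,
                cell_id = cell_id)
}

#' Write a point pattern to CSV plus window sidecar
#'
#' Writes `x_nm`, `y_nm` columns and a plain-text key-value sidecar
#' `<path>.window.txt` describing the observation window.
#'
#' @param pattern a `point_pattern`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  write_atomic_csv(data.frame(x_nm = pattern$x, y_nm = pattern$y), path)
  w <- pattern$window
  write_sidecar(paste0(path, ".window.txt"),
                c(xmin = w[1], xmax = w[2], ymin = w[3], ymax = w[4]))
  invisible(path)
}

write_sidecar <- function(path, kv) {
  writeLines(sprintf("%s=%s", names(kv),
                     vapply(kv, format, character(1), digits = 17)), path)
  invisible(path)
}

read_sidecar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(vapply(parts, `[`, character(1), 2L),
                  vapply(parts, `[`, character(1), 1L))
}

#' Write a multi-channel cell image as TIFF with a sidecar
#'
#' One 32-bit float page per channel. Because TIFF pages store values in
#' `[0, 1]`, intensities are divided by a per-file scale factor which is
#' recorded, together with channel names and the pixel size, in the
#' plain-text sidecar `<path>.meta.txt`; [read_cell_image()] restores the
#' original values (equal within float32 representation).
#'
#' @param image a [cell_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cell_image <- function(image, path) {
  stopifnot(inherits(image, "cell_image"))
  mx <- max(1e-12, vapply(image$channels, max, numeric(1)))
  mn <- min(0, vapply(image$channels, min, numeric(1)))
  if (mn < 0) abort_data("negative intensities cannot be written; offset first")
  pages <- lapply(image$channels, function(ch) ch / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_sidecar(paste0(path, ".meta.txt"),
                c(pixel_size_um = image$pixel_size, scale = mx,
                  channels = paste(names(image$channels), collapse = ",")))
  invisible(path)
}

#' Read a multi-channel cell image from TIFF
#'
#' Reads every page as one channel. Pixel size and channel names come
#' from the sidecar written by [write_cell_image()]; `pixel_size`
#' overrides the sidecar value (logged) and is required when no sidecar
#' exists.
#'
#' @param path TIFF file path.
#' @param pixel_size optional um/px override.
#' @param channels optional character vector naming the pages (overrides
#'   the sidecar).
#' @return A [cell_image()].
#' @export
read_cell_image <- function(path, pixel_size = NULL, channels = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".meta.txt")
  meta <- if (file.exists(side)) read_sidecar(side) else character()
  scale <- if ("scale" %in% names(meta)) as.numeric(meta[["scale"]]) else 1
  if (is.null(channels)) {
    channels <- if ("channels" %in% names(meta))
      strsplit(meta[["channels"]], ",", fixed = TRUE)[[1]]
    else sprintf("channel%d", seq_along(pages))
  }
  if (length(channels) != length(pages))
    abort_format(sprintf("%d channel names for %d pages", length(channels),
                         length(pages)))
  if (is.null(pixel_size)) {
    if (!"pixel_size_um" %in% names(meta))
      abort_config("pixel size not in metadata and not supplied")
    pixel_size <- as.numeric(meta[["pixel_size_um"]])
  } else if ("pixel_size_um" %in% names(meta)) {
    message(sprintf("pixel size override: using %g um/px (file says %s)",
                    pixel_size, meta[["pixel_size_um"]]))
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate grayscale-as-RGB
    matrix(p * scale, nrow(p), ncol(p))
  })
  names(pages) <- channels
  cell_image(pages, pixel_size = pixel_size)
}

#' Read a transwell / homing count table from CSV
#'
#' Accepts either counting schema: `label`, `n_input`, `n_migrated`
#' (transwell counts) or `label`, `pct_farred_tissue`,
#' `pct_violet_tissue`, `pct_farred_input`, `pct_violet_input` (homing
#' percentages). Validation: counts non-negative with
#' `n_migrated <= n_input`; percentages in `[0, 100]`.
#'
#' @param path CSV file path.
#' @return data.frame with a `"schema"` attribute (`"counts"` or
#'   `"homing"`).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts_cols <- c("n_input", "n_migrated")
  homing_cols <- c("pct_farred_tissue", "pct_violet_tissue",
                   "pct_farred_input", "pct_violet_input")
  if (!"label" %in% names(d)) abort_format("missing required column 'label'")
  if (all(counts_cols %in% names(d))) {
    if (any(d$n_input < 0) || any(d$n_migrated < 0))
      abort_data("counts must be non-negative")
    if (any(d$n_migrated > d$n_input))
      abort_data("n_migrated exceeds n_input (inconsistent counts)")
    attr(d, "schema") <- "counts"
  } else if (all(homing_cols %in% names(d))) {
    pct <- unlist(d[homing_cols])
    if (any(pct < 0 | pct > 100))
      abort_data("percentages must be in [0, 100]")
    attr(d, "schema") <- "homing"
  } else {
    abort_format(
      "need columns n_input/n_migrated or the four homing percentage columns")
  }
  d
}
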