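#' Construct a multi-channel cell image
#'
#' Named 2D intensity rasters sharing one shape and one pixel size.
#' Raster convention: matrices are row-major with the origin at the top
#' left; row index increases downward. Pixel (r, c) has centre
#' `x = (c - 0.5) * pixel_size`, `y = (r - 0.5) * pixel_size` in image
#' micrometre coordinates.
#'
#' @param channels named list of numeric matrices of equal dimension.
#' @param pixel_size pixel size in um/px.
#' @return A `cell_image` object.
#' @export
cell_image <- function(channels, pixel_size) {
  if (!is.list(channels) || !length(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    abort_param("`channels` must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    abort_param("all channels must be matrices")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    abort_param("all channels must share the same shape")
  check_scalar(pixel_size, "pixel_size", lower = 1e-12)
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<cell_image> %d x %d px (%g um/px), channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

get_channel <- function(image, channel) {
  if (!inherits(image, "cell_image"))
    abort_param("`image` must be a cell_image")
  if (!channel %in% names(image$channels))
    abort_param(sprintf("no channel named '%s' (have: %s)", channel,
                        paste(names(image$channels), collapse = ", ")))
  image$channels[[channel]]
}

#' Specification of a synthetic polarized cell image
#'
#' Describes an elliptical cell with its major axis horizontal, a
#' circular nucleus offset along that axis, and a piecewise-constant
#' polarity marker: intensity `base * rear_front_ratio` on the rear half
#' of the cell (the half toward which the nucleus is offset), `base` on
#' the front half, split at the line through the nucleus centre
#' perpendicular to the major axis, plus Gaussian noise inside the cell
#' and exactly 0 outside.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size um/px.
#' @param cell_axes full (major, minor) ellipse axes in um.
#' @param nucleus_radius nucleus radius in um.
#' @param nucleus_offset signed offset of the nucleus centre along the
#'   major axis in um; negative values place it toward the rear (the
#'   -x image side). The rear is always the side the nucleus is closer
#'   to ("rear" = shorter nucleus-to-edge distance).
#' @param rear_front_ratio true rear/front intensity ratio (> 0).
#' @param base_intensity front intensity in arbitrary units.
#' @param noise_sd s.d. of the Gaussian noise added inside the cell.
#' @param seed integer seed.
#' @return A `polarized_cell_spec` list.
#' @export
polarized_cell_spec <- function(image_shape = c(100, 240), pixel_size = 0.2,
                                cell_axes = c(40, 15), nucleus_radius = 4,
                                nucleus_offset = -8, rear_front_ratio = 2,
                                base_intensity = 100, noise_sd = 5,
                                seed = 1L) {
  if (length(image_shape) != 2L)
    abort_param("`image_shape` must be c(rows, cols)")
  image_shape <- c(check_count(image_shape[1], "image_shape[1]", 8L),
                   check_count(image_shape[2], "image_shape[2]", 8L))
  check_scalar(pixel_size, "pixel_size", lower = 1e-12)
  if (length(cell_axes) != 2L)
    abort_param("`cell_axes` must be (major, minor) in um")
  check_scalar(cell_axes[1], "cell_axes[1]", lower = 1e-12)
  check_scalar(cell_axes[2], "cell_axes[2]", lower = 1e-12)
  if (cell_axes[2] > cell_axes[1])
    abort_param("major axis must be at least as long as the minor axis")
  check_scalar(nucleus_radius, "nucleus_radius", lower = 1e-12)
  check_scalar(nucleus_offset, "nucleus_offset")
  check_scalar(rear_front_ratio, "rear_front_ratio", lower = 1e-12)
  check_scalar(base_intensity, "base_intensity", lower = 1e-12)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  seed <- check_count(seed, "seed", lower = 0L)

  # nucleus disk must sit fully inside the cell ellipse
  a <- cell_axes[1] / 2; b <- cell_axes[2] / 2
  phi <- seq(0, 2 * pi, length.out = 720)
  px <- nucleus_offset + nucleus_radius * cos(phi)
  py <- nucleus_radius * sin(phi)
  if (any((px / a)^2 + (py / b)^2 > 1))
    abort_param("nucleus is not fully inside the cell ellipse")
  structure(
    list(image_shape = image_shape, pixel_size = pixel_size,
         cell_axes = cell_axes, nucleus_radius = nucleus_radius,
         nucleus_offset = nucleus_offset,
         rear_front_ratio = rear_front_ratio,
         base_intensity = base_intensity, noise_sd = noise_sd, seed = seed),
    class = "polarized_cell_spec")
}

#' Generate a synthetic polarized cell image
#'
#' Renders the cell described by a [polarized_cell_spec()] into a
#' three-channel [cell_image()]: `signal` (the piecewise polarity marker
#' with noise), `nucleus` (binary nucleus disk) and `mask_truth` (binary
#' ground-truth cell ellipse). The generating spec is attached as
#' `attr(, "ground_truth")`.
#'
#' @param spec a [polarized_cell_spec()].
#' @return A `cell_image`.
#' @export
generate_polarized_cell_image <- function(spec) {
  if (!inherits(spec, "polarized_cell_spec"))
    abort_param("`spec` must be created with polarized_cell_spec()")
  s <- spec
  with_seed(s$seed, {
    nr <- s$image_shape[1]; nc <- s$image_shape[2]
    px <- s$pixel_size
    # pixel-centre coordinates in um, origin at the image centre
    xs <- ((seq_len(nc) - 0.5) - nc / 2) * px
    ys <- ((seq_len(nr) - 0.5) - nr / 2) * px
    X <- matrix(xs, nr, nc, byrow = TRUE)
    Y <- matrix(ys, nr, nc)
    a <- s$cell_axes[1] / 2; b <- s$cell_axes[2] / 2
    cell <- (X / a)^2 + (Y / b)^2 <= 1
    if (!any(cell))
      abort_param("cell ellipse does not intersect the image")
    nucleus <- (X - s$nucleus_offset)^2 + Y^2 <= s$nucleus_radius^2
    # rear = the side the nucleus is offset toward (ties go to -x)
    rear_sign <- if (s$nucleus_offset > 0) 1 else -1
    rear <- cell & (rear_sign * (X - s$nucleus_offset) > 0)
    signal <- matrix(0, nr, nc)
    signal[cell] <- s$base_intensity
    signal[rear] <- s$base_intensity * s$rear_front_ratio
    if (s$noise_sd > 0)
      signal[cell] <- signal[cell] + stats::rnorm(sum(cell), sd = s$noise_sd)
    img <- cell_image(
      list(signal = signal,
           nucleus = matrix(as.numeric(nucleus), nr, nc),
           mask_truth = matrix(as.numeric(cell), nr, nc)),
      pixel_size = px)
    attr(img, "ground_truth") <- s
    img
  })
}
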