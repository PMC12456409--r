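#' Define the gradient reference frame from the chemokine border
#'
#' The border of the chemokine-expressing region, identified on the
#' microscope image, defines the reference frame: after alignment the
#' border lies on the x axis and the gradient points up the +y axis.
#'
#' @param p1,p2 two distinct points (length-2 numeric, raw coordinates)
#'   on the border.
#' @param source optional point on the chemokine-source side of the
#'   border, used to orient the gradient; if omitted the gradient is the
#'   left-hand normal of `p2 - p1`.
#' @return A `gradient_frame` with fields `border` (2 x 2 matrix) and
#'   `gradient_direction` (unit 2-vector normal to the border, pointing
#'   toward the source).
#' @export
gradient_frame <- function(p1, p2, source = NULL) {
  if (!is.numeric(p1) || length(p1) != 2L || !is.numeric(p2) ||
      length(p2) != 2L)
    abort_param("`p1` and `p2` must be numeric 2-vectors")
  d <- p2 - p1
  if (sqrt(sum(d^2)) < 1e-12)
    abort_param("border points must be distinct")
  d <- d / sqrt(sum(d^2))
  normal <- c(-d[2], d[1])
  if (!is.null(source)) {
    if (!is.numeric(source) || length(source) != 2L)
      abort_param("`source` must be a numeric 2-vector")
    side <- sum((source - p1) * normal)
    if (abs(side) < 1e-12)
      abort_param("`source` lies on the border; cannot orient the gradient")
    if (side < 0) normal <- -normal
  }
  structure(list(border = rbind(p1, p2), gradient_direction = normal),
            class = "gradient_frame")
}

#' Rotate and shift tracks into the gradient-aligned frame
#'
#' Applies the rigid transform (rotation + translation, distances
#' preserved) that maps the chemokine border onto the x axis and the
#' gradient direction onto +y, so that displacement angles can be read
#' against the gradient axis.
#'
#' @param trackset a `track_set` in raw coordinates.
#' @param frame a [gradient_frame()].
#' @return The aligned `track_set`.
#' @export
align_to_gradient <- function(trackset, frame) {
  stopifnot(inherits(trackset, "track_set"))
  if (!inherits(frame, "gradient_frame"))
    abort_param("`frame` must be created with gradient_frame()")
  g <- frame$gradient_direction
  # rotation sending g to (0, 1): columns are images of the basis
  R <- rbind(c(g[2], -g[1]),
             c(g[1],  g[2]))
  p1 <- as.numeric(frame$border[1, ])
  transform_positions(trackset, function(xy) {
    out <- sweep(xy, 2L, p1) %*% t(R)
    out
  })
}

#' Displacement angle to the gradient axis
#'
#' The planar angle between a track's overall displacement vector (end
#' minus start) and the +y gradient axis, in degrees within `[0, 180]`:
#' 0 deg is movement directly up the gradient, 90 deg on average means no
#' directionality, 180 deg directly down the gradient. Tracks must already
#' be in the gradient-aligned frame.
#'
#' @param track a single track's data.frame (`x_um`, `y_um`).
#' @return angle in degrees, or `NA` if the net displacement is zero
#'   (undefined direction).
#' @examples
#' displacement_angle(data.frame(x_um = c(0, 0), y_um = c(0, 10)))  # 0
#' displacement_angle(data.frame(x_um = c(0, 3), y_um = c(0, 4)))   # 36.87
#' @export
displacement_angle <- function(track) {
  n <- nrow(track)
  dx <- track$x_um[n] - track$x_um[1]
  dy <- track$y_um[n] - track$y_um[1]
  nrm <- sqrt(dx^2 + dy^2)
  if (nrm < 1e-12) return(NA_real_)
  acos(pmin(pmax(dy / nrm, -1), 1)) * 180 / pi
}

#' Per-track displacement angles of an aligned track set
#'
#' @param trackset an aligned `track_set`.
#' @return An `angle_set` data.frame with columns `track_id`, `angle_deg`
#'   and (if set on the track set) `condition`, `donor`. Tracks with zero
#'   net displacement are excluded with a warning, not assigned 90 deg.
#' @export
displacement_angles <- function(trackset) {
  stopifnot(inherits(trackset, "track_set"))
  ang <- vapply(track_split(trackset), displacement_angle, numeric(1))
  drop <- is.na(ang)
  if (any(drop))
    warning(sprintf("%d track(s) with zero net displacement excluded",
                    sum(drop)), call. = FALSE)
  out <- data.frame(track_id = names(ang)[!drop], angle_deg = ang[!drop],
                    row.names = NULL)
  out$condition <- trackset$condition
  out$donor <- trackset$donor
  class(out) <- c("angle_set", "data.frame")
  out
}

#' Mean displacement angle
#'
#' Arithmetic mean of the per-track angle magnitudes on `[0, 180]` deg
#' (this is a statistic of unsigned deviation from the gradient axis, not
#' a circular mean). When donor labels are present, per-donor means are
#' attached as an attribute.
#'
#' @param angles an `angle_set` or a numeric vector of angles in degrees.
#' @return mean angle in degrees; per-donor means in
#'   `attr(, "donor_means")` when available.
#' @export
mean_angle <- function(angles) {
  if (is.data.frame(angles)) {
    if (!nrow(angles)) abort_data("empty angle set")
    m <- mean(angles$angle_deg)
    if (!is.null(angles$donor) && any(!is.na(angles$donor)))
      attr(m, "donor_means") <-
        tapply(angles$angle_deg, angles$donor, mean)
    return(m)
  }
  if (!length(angles)) abort_data("empty angle set")
  mean(angles)
}

#' Bootstrapped difference in mean displacement angle between two groups
#'
#' Percentile bootstrap of `mean(group_b) - mean(group_a)`: for each of
#' `B` resamples, angles are drawn with replacement within each group
#' (keeping group sizes), the difference of group means is recorded, and
#' the confidence interval is the percentile interval of the resampled
#' differences. Resampling is flat over cells (donors are not resampled
#' hierarchically).
#'
#' @param group_a,group_b `angle_set` data.frames or numeric angle
#'   vectors (degrees); each group needs at least 5 angles. By the
#'   reporting convention used here, `group_a` is the reference (e.g.
#'   control) so a negative difference means `group_b` has smaller angles.
#' @param B number of bootstrap resamples (default 10,000).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed (mandatory for reproducibility).
#' @return An `angle_bootstrap` list: `observed_diff`, `ci_low`,
#'   `ci_high`, `ci_level`, `B`, `seed`, `excludes_zero` and the retained
#'   `bootstrap_samples`.
#' @export
bootstrap_angle_difference <- function(group_a, group_b, B = 10000,
                                       ci_level = 0.95, seed) {
  a <- if (is.data.frame(group_a)) group_a$angle_deg else group_a
  b <- if (is.data.frame(group_b)) group_b$angle_deg else group_b
  if (length(a) < 5L || length(b) < 5L)
    abort_data("each group needs at least 5 angles")
  B <- check_count(B, "B", lower = 1L)
  check_scalar(ci_level, "ci_level", lower = 1e-6, upper = 1 - 1e-6)
  if (missing(seed)) abort_param("`seed` is required")
  seed <- check_count(seed, "seed", lower = 0L)

  with_seed(seed, {
    na <- length(a); nb <- length(b)
    boot_a <- colMeans(matrix(a[sample.int(na, na * B, replace = TRUE)], na))
    boot_b <- colMeans(matrix(b[sample.int(nb, nb * B, replace = TRUE)], nb))
    diffs <- boot_b - boot_a
    alpha <- (1 - ci_level) / 2
    ci <- unname(stats::quantile(diffs, c(alpha, 1 - alpha)))
    structure(
      list(observed_diff = mean(b) - mean(a), B = B,
           ci_low = ci[1], ci_high = ci[2], ci_level = ci_level,
           bootstrap_samples = diffs, seed = seed,
           excludes_zero = ci[1] > 0 || ci[2] < 0),
      class = "angle_bootstrap")
  })
}

#' @export
print.angle_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<angle_bootstrap> diff = %.2f deg, %g%% CI [%.2f, %.2f] (B = %d)\n",
    x$observed_diff, 100 * x$ci_level, x$ci_low, x$ci_high, x$B))
  cat(if (x$excludes_zero) "  CI excludes 0\n" else "  CI contains 0\n")
  invisible(x)
}
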