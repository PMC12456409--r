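# cumulative sum along rows, robust to 0/1-column inputs
row_cumsum <- function(m) {
  if (ncol(m) <= 1L) return(m)
  t(apply(m, 1L, cumsum))
}

#' Parameters for the persistent-random-walk track generator
#'
#' The motility null model used throughout: a fixed-speed persistent random
#' walk (PRW) in the plane whose heading decorrelates over a persistence
#' time `P`, optionally biased up a chemokine gradient. Speed and time step
#' default to the scale of amoeboid dendritic cells imaged every few
#' minutes (about 4 um/min, one frame per 4 min).
#'
#' @param n_tracks number of cells to simulate.
#' @param n_steps number of steps per track (tracks have `n_steps + 1`
#'   positions).
#' @param dt time step in minutes.
#' @param speed cell speed `s` in um/min (each step has length `s * dt`).
#' @param persistence persistence time `P` in minutes; the heading angle
#'   performs a wrapped-Gaussian walk with per-step s.d. `sqrt(2 * dt / P)`.
#'   `P = 0` gives uncorrelated headings, `P = Inf` a frozen heading.
#' @param bias gradient bias `b` in `[0, 1]`: each step moves along
#'   `normalize((1 - b) * u + b * g)` where `u` is the persistent heading
#'   and `g` the gradient direction. `b = 0` is an isotropic walk; `b = 1`
#'   moves straight up the gradient; the mean drift is approximately
#'   `b * s * dt` per step for small `b`.
#' @param gradient_direction 2-vector pointing up the gradient (normalized
#'   internally); default `+y`.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A `prw_params` list; the two-dimensional motility coefficient
#'   `D = s^2 * P / 2` is attached as `$diffusion`.
#' @export
prw_params <- function(n_tracks, n_steps, dt = 4, speed = 4,
                       persistence = 2, bias = 0,
                       gradient_direction = c(0, 1), seed = 1L) {
  n_tracks <- check_count(n_tracks, "n_tracks", lower = 1L)
  n_steps <- check_count(n_steps, "n_steps", lower = 1L)
  check_scalar(dt, "dt", lower = 1e-12)
  check_scalar(speed, "speed", lower = 0)
  check_scalar(persistence, "persistence", lower = 0, allow_inf = TRUE)
  check_scalar(bias, "bias", lower = 0, upper = 1)
  gradient_direction <- unit_vector(gradient_direction, "gradient_direction")
  seed <- check_count(seed, "seed", lower = 0L)
  structure(
    list(n_tracks = n_tracks, n_steps = n_steps, dt = dt, speed = speed,
         persistence = persistence, bias = bias,
         gradient_direction = gradient_direction, seed = seed,
         diffusion = speed^2 * persistence / 2),
    class = "prw_params")
}

#' Simulate persistent-random-walk cell tracks
#'
#' Generates a `track_set` of fixed-speed persistent random walks with an
#' optional gradient bias, the synthetic stand-in for manually tracked
#' cells migrating in a 3D collagen chamber (analyzed in planar projection).
#'
#' @param params a [prw_params()] object.
#' @return A `track_set` with `n_tracks` tracks of `n_steps + 1` positions
#'   starting at the origin, times `0, dt, ..., n_steps * dt`; the
#'   generating parameters are attached as `attr(, "ground_truth")`.
#' @examples
#' ts <- generate_prw_tracks(prw_params(5, 10, seed = 42))
#' n_tracks(ts)
#' @export
generate_prw_tracks <- function(params) {
  if (!inherits(params, "prw_params"))
    abort_param("`params` must be created with prw_params()")
  p <- params
  with_seed(p$seed, {
    n <- p$n_tracks
    m <- p$n_steps
    # heading chain: one row per track, one column per step
    theta0 <- stats::runif(n, 0, 2 * pi)
    if (p$persistence == 0) {
      theta <- matrix(stats::runif(n * m, 0, 2 * pi), n, m)
    } else if (is.infinite(p$persistence)) {
      theta <- matrix(theta0, n, m)
    } else {
      sd_step <- sqrt(2 * p$dt / p$persistence)
      inc <- matrix(stats::rnorm(n * (m - 1), sd = sd_step), n,
                    max(m - 1L, 0L))
      theta <- cbind(theta0, theta0 + row_cumsum(inc))
    }
    b <- p$bias
    g <- p$gradient_direction
    vx <- (1 - b) * cos(theta) + b * g[1]
    vy <- (1 - b) * sin(theta) + b * g[2]
    nrm <- sqrt(vx^2 + vy^2)
    # measure-zero cancellation (heading exactly opposite the gradient at
    # b = 1/2): fall back to the gradient direction
    degen <- nrm < 1e-12
    if (any(degen)) {
      vx[degen] <- g[1]; vy[degen] <- g[2]; nrm[degen] <- 1
    }
    step <- p$speed * p$dt
    x <- cbind(0, row_cumsum(step * vx / nrm))
    y <- cbind(0, row_cumsum(step * vy / nrm))
    ids <- sprintf("track%05d", seq_len(n))
    out <- data.frame(
      track_id = rep(ids, each = m + 1L),
      t_min = rep(seq(0, m * p$dt, by = p$dt), times = n),
      x_um = as.vector(t(x)),
      y_um = as.vector(t(y)))
    ts <- track_set(out, frame_interval = p$dt, condition = "synthetic")
    attr(ts, "ground_truth") <- p
    ts
  })
}
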