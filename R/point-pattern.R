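#' Construct a planar point pattern of single-molecule localizations
#'
#' Per-cell localization coordinates in nanometres inside an axis-aligned
#' rectangular observation window, the unit of analysis for nanocluster
#' sizing.
#'
#' @param x,y localization coordinates in nm.
#' @param window observation window `c(xmin, xmax, ymin, ymax)` in nm.
#' @param cell_id optional cell identifier.
#' @return A `point_pattern` object.
#' @export
point_pattern <- function(x, y, window, cell_id = NA_character_) {
  if (length(x) != length(y))
    abort_param("`x` and `y` must have the same length")
  if (!is.numeric(window) || length(window) != 4L || any(!is.finite(window)))
    abort_param("`window` must be c(xmin, xmax, ymin, ymax)")
  if (window[2] <= window[1] || window[4] <= window[3])
    abort_param("`window` must have positive area")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort_data("localization coordinates must be finite")
  inside <- x >= window[1] & x <= window[2] & y >= window[3] & y <= window[4]
  if (any(!inside))
    abort_data(sprintf("%d point(s) outside the window; filter on read",
                       sum(!inside)))
  structure(list(x = as.numeric(x), y = as.numeric(y), window = window,
                 cell_id = cell_id),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  w <- x$window
  cat(sprintf("<point_pattern> %d points in [%g, %g] x [%g, %g] nm",
              length(x$x), w[1], w[2], w[3], w[4]))
  if (!is.na(x$cell_id)) cat(" (cell ", x$cell_id, ")", sep = "")
  cat("\n")
  invisible(x)
}

n_points <- function(p) length(p$x)
window_area <- function(w) (w[2] - w[1]) * (w[4] - w[3])

#' Parameters of the Thomas cluster process
#'
#' The clustered null model used to validate the nanocluster pipeline:
#' Poisson parents of intensity `kappa`, each emitting a Poisson(`mu`)
#' number of offspring displaced by an isotropic Gaussian of s.d.
#' `sigma`. Defaults emulate a dSTORM-like density of about 4,000
#' localizations in a 5,000 x 5,000 nm membrane ROI.
#'
#' @param kappa parent intensity in 1/nm^2.
#' @param sigma offspring dispersion s.d. in nm.
#' @param mu mean offspring per parent.
#' @param window observation window `c(xmin, xmax, ymin, ymax)` in nm.
#' @param seed integer seed.
#' @return A `thomas_params` list. The theoretical pair correlation
#'   function of this process is
#'   `g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi kappa sigma^2)`,
#'   available as [thomas_pcf()].
#' @export
thomas_params <- function(kappa = 2e-6, sigma = 30, mu = 80,
                          window = c(0, 5000, 0, 5000), seed = 1L) {
  check_scalar(kappa, "kappa", lower = 1e-300)
  check_scalar(sigma, "sigma", lower = 1e-300)
  check_scalar(mu, "mu", lower = 1e-300)
  if (!is.numeric(window) || length(window) != 4L ||
      window[2] <= window[1] || window[4] <= window[3])
    abort_param("`window` must be c(xmin, xmax, ymin, ymax) with positive area")
  seed <- check_count(seed, "seed", lower = 0L)
  structure(list(kappa = kappa, sigma = sigma, mu = mu, window = window,
                 seed = seed),
            class = "thomas_params")
}

#' Simulate a Thomas-process point pattern
#'
#' Parents are drawn in the window dilated by `4 sigma` on each side (so
#' that the pattern restricted to the window is a piece of the stationary
#' process, without edge deficit); offspring falling outside the window
#' are discarded. The expected retained count is
#' `kappa * mu * |window|`.
#'
#' @param params a [thomas_params()] object.
#' @return A `point_pattern` with the generating parameters attached as
#'   `attr(, "ground_truth")`.
#' @export
generate_thomas_pattern <- function(params) {
  if (!inherits(params, "thomas_params"))
    abort_param("`params` must be created with thomas_params()")
  p <- params
  with_seed(p$seed, {
    w <- p$window
    pad <- 4 * p$sigma
    ext <- c(w[1] - pad, w[2] + pad, w[3] - pad, w[4] + pad)
    n_par <- stats::rpois(1L, p$kappa * window_area(ext))
    px <- stats::runif(n_par, ext[1], ext[2])
    py <- stats::runif(n_par, ext[3], ext[4])
    n_off <- stats::rpois(n_par, p$mu)
    cx <- rep(px, n_off) + stats::rnorm(sum(n_off), sd = p$sigma)
    cy <- rep(py, n_off) + stats::rnorm(sum(n_off), sd = p$sigma)
    keep <- cx >= w[1] & cx <= w[2] & cy >= w[3] & cy <= w[4]
    pat <- point_pattern(cx[keep], cy[keep], window = w,
                         cell_id = "synthetic")
    attr(pat, "ground_truth") <- p
    pat
  })
}

#' Theoretical pair correlation function of a Thomas process
#'
#' @param r radii in nm.
#' @param kappa parent intensity (1/nm^2).
#' @param sigma offspring dispersion s.d. (nm).
#' @return `g(r) = 1 + exp(-r^2/(4 sigma^2)) / (4 pi kappa sigma^2)`.
#' @export
thomas_pcf <- function(r, kappa, sigma) {
  1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * kappa * sigma^2)
}
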