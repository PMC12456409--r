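# Small fixtures built in code, shared across test files.

# straight track along +y at `speed` um/min
straight_track <- function(n = 16, dt = 4, speed = 5, id = "s1") {
  t <- seq(0, by = dt, length.out = n)
  data.frame(track_id = id, t_min = t, x_um = 0, y_um = speed * t)
}

make_track_set <- function(..., dt = 4) {
  track_set(do.call(rbind, list(...)), frame_interval = dt)
}

# uniform (CSR) point pattern in a square window
csr_pattern <- function(n, side = 5000, seed = 1) {
  dcmotion:::with_seed(seed, {
    point_pattern(stats::runif(n, 0, side), stats::runif(n, 0, side),
                  window = c(0, side, 0, side))
  })
}

# a pair_correlation object holding an analytically known curve
analytic_pcf <- function(r, g, window = c(0, 5000, 0, 5000),
                         n_pairs = rep(100, length(r))) {
  out <- data.frame(r = r, g = g, n_pairs = n_pairs)
  attr(out, "lambda") <- 1e-4
  attr(out, "window") <- window
  attr(out, "edge_correction") <- "translation"
  attr(out, "n") <- 1000L
  class(out) <- c("pair_correlation", "data.frame")
  out
}

# default synthetic polarized cell, pipeline-segmented geometry
segmented_cell <- function(spec = polarized_cell_spec()) {
  img <- generate_polarized_cell_image(spec)
  cmask <- segment_cell(img, "signal")
  nmask <- img$channels$nucleus > 0.5
  geom <- compute_geometry(cmask, nmask, img$pixel_size)
  list(img = img, geom = geom)
}
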