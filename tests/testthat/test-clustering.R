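test_that("Thomas generator hits the Poisson count expectation", {
  # kappa * mu * |W| = 2e-6 * 80 * 25e6 = 4000 expected points
  counts <- vapply(1:100, function(i)
    length(generate_thomas_pattern(thomas_params(seed = i))$x), numeric(1))
  expected <- 2e-6 * 80 * 5000^2
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # determinism
  a <- generate_thomas_pattern(thomas_params(seed = 5))
  b <- generate_thomas_pattern(thomas_params(seed = 5))
  expect_identical(a$x, b$x)
  expect_error(thomas_params(kappa = 0), class = "dcmotion_parameter_error")
})

test_that("pair correlation of CSR is flat at 1", {
  p <- csr_pattern(5000, seed = 2)
  pcf <- pair_correlation(p, r_max = 200, dr = 20)
  expect_true(all(abs(pcf$g[pcf$r >= 30] - 1) < 0.1))
  expect_lt(abs(mean(pcf$g) - 1), 0.05)
  f <- fit_cluster_model(pcf)
  expect_false(f$clustered)
  expect_true(is.na(f$amplitude) || f$amplitude < 0.2)
})

test_that("well-separated close pairs light up a single g(r) bin", {
  # five pairs at exactly 50 nm, pairs >> r_max apart: all pair counts in
  # one bin
  base <- cbind(c(500, 500, 2500, 2500, 4500),
                c(500, 4500, 500, 4500, 2500))
  x <- c(base[, 1], base[, 1] + 50)
  y <- c(base[, 2], base[, 2])
  p <- point_pattern(x, y, c(0, 5000, 0, 5000))
  pcf <- pair_correlation(p, r_max = 200, dr = 10)
  expect_equal(pcf$n_pairs[pcf$r == 45], 5)
  expect_true(all(pcf$n_pairs[pcf$r != 45] == 0))
  expect_gt(pcf$g[pcf$r == 45], 1)
})

test_that("estimated g(r) matches the Thomas closed form", {
  kappa <- 2e-6; sigma <- 30
  gs <- vapply(1:20, function(i) {
    pat <- generate_thomas_pattern(thomas_params(kappa = kappa,
                                                 sigma = sigma, seed = i))
    pair_correlation(pat, r_max = 200, dr = 10)$g
  }, numeric(20))
  g_mean <- rowMeans(gs)
  g_se <- apply(gs, 1L, stats::sd) / sqrt(ncol(gs))
  r <- seq(5, 195, by = 10)
  g_true <- thomas_pcf(r, kappa, sigma)
  # Monte-Carlo band: 4 SE, plus a small allowance for binning bias
  expect_true(all(abs(g_mean - g_true) < 4 * g_se + 0.05 * g_true))
  # g -> 1 far beyond the cluster scale (r > 10 sigma needs a wider window)
  pat <- generate_thomas_pattern(thomas_params(kappa = kappa / 4,
                                               sigma = sigma, mu = 320,
                                               window = c(0, 8000, 0, 8000),
                                               seed = 99))
  pcf <- pair_correlation(pat, r_max = 390, dr = 30)
  far <- pcf$g[pcf$r > 10 * sigma]
  expect_true(all(abs(far - 1) < 0.25 * thomas_pcf(0, kappa / 4, sigma)))
})

test_that("g(r) is invariant to translation and point relabelling", {
  pat <- generate_thomas_pattern(thomas_params(seed = 8))
  g0 <- pair_correlation(pat, 150, 10)$g
  # translate pattern and window together
  shifted <- point_pattern(pat$x + 300, pat$y - 200,
                           window = pat$window + c(300, 300, -200, -200))
  expect_equal(pair_correlation(shifted, 150, 10)$g, g0, tolerance = 1e-9)
  perm <- dcmotion:::with_seed(1, sample(length(pat$x)))
  relab <- point_pattern(pat$x[perm], pat$y[perm], pat$window)
  expect_equal(pair_correlation(relab, 150, 10)$g, g0, tolerance = 1e-9)
})

test_that("uniform thinning leaves the expected g(r) unchanged", {
  kappa <- 2e-6; sigma <- 30
  diff_sum <- 0
  for (i in 1:15) {
    pat <- generate_thomas_pattern(thomas_params(kappa = kappa,
                                                 sigma = sigma, seed = i))
    keep <- dcmotion:::with_seed(1000 + i,
                                 stats::runif(length(pat$x)) < 0.5)
    thin <- point_pattern(pat$x[keep], pat$y[keep], pat$window)
    g_full <- pair_correlation(pat, 150, 15)$g
    g_thin <- pair_correlation(thin, 150, 15)$g
    diff_sum <- diff_sum + (g_thin - g_full)
  }
  expect_true(all(abs(diff_sum / 15) < 0.2 * thomas_pcf(0, kappa, sigma)))
})

test_that("the cluster model refits its own analytic curve", {
  r <- seq(5, 195, by = 10)
  fit <- fit_cluster_model(analytic_pcf(r, thomas_pcf(r, 2e-6, 25)))
  expect_true(fit$converged)
  expect_true(fit$clustered)
  expect_equal(fit$sigma, 25, tolerance = 0.5 / 25)
  expect_equal(fit$diameter, 100, tolerance = 0.02)
  expect_equal(fit$baseline, 1, tolerance = 0.01)
})

test_that("r_max and bin-count guards reject bad inputs", {
  p <- csr_pattern(100, side = 1000, seed = 3)
  expect_error(pair_correlation(p, r_max = 600, dr = 10),
               class = "dcmotion_parameter_error")
  few <- point_pattern(runif(5, 0, 100), runif(5, 0, 100), c(0, 100, 0, 100))
  expect_error(pair_correlation(few, 40, 5), class = "dcmotion_data_error")
  small <- pair_correlation(csr_pattern(400, side = 1000, seed = 4),
                            r_max = 20, dr = 5)
  expect_error(fit_cluster_model(small), class = "dcmotion_data_error")
})

test_that("cluster summaries aggregate converged fits only", {
  mk <- function(d, conv = TRUE) structure(
    list(sigma = d / 4, diameter = if (conv) d else NA_real_,
         amplitude = 1, baseline = 1, fit_rss = 0, converged = conv,
         clustered = conv), class = "cluster_fit")
  s <- cluster_summary(list(mk(100), mk(120), mk(140)))
  expect_equal(s$mean_diameter, 120)
  expect_equal(s$sem_diameter, stats::sd(c(100, 120, 140)) / sqrt(3))
  expect_equal(s$sem_diameter, 11.547, tolerance = 1e-3)

  expect_message(s2 <- cluster_summary(list(mk(100), mk(120),
                                            mk(140, conv = FALSE))),
                 "excluded")
  expect_equal(s2$n_cells, 2L)
  expect_equal(s2$mean_diameter, 110)
  expect_error(cluster_summary(list(mk(1, conv = FALSE))),
               class = "dcmotion_data_error")
})

test_that("groups simulated at different sigma order their mean diameters", {
  n_pairs_ordered <- 0
  n_rep <- 10
  for (i in seq_len(n_rep)) {
    f25 <- fit_cluster_model(pair_correlation(
      generate_thomas_pattern(thomas_params(sigma = 25, seed = 100 + i)),
      r_max = 200, dr = 10))
    f35 <- fit_cluster_model(pair_correlation(
      generate_thomas_pattern(thomas_params(sigma = 35, seed = 200 + i)),
      r_max = 200, dr = 10))
    if (f25$converged && f35$converged && f25$diameter < f35$diameter)
      n_pairs_ordered <- n_pairs_ordered + 1
  }
  expect_gte(n_pairs_ordered, n_rep - 1)
})
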