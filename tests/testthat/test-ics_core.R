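# Fluctuation field, spatial ACF, Gaussian fitting and derived metrics.

test_that("fluctuation field centers the ROI and keeps the mean", {
  const <- pixel_grid(matrix(5, 4, 4), 25)
  fl <- fluctuation_field(const)
  expect_true(all(fl$delta == 0))
  expect_identical(fl$mean_intensity, 5)

  g <- pixel_grid(matrix(c(1, 5, 3, 7), 2, 2), 25)
  fl2 <- fluctuation_field(g)
  expect_identical(fl2$mean_intensity, 4)
  expect_identical(fl2$delta, matrix(c(-3, 1, -1, 3), 2, 2))

  set.seed(8)
  r <- pixel_grid(matrix(runif(64, 1, 10), 8, 8), 25)
  flr <- fluctuation_field(r)
  expect_lt(abs(sum(flr$delta)), 1e-9 * 64 * flr$mean_intensity)

  expect_error(fluctuation_field(pixel_grid(matrix(0, 4, 4), 25)),
               "degenerate")
  # background subtraction corrects the mean, not the fluctuations
  flb <- fluctuation_field(const, background = 2)
  expect_identical(flb$mean_intensity, 3)
  expect_true(all(flb$delta == 0))
  expect_error(fluctuation_field(const, background = 5), "degenerate")
})

test_that("spatial ACF matches its definition and analytic cases", {
  # constant image: zero fluctuations, g = 0 at every lag
  ac0 <- spatial_acf(fluctuation_field(pixel_grid(matrix(7, 8, 8), 25)),
                     max_lag_px = 2)
  expect_true(all(ac0$g == 0))

  # one-hot 4x4 image: g(0,0) = variance/mean^2 = N - 1 = 15
  one <- matrix(0, 4, 4); one[2, 3] <- 1
  ac1 <- spatial_acf(fluctuation_field(pixel_grid(one, 25)), max_lag_px = 1)
  expect_equal(acf_at(ac1, 0, 0), 15, tolerance = 1e-12)

  # transform result equals the direct double-loop oracle at all lags
  set.seed(21)
  m <- matrix(runif(64, 0, 4), 8, 8)
  fl <- fluctuation_field(pixel_grid(m, 25))
  ac <- spatial_acf(fl, max_lag_px = 2)
  for (xi in ac$xi) for (eta in ac$eta) {
    expect_lt(abs(acf_at(ac, xi, eta) -
                  acf_direct_oracle(fl$delta, fl$mean_intensity, xi, eta)),
              1e-10)
  }

  # zero-lag value equals population variance over squared mean
  expect_equal(acf_at(ac, 0, 0),
               mean((m - mean(m))^2) / mean(m)^2, tolerance = 1e-10)

  # lag-inversion symmetry holds exactly
  for (xi in -3:3) for (eta in -3:3) {
    expect_identical(acf_at(ac, xi, eta), acf_at(ac, -xi, -eta))
  }

  expect_error(spatial_acf(fl, max_lag_px = 10), "max_lag_px")
})

test_that("Gaussian ACF fit recovers parameters and ignores the zero lag", {
  # model-generated surface with corrupted zero lag: exact recovery
  ac <- model_acf_surface(0.5, 4, 0.01, corrupt_zero_lag = 0.9)
  fit <- fit_acf(ac)
  expect_true(fit$converged)
  expect_equal(fit$g0, 0.5, tolerance = 1e-6)
  expect_equal(fit$omega_px, 4, tolerance = 1e-6)
  expect_equal(fit$g_inf, 0.01, tolerance = 1e-6)
  expect_identical(fit$omega_nm, fit$omega_px * 25)

  # two surfaces identical except at (0,0) give identical fits
  ac_a <- model_acf_surface(0.3, 5, 0, corrupt_zero_lag = 0.31)
  ac_b <- model_acf_surface(0.3, 5, 0, corrupt_zero_lag = 5)
  fa <- fit_acf(ac_a); fb <- fit_acf(ac_b)
  expect_identical(fa$g0, fb$g0)
  expect_identical(fa$omega_px, fb$omega_px)
  expect_identical(fa$g_inf, fb$g_inf)

  # all-zero surface: degenerate, no metrics downstream
  ac0 <- model_acf_surface(0, 4, 0)
  f0 <- fit_acf(ac0)
  expect_false(f0$converged)
  fl <- fluctuation_field(pixel_grid(matrix(1:16 + 0, 4, 4), 25))
  expect_error(ics_metrics(f0, fl), "converge")
})

test_that("ICS metrics follow the defining formulas", {
  fit <- structure(list(g0 = 0.1, omega_px = 4, omega_nm = 100, g_inf = 0,
                        rss = 0, converged = TRUE, degenerate = FALSE,
                        n_points_fit = 100L), class = "acf_fit")
  fl <- structure(list(delta = matrix(0, 2, 2), mean_intensity = 200,
                       pixel_size_nm = 25, channel_label = "ch0"),
                  class = "fluctuation_field")
  m <- ics_metrics(fit, fl, roi_id = "r1", channel = "ch0", condition = "WT")
  expect_equal(m$n_assemblies, 10)                       # 1/g0
  # CD = 1/(g0 pi omega^2), omega = 0.1 um: 1/(0.1 * pi * 0.01)
  expect_equal(m$cluster_density_per_um2, 1 / (0.1 * pi * 0.01),
               tolerance = 1e-12)
  expect_equal(m$degree_of_aggregation,
               200 / m$cluster_density_per_um2, tolerance = 1e-12)

  fit$g0 <- 0.5; fit$omega_nm <- 100
  m2 <- ics_metrics(fit, fl)
  expect_equal(m2$cluster_density_per_um2, 63.662, tolerance = 1e-4)
})

test_that("Pearson colocalization matches hand computation", {
  set.seed(5)
  a <- pixel_grid(matrix(runif(64, 1, 9), 8, 8), 25)
  expect_equal(pearson_colocalization(a, a), 1, tolerance = 1e-12)

  b <- pixel_grid(10 - a$values, 25)
  expect_equal(pearson_colocalization(a, b), -1, tolerance = 1e-12)

  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3, 3)
  y <- matrix(c(2, 1, 4, 4, 6, 5, 9, 8, 12), 3, 3)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_colocalization(pixel_grid(x, 25), pixel_grid(y, 25)),
               manual, tolerance = 1e-12)

  cst <- pixel_grid(matrix(3, 8, 8), 25)
  expect_error(pearson_colocalization(a, cst), "constant")
  expect_error(pearson_colocalization(a, pixel_grid(x, 25)), "shapes")
})

test_that("batch analysis flags non-converged ROIs instead of failing", {
  # pure noise with no spatial structure: fit may converge or not, but the
  # row must always come back with a convergence flag
  set.seed(2)
  noise <- pixel_grid(matrix(rpois(4096, 100) + 0, 64, 64), 25)
  row <- ics_analyze(noise, roi_id = "noise")
  expect_identical(nrow(row), 1L)
  expect_true(is.logical(row$converged))
  if (!row$converged) expect_true(is.na(row$cluster_density_per_um2))
})
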