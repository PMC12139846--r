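# Emitter-field simulation, image rendering and FRAP trace generation.

test_that("emitter placement follows the Poisson cluster model", {
  # zero rate -> empty field
  p0 <- sim_params(cluster_rate = 0, seed = 1)
  expect_identical(nrow(simulate_emitter_field(p0)$emitters), 0L)

  # monomeric clusters: every cluster id appears exactly once
  p1 <- sim_params(cluster_rate = 20, monomers_per_cluster = fixed_monomers(1),
                   seed = 4)
  f1 <- simulate_emitter_field(p1)
  expect_true(all(table(f1$emitters$cluster_id) == 1L))

  # fixed k multiplicities
  p5 <- sim_params(cluster_rate = 5, monomers_per_cluster = fixed_monomers(5),
                   seed = 4)
  expect_true(all(table(simulate_emitter_field(p5)$emitters$cluster_id) == 5L))

  # positions stay inside the placement region
  pm <- sim_params(cluster_rate = 50, seed = 2)
  fm <- simulate_emitter_field(pm)
  lo <- -pm$margin_nm; hi <- fm$field_extent_nm + pm$margin_nm
  expect_true(all(fm$emitters$x_nm >= lo & fm$emitters$x_nm < hi))
  expect_true(all(fm$emitters$y_nm >= lo & fm$emitters$y_nm < hi))
})

test_that("cluster counts match the Poisson mean over Monte-Carlo seeds", {
  # rate 10/um^2 on a 3.2 x 3.2 um field (margin 0): mean count 102.4
  counts <- vapply(1:500, function(s) {
    p <- sim_params(cluster_rate = 10, margin_nm = 0, seed = s)
    nrow(simulate_emitter_field(p)$cluster_centers)
  }, numeric(1))
  sem <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 102.4), 2 * sem + 1e-12)

  # expected emitter count = rate * area * E[multiplicity]
  em_counts <- vapply(1:300, function(s) {
    p <- sim_params(cluster_rate = 10, margin_nm = 0,
                    monomers_per_cluster = poisson_monomers(3), seed = s)
    nrow(simulate_emitter_field(p)$emitters)
  }, numeric(1))
  expected <- 10 * 3.2^2 * 4
  sem <- sd(em_counts) / sqrt(length(em_counts))
  expect_lt(abs(mean(em_counts) - expected), 3 * sem)
})

test_that("simulation is bit-identical for a fixed seed", {
  p <- sim_params(cluster_rate = 25, seed = 11)
  f1 <- simulate_emitter_field(p); f2 <- simulate_emitter_field(p)
  expect_identical(f1, f2)
  expect_identical(render_image(f1, p)$values, render_image(f2, p)$values)
  t1 <- simulate_frap_trace(0.05, 0.8, noise_sd = 0.05, seed = 9)
  t2 <- simulate_frap_trace(0.05, 0.8, noise_sd = 0.05, seed = 9)
  expect_identical(t1$values, t2$values)
  # same placement re-renders identically under different noise settings
  pn <- sim_params(cluster_rate = 25, seed = 11, read_noise_sd = 5)
  expect_identical(simulate_emitter_field(pn)$emitters, f1$emitters)
})

test_that("rendering integrates the PSF exactly over pixels", {
  ext <- 64 * 25
  p <- sim_params(roi_px = 64, background_mean = 0, read_noise_sd = 0,
                  shot_noise = FALSE, margin_nm = 0, seed = 1)

  # empty field, no background, no noise -> all zeros
  f0 <- emitter_field(numeric(0), numeric(0), integer(0),
                      field_extent_nm = ext)
  expect_true(all(render_image(f0, p)$values == 0))

  # one interior emitter of unit brightness -> pixel sum 1 within 1e-6
  f1 <- emitter_field(800, 800, 1L, brightness = 1, field_extent_nm = ext)
  expect_lt(abs(sum(render_image(f1, p)$values) - 1), 1e-6)

  # many interior emitters: total signal = sum of brightness within 1e-4 rel
  set.seed(42)
  n <- 40
  f <- emitter_field(runif(n, 400, ext - 400), runif(n, 400, ext - 400),
                     seq_len(n), brightness = 500, field_extent_nm = ext)
  total <- sum(render_image(f, p)$values)
  expect_lt(abs(total - n * 500) / (n * 500), 1e-4)
})

test_that("Poisson shot noise is unbiased about the noiseless image", {
  ext <- 32 * 25
  base <- sim_params(roi_px = 32, background_mean = 4, read_noise_sd = 0,
                     shot_noise = FALSE, margin_nm = 0, seed = 1)
  f <- emitter_field(c(300, 500, 420), c(350, 300, 550), 1:3,
                     brightness = 300, field_extent_nm = ext)
  noiseless <- render_image(f, base)$values

  n_rep <- 2000
  acc <- matrix(0, 32, 32)
  for (s in seq_len(n_rep)) {
    pn <- sim_params(roi_px = 32, background_mean = 4, read_noise_sd = 0,
                     shot_noise = TRUE, margin_nm = 0, seed = s)
    acc <- acc + render_image(f, pn)$values
  }
  emp_mean <- acc / n_rep
  se <- sqrt(noiseless / n_rep)   # per-pixel SE of a Poisson mean
  expect_true(all(abs(emp_mean - noiseless) <= 3.9 * se + 1e-9))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(roi_px = 0), "positive")
  expect_error(sim_params(read_noise_sd = -1), "non-negative")
  expect_warning(sim_params(psf_e2_radius_nm = 4), "undersampled")
  expect_error(simulate_frap_trace(-0.1, 0.8), "positive")
  expect_error(simulate_frap_trace(0.1, 1.4), "\\[0, 1\\]")
  expect_error(simulate_frap_trace(0.1, 0.8, noise_sd = -1), "non-negative")
})

test_that("two-channel co-aggregation places channel-2 clusters as specified", {
  # full co-aggregation, point clusters: ch2 centers are a subset of ch1
  p <- sim_params(co_aggregation = 1, cluster_spread_nm = 0, seed = 3)
  s2 <- simulate_two_channel(p)
  key1 <- paste(s2$field_ch0$cluster_centers[, 1],
                s2$field_ch0$cluster_centers[, 2])
  key2 <- paste(s2$field_ch1$cluster_centers[, 1],
                s2$field_ch1$cluster_centers[, 2])
  expect_true(all(key2 %in% key1))

  # independence: mean Pearson over seeds within 3 SEM of 0
  pc <- vapply(1:100, function(s) {
    sim <- simulate_two_channel(sim_params(co_aggregation = 0, seed = s))
    pearson_colocalization(sim$image_ch0, sim$image_ch1)
  }, numeric(1))
  expect_lt(abs(mean(pc)), 3 * sd(pc) / sqrt(length(pc)))

  # co-aggregation raises the correlation well above the independent case
  pc1 <- vapply(1:20, function(s) {
    sim <- simulate_two_channel(sim_params(co_aggregation = 1,
                                           cluster_spread_nm = 0, seed = s))
    pearson_colocalization(sim$image_ch0, sim$image_ch1)
  }, numeric(1))
  expect_gt(mean(pc1), 0.3)
})

test_that("channel symmetry: equal monomeric channels give matching DA", {
  ratios <- vapply(1:50, function(s) {
    sim <- simulate_two_channel(sim_params(cluster_rate = 40,
                                           co_aggregation = 0, seed = s))
    r1 <- ics_analyze(sim$image_ch0, background = 10)
    r2 <- ics_analyze(sim$image_ch1, background = 10)
    c(r1$degree_of_aggregation, r2$degree_of_aggregation)
  }, numeric(2))
  da1 <- mean(ratios[1, ]); da2 <- mean(ratios[2, ])
  expect_lt(abs(da1 - da2) / da1, 0.15)
})

test_that("FRAP traces follow the one-phase model exactly when noiseless", {
  sched <- frap_schedule()
  expect_identical(sched[1], 0)
  expect_equal(length(sched), 51L)
  expect_equal(max(sched), 5 * 0.526 + 15 * 1 + 30 * 4)

  tr <- simulate_frap_trace(0.1, 1, schedule = c(0, 10), noise_sd = 0)
  expect_equal(tr$values[1], 0)
  expect_equal(tr$values[2], 1 - exp(-1), tolerance = 1e-12)

  tr_inf <- simulate_frap_trace(0.1, 0.73, schedule = c(0, 1e6), noise_sd = 0)
  expect_equal(tr_inf$values[2], 0.73, tolerance = 1e-12)

  tr_full <- simulate_frap_trace(0.05, 0.8, noise_sd = 0)
  expect_equal(tr_full$values, 0.8 * (1 - exp(-0.05 * tr_full$times_s)),
               tolerance = 1e-12)
})

test_that("simulations round-trip through the on-disk layout", {
  dir <- withr::local_tempdir()
  p <- sim_params(cluster_rate = 20, roi_px = 64, seed = 5)
  sim <- simulate_two_channel(p)
  paths <- write_simulation(sim, p, dir)
  imgs <- read_image(paths$ch0, pixel_size_nm = p$pixel_size_nm)
  expect_identical(imgs[[1]]$values, round(sim$image_ch0$values))
  truth <- read.csv(paths$truth)
  expect_setequal(unique(truth$channel), c("ch0", "ch1"))
  expect_equal(sum(truth$channel == "ch0"), nrow(sim$field_ch0$emitters))
  prm <- jsonlite::read_json(paths$params)
  expect_equal(prm$cluster_rate, 20)
})
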