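test_that("the standard wave set enumerates 6 directions x 2 polarizations", {
  ws <- standard_12_waves(60e9)
  expect_length(ws, 12)
  for (w in ws) {
    expect_equal(sum(w$k_hat^2), 1, tolerance = 1e-12)
    expect_equal(sum(w$e_hat^2), 1, tolerance = 1e-12)
    expect_equal(sum(w$k_hat * w$e_hat), 0, tolerance = 1e-12)
  }
  # exactly 4 waves polarized along each Cartesian axis
  pol_axis <- sapply(ws, function(w) which(abs(w$e_hat) > 0.99))
  expect_equal(as.integer(table(pol_axis)), rep(4L, 3))
  # each propagation direction appears twice
  k_axis <- sapply(ws, function(w) which(abs(w$k_hat) > 0.99))
  expect_equal(as.integer(table(k_axis)), rep(4L, 3))
})

test_that("random waves are seeded, orthonormal and isotropic", {
  a <- random_waves(30, seed = 5, f = 60e9)
  b <- random_waves(30, seed = 5, f = 60e9)
  expect_identical(a, b)
  expect_false(identical(a, random_waves(30, seed = 6, f = 60e9)))
  for (w in a) expect_equal(sum(w$k_hat * w$e_hat), 0, tolerance = 1e-9)

  big <- random_waves(1e4, seed = 1, f = 60e9)
  kbar <- rowMeans(sapply(big, function(w) w$k_hat))
  se <- sqrt(1 / 3 / 1e4)   # each component has variance 1/3
  expect_true(all(abs(kbar) < 3 * se))
})

test_that("field rescaling is exactly quadratic", {
  expect_equal(scale_pabs(2.37e-9, 1), 2.37e-9)
  expect_equal(scale_pabs(1, 61.5), 3782.25)
  expect_equal(scale_pabs(4e-9, 0.5), 1e-9)
})

test_that("far-field bound follows 2 l^2 / lambda", {
  expect_equal(far_field_min_distance(0, 60e9), 0)
  expect_equal(far_field_min_distance(4e-3, 60e9), 6.406e-3,
               tolerance = 1e-3)
  fs <- c(2e9, 6e9, 60e9, 240e9)
  expect_true(all(diff(far_field_min_distance(4e-3, fs)) > 0))
})

test_that("KS statistic follows the empirical-CDF definition", {
  expect_equal(ks_statistic(1:10, 1:10)$statistic, 0)
  expect_equal(ks_statistic(1:10, 101:110)$statistic, 1)
  set.seed(3)
  x <- rnorm(40); y <- rnorm(35, mean = 0.5)
  ours <- ks_statistic(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 0.01)
})

test_that("aggregation reproduces hand-computed summaries and ratios", {
  toy <- data.frame(
    model = rep(c("a", "b"), each = 4),
    frequency_hz = rep(c(6e9, 60e9), 4),
    wave_id = rep(1:2, 4),
    part = "whole",
    pabs_w = c(0.1, 1.6, 0.1, 1.6, 0.1, 1.6, 0.1, 1.6) * 1e-9,
    volume_m3 = 1e-9)
  class(toy) <- c("exposure_result", "data.frame")
  agg <- aggregate_exposure(toy, groups = list(g1 = "a", g2 = "b"))
  expect_equal(agg$ratio(60e9, 6e9), 16)
  expect_equal(agg$ks$statistic, 0)   # identical groups
  one <- aggregate_exposure(toy[toy$model == "a" & toy$wave_id == 1, ])
  expect_equal(one$per_model$mean_w, one$per_model$min_w)
  expect_equal(one$per_model$mean_w, one$per_model$max_w)
  expect_error(aggregate_exposure(toy, groups = list(g = character())),
               "at least one")
})

test_that("configurations validate and load from YAML", {
  expect_error(exposure_config(frequencies_ghz = c(6, -2)), "frequencies")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("frequencies_ghz: [6, 60]",
               "voxel_um: 140",
               "e_rms: 1",
               "seed: 7",
               "pml:",
               "  cells: 8"), path)
  cfg <- config_from_yaml(path)
  expect_s3_class(cfg, "exposure_config")
  expect_equal(cfg$frequencies_ghz, c(6, 60))
  expect_equal(cfg$pml$cells, 8)
  expect_equal(cfg$seed, 7L)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("frequencies_gzh: [6]", bad)
  expect_error(config_from_yaml(bad), "unknown configuration key")
})

test_that("zero-conductivity dielectric gives zero absorbed power", {
  lossless <- debye_params(5)   # no relaxations, no static conduction
  blob <- voxel_model(array(TRUE, c(3, 3, 3)), 30e-6)
  cfg <- exposure_config(frequencies_ghz = 240, conv_tol = 1e-3)
  res <- run_protocol(blob, dielectric = lossless, config = cfg,
                      model_id = "blob")
  expect_equal(nrow(res), 12)   # 12 waves x 1 frequency, no labels
  expect_true(all(res$pabs_w < 1e-13))
})

test_that("protocol output is tidy, deterministic and label-resolved", {
  d <- aedes_debye("pair")
  # minimal labeled model: two voxels, head + thorax
  occ <- array(FALSE, c(4, 3, 3)); occ[2:3, 2, 2] <- TRUE
  lab <- array(0L, c(4, 3, 3)); lab[2, 2, 2] <- 1L; lab[3, 2, 2] <- 2L
  mdl <- voxel_model(occ, 30e-6, labels = lab)
  cfg <- exposure_config(frequencies_ghz = 240)
  r1 <- run_protocol(mdl, d, cfg, model_id = "m")
  r2 <- run_protocol(mdl, d, cfg, model_id = "m")
  expect_identical(r1$pabs_w, r2$pabs_w)
  expect_setequal(unique(r1$part), c("whole", "head", "thorax"))
  # the two parts partition the body: their volume integrals add up and
  # land within a factor of the flux-based whole-body estimate (which
  # carries no staircase surface bias, large for a 2-voxel body)
  w1 <- r1[r1$wave_id == 1, ]
  parts_sum <- w1$pabs_w[w1$part == "head"] + w1$pabs_w[w1$part == "thorax"]
  whole <- w1$pabs_w[w1$part == "whole"]
  expect_gt(parts_sum, 0)
  expect_lt(abs(log(parts_sum / whole)), log(4))
  expect_true(all(r1$pabs_w >= 0))
})
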