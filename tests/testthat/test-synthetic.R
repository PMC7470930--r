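# Generator closed forms, geometric construction, slicing behaviour and
# determinism.

test_that("lognormal moment matching reproduces printed mean/median pairs", {
  lp <- lognormal_params_from_mean_median(0.05, 0.05)
  expect_equal(lp$sigma, 0)
  lp1 <- lognormal_params_from_mean_median(0.050, 0.027)
  expect_equal(lp1$mu, log(0.027))
  expect_equal(lp1$sigma, sqrt(2 * log(50 / 27)))
  set.seed(10)
  draws <- rlnorm(1e6, lp1$mu, lp1$sigma)
  expect_equal(mean(draws), 0.050, tolerance = 0.01)
  expect_equal(median(draws), 0.027, tolerance = 0.01)
  lp2 <- lognormal_params_from_mean_median(0.089, 0.030)
  draws2 <- rlnorm(1e6, lp2$mu, lp2$sigma)
  expect_equal(median(draws2), 0.030, tolerance = 0.02)
  expect_error(lognormal_params_from_mean_median(0.02, 0.03),
               class = "spinemorph_validation_error")
})

test_that("perforation intercept calibration hits the target rate", {
  for (target in c(0.0152, 0.0642, 0.2115)) {
    b0 <- calibrate_perforation_intercept(target, 0.9, 1.1)
    rate <- integrate(function(z) plogis(b0 + 0.9 * 1.1 * z) * dnorm(z), -8, 8)$value
    expect_equal(rate, target, tolerance = 1e-6)
  }
  # zero slope reduces to a plain Bernoulli with the base probability
  cfg0 <- tiny_config(perforation_rate = 0.3)
  cfg0$volume_odds_slope <- 0
  cfg0$perforation_intercept <- calibrate_perforation_intercept(0.3, 0, 1)
  expect_equal(plogis(cfg0$perforation_intercept), 0.3, tolerance = 1e-6)
})

test_that("sampled populations have the configured structure", {
  cfg <- tiny_config(n_dendrites = 7, density = 2.0)
  set.seed(20)
  truth <- sample_spine_population(cfg)
  expect_equal(nrow(truth$dendrites), 7L)
  total <- sum(truth$dendrites$n_spines)
  lambda <- 2.0 * sum(truth$dendrites$arc_length)
  expect_lt(abs(total - lambda), 3 * sqrt(lambda))
  expect_true(all(truth$spines$head_volume >= 0.001))
  expect_true(all(truth$spines$neck_length >= 0.05))
  # noise-free coupling: PSD / V^b constant
  cfg0 <- tiny_config()
  cfg0$psd_noise_sd <- 1e-12
  set.seed(21)
  t0 <- sample_spine_population(cfg0)
  expect_equal(stats::var(t0$spines$psd_area / t0$spines$head_volume), 0,
               tolerance = 1e-12)
})

test_that("head spheres have the inverted-volume radius and necks the stated span", {
  v <- 0.036
  cfg <- tiny_config(n_dendrites = 1)
  set.seed(22)
  truth <- sample_spine_population(cfg)
  expect_equal(truth$spines$head_radius,
               (3 * truth$spines$head_volume / (4 * pi))^(1 / 3))
  expect_equal((3 * v / (4 * pi))^(1 / 3), 0.2048, tolerance = 1e-3)
  scene <- build_geometry(truth$dendrites[1, ], truth$spines, cfg)
  for (i in seq_along(scene$spines)) {
    sp <- scene$spines[[i]]
    tr <- truth$spines[truth$spines$spine_id == sp$spine_id, ]
    # head centre sits neck_length + head radius beyond the shaft surface
    d_axis <- sqrt(sum((sp$center - sp$neck_start)^2))
    expect_equal(d_axis, tr$neck_length + tr$head_radius, tolerance = 1e-9)
    if (sp$perforated) expect_gt(sp$psd_rho_in, 0)
    else expect_equal(sp$psd_rho_in, 0)
  }
})

test_that("slicing a sphere yields the expected section count and volume", {
  # r = 0.2, t = 0.05: floor/ceil of 2r/t -> 8 or 9 nonempty sections
  cfg <- tiny_config()
  scene <- structure(list(
    dendrite_id = "dx", arc_length = 10,
    axis = cbind(x = c(0, 0), y = c(0, 0), z = c(1, 11), s = c(0, 10)),
    shaft_radius = 0.3, margin = 1, z_top = 12,
    spines = list(list(spine_id = "sx", center = c(2, 0, 5.513), radius = 0.2,
                       neck_start = c(0.3, 0, 5.513), neck_end = c(1.8, 0, 5.513),
                       psd_center = c(2.2, 0, 5.513), psd_e2 = c(0, 1, 0),
                       psd_rho_out = 0.1, psd_rho_in = 0, perforated = FALSE))),
    class = "dendrite_scene")
  series <- suppressWarnings(slice_to_series(scene, cfg))
  heads <- Filter(function(ct) ct$object_id == "sx", series$contours)
  expect_true(length(heads) %in% c(8L, 9L))
  m <- measure_series(series)
  v_true <- 4 / 3 * pi * 0.2^3
  expect_equal(m$spines$head_volume_um3[m$spines$spine_id == "sx"], v_true,
               tolerance = 0.05)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  cfg <- tiny_config(n_dendrites = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  r1 <- suppressWarnings(generate_dataset(list(cfg), d1, seed = 99))
  r2 <- suppressWarnings(generate_dataset(list(cfg), d2, seed = 99))
  r3 <- suppressWarnings(generate_dataset(list(cfg), d3, seed = 100))
  expect_identical(r1$manifest, r2$manifest)
  expect_identical(r1$truth_spines, r2$truth_spines)
  f <- r1$manifest$file[1]
  expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                   readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  expect_false(identical(r1$truth_spines$head_volume, r3$truth_spines$head_volume))
  expect_error(generate_dataset(list(cfg, cfg), withr::local_tempdir(), 1),
               class = "spinemorph_validation_error")
})

test_that("generated series load with the emitted contour count and pass validation", {
  cfg <- tiny_config(n_dendrites = 1)
  dir <- withr::local_tempdir()
  res <- suppressWarnings(generate_dataset(list(cfg), dir, seed = 1))
  f <- file.path(dir, res$manifest$file[1])
  s <- load_series(f)   # full validation including polygon simplicity
  expect_s3_class(s, "spine_series")
  raw <- jsonlite::read_json(f)
  expect_length(s$contours, length(raw$contours))
})

test_that("end-to-end parameter recovery on one group stays within sampling error", {
  cfg <- tiny_config(n_dendrites = 7, density = 2.0, perforation_rate = 0.15)
  dir <- withr::local_tempdir()
  res <- suppressWarnings(generate_dataset(list(cfg), dir, seed = 123))
  m <- measure_dataset(dir, morphometry_config(boundary_policy = "include_all"))
  truth <- res$truth_spines
  mm <- m$spines[match(truth$spine_id, m$spines$spine_id), ]
  # per-spine agreement between pipeline estimates and generative truth
  expect_equal(mm$head_volume_um3, truth$head_volume, tolerance = 0.08)
  expect_equal(mm$psd_area_um2, truth$psd_area, tolerance = 0.15)
  expect_equal(mm$neck_length_um, truth$neck_length, tolerance = 0.10)
  expect_equal(mm$perforated, truth$perforated)
  # dendrite arc lengths within 2%
  md <- m$dendrites[match(res$truth_dendrites$dendrite_id, m$dendrites$dendrite_id), ]
  expect_equal(md$path_length_um, res$truth_dendrites$arc_length, tolerance = 0.02)
  expect_equal(md$n_spines, res$truth_dendrites$n_spines)
  # pooled density within 3 Poisson standard errors of the generative rate
  dens <- sum(md$n_spines) / sum(md$path_length_um)
  se <- sqrt(sum(md$n_spines)) / sum(md$path_length_um)
  expect_lt(abs(dens - 2.0), 3 * se)
})
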