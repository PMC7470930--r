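# Planimetric primitives against closed forms, and rectangle-rule volume /
# surface estimators against analytic solids.

test_that("contour area matches closed forms and is rigid-motion invariant", {
  expect_equal(contour_area(square_pts()), 1.0)
  expect_equal(contour_area(square_pts(at = c(5, 5))), 1.0)
  # regular 64-gon of circumradius 0.5: area = n r^2 sin(2 pi / n) / 2
  expect_equal(contour_area(regular_polygon(64, 0.5)),
               64 * 0.25 * sin(2 * pi / 64) / 2, tolerance = 1e-12)
  # rotation invariance
  ang <- 0.73
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  expect_equal(contour_area(square_pts() %*% rot), 1.0)
  # quadratic scaling
  expect_equal(contour_area(3 * square_pts()), 9.0)
})

test_that("self-intersecting and degenerate contours raise geometry errors", {
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(contour_area(bowtie), class = "spinemorph_geometry_error")
  expect_error(contour_area(rbind(c(0, 0), c(1, 0))),
               class = "spinemorph_geometry_error")
  expect_false(is_simple_polygon(bowtie))
  expect_true(is_simple_polygon(regular_polygon(16)))
  # non-convex but simple polygon passes the general test
  lshape <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2))
  expect_true(is_simple_polygon(lshape))
  expect_equal(contour_area(lshape), 3.0)
})

test_that("object volume follows the rectangle rule", {
  expect_equal(object_volume(list(square_pts()), 0.05), 0.05)
  two <- list(regular_polygon(64, sqrt(0.2 / (64 * sin(2 * pi / 64) / 2))),
              regular_polygon(64, sqrt(0.3 / (64 * sin(2 * pi / 64) / 2))))
  expect_equal(object_volume(two, 0.04), 0.02, tolerance = 1e-12)
  expect_error(object_volume(list(), 0.05), class = "spinemorph_geometry_error")
})

test_that("sliced-sphere volume converges to the analytic value", {
  r <- 0.3
  v_true <- 4 / 3 * pi * r^3
  errs <- vapply(c(0.1, 0.05, 0.025), function(t) {
    abs(object_volume(sphere_slices(r, t), t, check = FALSE) - v_true) / v_true
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # monotone convergence on the ladder
  expect_lt(errs[3], 0.05)
  # at thickness r/20 the estimate is within 5%
  expect_equal(object_volume(sphere_slices(r, r / 20), r / 20, check = FALSE),
               v_true, tolerance = 0.05)
})

test_that("surface area = lateral + optional end caps, and approximates a sphere", {
  expect_equal(object_surface_area(list(square_pts()), 0.05, include_end_caps = FALSE),
               0.2)
  expect_equal(object_surface_area(list(square_pts()), 0.05), 2.2)
  # lateral stair-step estimate is exact for a plane-perpendicular cylinder
  r <- 0.3
  cyl <- lapply(1:40, function(k) regular_polygon(512, r))
  est_cyl <- object_surface_area(cyl, 0.05, include_end_caps = FALSE, check = FALSE)
  expect_equal(est_cyl, 2 * pi * r * 40 * 0.05, tolerance = 1e-4)
  # for a sphere the perimeter-times-thickness convention converges to the
  # projected-band limit pi^2 r^2 (a documented pi/4 underestimate of 4 pi r^2
  # on oblique surfaces), caps vanishing with thickness
  t <- 0.005
  est <- object_surface_area(sphere_slices(r, t), t, include_end_caps = FALSE,
                             check = FALSE)
  expect_equal(est, pi^2 * r^2, tolerance = 0.02)
})

test_that("psd_area is thickness times summed trace length", {
  traces <- list(rbind(c(0, 0), c(0.4, 0)), rbind(c(0, 0), c(0.5, 0)),
                 rbind(c(0, 0), c(0.3, 0), c(0.3, 0.1)))
  expect_equal(psd_area(traces, 0.05), 0.05 * (0.4 + 0.5 + 0.4))
  expect_equal(psd_area(list(rbind(c(0, 0), c(1, 0))), 0.04), 0.04)
  expect_warning(psd_area(list(rbind(c(0, 0), c(0, 0))), 0.04), "zero-length")
  # chord-integral identity: chords of a disc of radius rho summed over fine
  # sections approach pi rho^2
  rho <- 0.2
  for (t in c(0.02, 0.01, 0.005)) {
    zs <- seq(-rho + t / 3, rho, by = t)
    chords <- lapply(zs, function(z) rbind(c(0, 0), c(2 * sqrt(rho^2 - z^2), 0)))
    expect_equal(psd_area(chords, t), pi * rho^2, tolerance = 4 * t / rho)
  }
})

test_that("path length handles lines, corners, and a helix", {
  expect_equal(path_length(rbind(c(0, 0, 0), c(1, 0, 0))), 1.0)
  expect_equal(path_length(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))), 2.0)
  expect_error(path_length(rbind(c(0, 0, 0))), class = "spinemorph_geometry_error")
  expect_error(path_length(rbind(c(0, 0, 0), c(0, 0, 0))),
               class = "spinemorph_geometry_error")
  # helix x = R cos(u), y = R sin(u), z = c u has arc length u sqrt(R^2 + c^2)
  R <- 0.7; cc <- 0.25; u <- seq(0, 4 * pi, length.out = 100)
  helix <- cbind(R * cos(u), R * sin(u), cc * u)
  expect_equal(path_length(helix), 4 * pi * sqrt(R^2 + cc^2), tolerance = 0.01)
})

test_that("dendrite path length uses the centroid polyline", {
  s <- minimal_series(n_sections = 201)
  cts <- lapply(s$contours, `[[`, "points")
  secs <- vapply(s$contours, `[[`, integer(1), "section")
  expect_equal(dendrite_path_length(cts, secs, 0.05), 10.0, tolerance = 1e-9)
  # translation invariance
  cts2 <- lapply(cts, function(p) p + 3.3)
  expect_equal(dendrite_path_length(cts2, secs, 0.05), 10.0, tolerance = 1e-9)
  expect_error(dendrite_path_length(cts[1], secs[1], 0.05),
               class = "spinemorph_geometry_error")
})

test_that("spine density is count over length and inverts exactly", {
  expect_equal(spine_density(13, 10), 1.3)
  expect_equal(spine_density(0, 7.3), 0)
  expect_error(spine_density(3, 0), class = "spinemorph_geometry_error")
  for (n in c(1L, 7L, 132L)) {
    len <- runif(1, 5, 25)
    expect_equal(spine_density(n, len) * len, n)
  }
})

test_that("neck length from anchors recovers the head-base to shaft gap", {
  axis <- cbind(0, 0, seq(0, 10, by = 0.05))
  center <- c(0.3 + 1.0 + 0.2, 0, 5.0)   # shaft radius + neck + head radius
  expect_equal(neck_length_from_anchors(center, 0.2, axis, 0.3), 1.0)
  # floored at zero for sessile spines
  expect_equal(neck_length_from_anchors(c(0.35, 0, 5), 0.2, axis, 0.3), 0)
})

test_that("metrics are invariant under rigid in-plane transforms of a series", {
  cfg <- tiny_config(n_dendrites = 1)
  set.seed(7)
  truth <- sample_spine_population(cfg)
  scene <- build_geometry(truth$dendrites[1, ],
                          truth$spines[truth$spines$dendrite_id ==
                                         truth$dendrites$dendrite_id[1], ], cfg)
  series <- suppressWarnings(slice_to_series(scene, cfg))
  ang <- 0.41
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  moved <- series
  moved$contours <- lapply(series$contours, function(ct) {
    ct$points <- ct$points %*% rot + matrix(c(2, -1), nrow(ct$points), 2, byrow = TRUE)
    ct
  })
  m1 <- measure_series(series)
  m2 <- measure_series(moved)
  expect_equal(m2$spines$head_volume_um3, m1$spines$head_volume_um3, tolerance = 1e-9)
  expect_equal(m2$spines$psd_area_um2, m1$spines$psd_area_um2, tolerance = 1e-9)
  expect_equal(m2$spines$neck_length_um, m1$spines$neck_length_um, tolerance = 1e-9)
  expect_equal(m2$dendrites$path_length_um, m1$dendrites$path_length_um,
               tolerance = 1e-9)
})
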