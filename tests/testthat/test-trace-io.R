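# JSON series round trips and total validation.

test_that("a minimal series round-trips through JSON exactly", {
  s <- minimal_series(n_sections = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_series(s, path)
  s2 <- load_series(path)
  expect_equal(s2$metadata$n_sections, 1L)
  expect_length(s2$contours, 1L)
  expect_equal(s2$contours[[1]]$points, s$contours[[1]]$points, tolerance = 1e-12)
  expect_equal(s2$hierarchy, s$hierarchy)
})

test_that("a generated multi-section series round-trips with equal contours", {
  cfg <- tiny_config(n_dendrites = 1)
  set.seed(3)
  truth <- sample_spine_population(cfg)
  scene <- build_geometry(truth$dendrites[1, ], truth$spines, cfg)
  series <- suppressWarnings(slice_to_series(scene, cfg))
  path <- withr::local_tempfile(fileext = ".json")
  write_series(series, path)
  s2 <- load_series(path, check_geometry = FALSE)
  expect_length(s2$contours, length(series$contours))
  expect_equal(lapply(s2$contours, `[[`, "points"),
               lapply(series$contours, `[[`, "points"), tolerance = 1e-9)
  expect_equal(vapply(s2$contours, `[[`, integer(1), "section"),
               vapply(series$contours, `[[`, integer(1), "section"))
  # writing the reloaded series again is byte-identical (determinism)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_series(series, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("validation rejects malformed series with typed, named errors", {
  md <- series_metadata(4.5, 50, 3)
  shaft <- data.frame(id = "d1", kind = "shaft", parent_id = NA_character_)
  ct <- list(contour(0, "d1", regular_polygon(12, 0.3)))

  expect_error(series_metadata(-4.5, 50, 3), class = "spinemorph_validation_error")
  expect_error(series_metadata(4.5, 0, 3), class = "spinemorph_validation_error")
  expect_error(series_metadata(4.5, 50, 0), class = "spinemorph_validation_error")

  # psd referencing a missing spine names the id
  h <- rbind(shaft, data.frame(id = "p9", kind = "psd", parent_id = "s_missing"))
  expect_error(spine_series(md, ct, h), "s_missing",
               class = "spinemorph_validation_error")

  # psd attached to a shaft rather than a spine head
  h <- rbind(shaft, data.frame(id = "p1", kind = "psd", parent_id = "d1"))
  expect_error(spine_series(md, ct, h), class = "spinemorph_validation_error")

  # cycle
  h <- data.frame(id = c("s1", "d1"), kind = c("spine_head", "shaft"),
                  parent_id = c("d1", NA))
  cyc <- h
  cyc$parent_id <- c("s1", NA)
  cyc$kind <- c("spine_head", "shaft")
  expect_error(
    spine_series(md, ct, data.frame(id = c("a", "b"),
                                    kind = c("spine_head", "spine_head"),
                                    parent_id = c("b", "a"))),
    class = "spinemorph_validation_error")

  # two necks on one spine
  h <- rbind(shaft,
             data.frame(id = "s1", kind = "spine_head", parent_id = "d1"),
             data.frame(id = c("n1", "n2"), kind = "spine_neck", parent_id = "s1"))
  expect_error(spine_series(md, ct, h), "more than one neck",
               class = "spinemorph_validation_error")

  # contour outside the stack
  bad_ct <- list(contour(5, "d1", regular_polygon(12, 0.3)))
  expect_error(spine_series(md, bad_ct, shaft), class = "spinemorph_validation_error")

  # open trace with one point
  one_pt <- structure(list(section = 0L, object_id = "d1", closed = FALSE,
                           points = matrix(c(0, 0), 1)), class = "contour")
  expect_error(spine_series(md, list(one_pt), shaft),
               class = "spinemorph_validation_error")

  # self-intersecting closed contour
  bow <- list(contour(0, "d1", rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))))
  expect_error(spine_series(md, bow, shaft), class = "spinemorph_validation_error")

  # cycle refuses to write
  s <- minimal_series()
  s$hierarchy$parent_id <- "d1"  # shaft parented to itself
  expect_error(write_series(s, tempfile()), class = "spinemorph_validation_error")
})

test_that("malformed JSON and missing files raise I/O errors", {
  expect_error(load_series(file.path(tempdir(), "nope.json")),
               class = "spinemorph_io_error")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_series(bad), class = "spinemorph_io_error")
})

test_that("spine/dendrite CSV export has one row per record", {
  cfg <- tiny_config(n_dendrites = 2)
  set.seed(11)
  truth <- sample_spine_population(cfg)
  dir <- withr::local_tempdir()
  res <- suppressWarnings(generate_dataset(list(cfg), dir, seed = 11))
  meas <- measure_dataset(dir, morphometry_config(boundary_policy = "include_all"))
  paths <- export_spine_table(meas$spines, meas$dendrites, withr::local_tempdir())
  sp <- read.csv(paths[["spines"]])
  dd <- read.csv(paths[["dendrites"]])
  expect_equal(nrow(sp), nrow(meas$spines))
  expect_equal(nrow(dd), 2L)
  expect_type(sp$perforated, "logical")
  # >= 6 significant digits survive the round trip
  expect_equal(sp$head_volume_um3, meas$spines$head_volume_um3, tolerance = 1e-7)
  expect_warning(export_spine_table(meas$spines[0, ], meas$dendrites, withr::local_tempdir()),
                 "header-only")
})
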