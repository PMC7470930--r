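# Fixture builders used across test files. All fixtures are constructed in
# code; nothing is read from disk except files the tests themselves write.

square_pts <- function(side = 1, at = c(0, 0)) {
  rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)) +
    matrix(at, 4, 2, byrow = TRUE)
}

regular_polygon <- function(n, r = 0.5, center = c(0, 0), phase = 0) {
  ang <- phase + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# closed contours of a sphere sliced at planes z = k * t (k any integer),
# polygonized finely so slicing error dominates polygon error
sphere_slices <- function(r, t, center_z = 0, n_pts = 256) {
  ks <- seq(ceiling((center_z - r) / t), floor((center_z + r) / t))
  ks <- ks[abs(ks * t - center_z) < r]
  lapply(ks, function(k) {
    regular_polygon(n_pts, sqrt(r^2 - (k * t - center_z)^2))
  })
}

# minimal one-shaft series: a straight vertical cylinder traced on n sections
minimal_series <- function(n_sections = 3, radius = 0.3, t_nm = 50, px_nm = 4.5) {
  md <- series_metadata(px_nm, t_nm, n_sections, "fixture")
  contours <- lapply(seq_len(n_sections) - 1L, function(k) {
    contour(k, "d1", regular_polygon(24, radius, center = c(1, 1)))
  })
  hier <- data.frame(id = "d1", kind = "shaft", parent_id = NA_character_,
                     stringsAsFactors = FALSE)
  spine_series(md, contours, hier)
}

tiny_config <- function(n_dendrites = 2, density = 2.0, perforation_rate = 0.1,
                        ...) {
  synth_group_config("WT", 1, n_dendrites = n_dendrites,
                     dendrite_length_mean = 9.2, dendrite_length_sd = 1.6,
                     spine_density = density,
                     head_volume_mean = 0.050, head_volume_median = 0.027,
                     neck_length_mean = 1.0, neck_length_sd = 0.5,
                     perforation_rate = perforation_rate, ...)
}
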