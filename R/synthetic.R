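# Synthetic serial-section dendrite generator.
#
# The generator emulates the trace-level structure the morphometry pipeline
# consumes: a tortuous dendritic shaft running through the section stack,
# spherical spine heads attached by cylindrical necks, and planar PSD discs
# (annuli when perforated) tangent to the head surface and facing away from
# the shaft. Head volumes are lognormal, moment-matched to a printed group
# mean and median; neck lengths truncated normal; spine counts Poisson at the
# group density; PSD area couples to head volume as c * V^b with lognormal
# noise; perforation probability rises with log head volume. Every sampled
# quantity is recorded as ground truth so pipeline estimates can be checked
# by parameter recovery.

#' Lognormal parameters from a mean and a median
#'
#' For a lognormal distribution, `mu = log(median)` and matching the mean
#' `exp(mu + sigma^2/2)` gives `sigma = sqrt(2 * log(mean / median))`. A
#' right-skewed sample with printed mean and median therefore determines the
#' generative distribution; mean < median is incompatible with a lognormal.
#'
#' @param mean target mean (> 0), same units as `median`.
#' @param median target median (`mean >= median > 0`).
#' @return list with `mu` and `sigma` (log scale).
#' @export
lognormal_params_from_mean_median <- function(mean, median) {
  if (median <= 0) stop_validation("median must be positive")
  if (mean < median) stop_validation("mean < median is incompatible with a lognormal")
  list(mu = log(median), sigma = sqrt(2 * log(mean / median)))
}

#' Calibrate the perforation-model intercept for a target rate
#'
#' Perforation is Bernoulli with probability
#' `plogis(intercept + slope * (log V - mu))` where `log V ~ N(mu, sigma)`.
#' Given the slope and sigma, solves for the intercept whose population
#' perforation rate equals `target_rate` (by Gauss-Hermite-free numerical
#' integration over the normal log-volume density).
#'
#' @param target_rate desired expected perforation probability in (0, 1).
#' @param slope log-volume odds slope.
#' @param sigma lognormal sigma of head volumes.
#' @return intercept (log-odds at the median volume).
#' @export
calibrate_perforation_intercept <- function(target_rate, slope, sigma) {
  if (target_rate <= 0 || target_rate >= 1) stop_validation("target_rate must be in (0,1)")
  expected_rate <- function(b0) {
    stats::integrate(function(z) stats::plogis(b0 + slope * sigma * z) * stats::dnorm(z),
                     -8, 8, rel.tol = 1e-10)$value - target_rate
  }
  stats::uniroot(expected_rate, c(-30, 30), tol = 1e-10)$root
}

# expected perforation rate implied by a config (used as the generative value
# in recovery checks)
expected_perforation_rate <- function(config) {
  stats::integrate(function(z) {
    stats::plogis(config$perforation_intercept +
                    config$volume_odds_slope * config$head_volume_sigma * z) *
      stats::dnorm(z)
  }, -8, 8, rel.tol = 1e-10)$value
}

# smallest PSD area whose annular perforation is representable at the
# digitization resolution: the hole must span a section plane (inner radius
# 0.6 * thickness) and the ring must be at least ~3 pixels wide
min_perforated_psd_area <- function(config) {
  t_um <- config$section_thickness_nm / 1000
  px_um <- config$pixel_size_nm / 1000
  rho_in <- 0.6 * t_um
  pi * ((rho_in + 3 * px_um)^2 - rho_in^2)
}

# mean of a normal(mean, sd) truncated below at `lower`
truncnorm_mean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

rtruncnorm_lower <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Generative configuration for one (genotype, age) group
#'
#' @param genotype,age_months group labels.
#' @param n_dendrites dendrites to generate.
#' @param dendrite_length_mean,dendrite_length_sd dendrite arc length (um),
#'   truncated to the reconstructable 5-25 um range.
#' @param spine_density expected spines per um of dendrite.
#' @param head_volume_mean,head_volume_median lognormal head-volume targets
#'   (um^3); sampled volumes are floored at 0.001 um^3, the smallest head
#'   volume observed in the reference survey.
#' @param neck_length_mean,neck_length_sd neck length (um), truncated normal
#'   with lower bound `neck_min`.
#' @param neck_min shortest permitted neck (default 0.05 um).
#' @param psd_coupling_c,psd_coupling_b PSD-area coupling `c * V^b`
#'   (defaults c = 1 um^2 per um^3, b = 1: pure linear).
#' @param psd_noise_sd lognormal sigma of multiplicative PSD noise
#'   (default 0.3).
#' @param perforation_rate target population perforation probability; the
#'   model intercept is calibrated to it given `volume_odds_slope`.
#' @param volume_odds_slope log-odds increase of perforation per unit log
#'   head volume (default 0.9, encoding that perforated PSDs concentrate in
#'   large/mushroom spines).
#' @param shaft_radius dendritic shaft radius (default 0.3 um).
#' @param section_thickness_nm,pixel_size_nm imaging calibration (defaults
#'   50 nm and 4.5 nm).
#' @return a `synth_group_config` list (includes derived `head_volume_mu`,
#'   `head_volume_sigma`, `perforation_intercept`).
#' @export
synth_group_config <- function(genotype, age_months, n_dendrites,
                               dendrite_length_mean, dendrite_length_sd,
                               spine_density,
                               head_volume_mean, head_volume_median,
                               neck_length_mean, neck_length_sd,
                               neck_min = 0.05,
                               psd_coupling_c = 1.0, psd_coupling_b = 1.0,
                               psd_noise_sd = 0.3,
                               perforation_rate = 0.05, volume_odds_slope = 0.9,
                               shaft_radius = 0.3,
                               section_thickness_nm = 50, pixel_size_nm = 4.5) {
  for (v in c(n_dendrites, dendrite_length_mean, dendrite_length_sd, spine_density,
              head_volume_mean, head_volume_median, neck_length_mean, neck_length_sd,
              psd_coupling_c, psd_noise_sd, shaft_radius,
              section_thickness_nm, pixel_size_nm)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop_validation("all scale parameters must be positive scalars")
    }
  }
  lp <- lognormal_params_from_mean_median(head_volume_mean, head_volume_median)
  cfg <- list(genotype = as.character(genotype), age_months = as.numeric(age_months),
              n_dendrites = as.integer(n_dendrites),
              dendrite_length_mean = dendrite_length_mean,
              dendrite_length_sd = dendrite_length_sd,
              spine_density = spine_density,
              head_volume_mean = head_volume_mean,
              head_volume_median = head_volume_median,
              head_volume_mu = lp$mu, head_volume_sigma = lp$sigma,
              neck_length_mean = neck_length_mean, neck_length_sd = neck_length_sd,
              neck_min = neck_min,
              psd_coupling_c = psd_coupling_c, psd_coupling_b = psd_coupling_b,
              psd_noise_sd = psd_noise_sd,
              perforation_rate = perforation_rate,
              volume_odds_slope = volume_odds_slope,
              perforation_intercept = calibrate_perforation_intercept(
                perforation_rate, volume_odds_slope, max(lp$sigma, 1e-8)),
              shaft_radius = shaft_radius,
              section_thickness_nm = section_thickness_nm,
              pixel_size_nm = pixel_size_nm)
  structure(cfg, class = "synth_group_config")
}

#' Sample ground-truth spine populations for one group
#'
#' Draws dendrite arc lengths, Poisson spine counts at the configured density,
#' lognormal head volumes, truncated-normal neck lengths, noisy PSD areas and
#' volume-dependent perforation flags. Uses the current RNG stream (seed it
#' with `set.seed()` or via [generate_dataset()]).
#'
#' @param config a [synth_group_config()].
#' @return list of tibbles `dendrites` (`dendrite_id`, `arc_length`,
#'   `n_spines`) and `spines` (per-spine generative truth).
#' @export
sample_spine_population <- function(config) {
  nd <- config$n_dendrites
  len <- pmin(rtruncnorm_lower(nd, config$dendrite_length_mean,
                               config$dendrite_length_sd, 5), 25)
  counts <- stats::rpois(nd, config$spine_density * len)
  dendrite_id <- sprintf("%s_%smo_d%02d", config$genotype, config$age_months, seq_len(nd))
  spines <- lapply(seq_len(nd), function(i) {
    n <- counts[i]
    if (n == 0L) return(NULL)
    v <- stats::rlnorm(n, config$head_volume_mu, config$head_volume_sigma)
    low <- which(v < 0.001)
    while (length(low)) {
      v[low] <- stats::rlnorm(length(low), config$head_volume_mu, config$head_volume_sigma)
      low <- low[v[low] < 0.001]
    }
    neck <- rtruncnorm_lower(n, config$neck_length_mean, config$neck_length_sd,
                             config$neck_min)
    psd <- config$psd_coupling_c * v^config$psd_coupling_b *
      exp(stats::rnorm(n, 0, config$psd_noise_sd))
    p_perf <- stats::plogis(config$perforation_intercept +
                              config$volume_odds_slope * (log(v) - config$head_volume_mu))
    # a discontinuity is only physically representable in a PSD wider than
    # the digitization resolution; perforated PSDs live in large spines anyway
    perforated <- stats::runif(n) < p_perf & psd >= min_perforated_psd_area(config)
    attach_s <- sort(stats::runif(n, 0.2, len[i] - 0.2))
    theta <- stats::runif(n, 0, 2 * pi)
    did <- dendrite_id[i]
    tibble::tibble(
      dendrite_id = did,
      spine_id = sprintf("%s_s%03d", did, seq_len(n)),
      head_volume = v, head_radius = (3 * v / (4 * pi))^(1 / 3),
      neck_length = neck, psd_area = psd, perforated = perforated,
      attach_s = attach_s, theta = theta
    )
  })
  list(
    dendrites = tibble::tibble(dendrite_id = dendrite_id,
                               genotype = config$genotype,
                               age_months = config$age_months,
                               arc_length = len, n_spines = counts),
    spines = dplyr::bind_rows(spines)
  )
}

# smooth tortuous axis of given arc length, parametrized by arc length:
# lateral coordinates are low-frequency sinusoids, the axial derivative is
# chosen so the speed is exactly 1
make_axis <- function(arc_length, ds = 0.02) {
  s <- seq(0, arc_length, by = ds)
  a1 <- stats::runif(1, 0.15, 0.3); a2 <- stats::runif(1, 0.15, 0.3)
  l1 <- stats::runif(1, 6, 9);      l2 <- stats::runif(1, 7, 11)
  p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
  x <- a1 * sin(2 * pi * s / l1 + p1)
  y <- a2 * sin(2 * pi * s / l2 + p2)
  vx <- (2 * pi * a1 / l1) * cos(2 * pi * s / l1 + p1)
  vy <- (2 * pi * a2 / l2) * cos(2 * pi * s / l2 + p2)
  vz <- sqrt(pmax(1 - vx^2 - vy^2, 0.5))
  z <- cumsum(c(0, (vz[-1] + vz[-length(vz)]) / 2 * diff(s)))
  cbind(x = x - x[1], y = y - y[1], z = z, s = s)
}

axis_interp <- function(axis, at, key) {
  cbind(stats::approx(axis[, key], axis[, "x"], xout = at, rule = 2)$y,
        stats::approx(axis[, key], axis[, "y"], xout = at, rule = 2)$y,
        stats::approx(axis[, key], axis[, "z"], xout = at, rule = 2)$y)
}

#' Build the 3D scene for one synthetic dendrite
#'
#' The dendrite is a tube of the stated arc length around a smooth tortuous
#' axis running through the section stack; each spine is a sphere of the
#' sampled head volume, displaced laterally from its attachment point by
#' shaft radius + neck length + head radius; the PSD is a planar disc
#' (annulus when perforated) of the sampled area, tangent to the head at the
#' point opposite the neck. Overlapping head placements are resolved by
#' re-drawing the attachment azimuth (at most 100 attempts per spine).
#'
#' @param dendrite one row of the ground-truth `dendrites` tibble.
#' @param spines the ground-truth spine rows of that dendrite.
#' @param config the group [synth_group_config()].
#' @return a `dendrite_scene` list.
#' @export
build_geometry <- function(dendrite, spines, config) {
  t_um <- config$section_thickness_nm / 1000
  axis <- make_axis(dendrite$arc_length)
  margin <- max(1.0, if (nrow(spines)) max(spines$head_radius) + 0.2 else 1.0)
  # z-margin keeps every head strictly inside the stack
  axis[, "z"] <- axis[, "z"] + margin
  placed <- list()
  if (nrow(spines)) {
    anchors <- axis_interp(axis, spines$attach_s, "s")
    for (i in seq_len(nrow(spines))) {
      rh <- spines$head_radius[i]
      offset <- config$shaft_radius + spines$neck_length[i] + rh
      theta <- spines$theta[i]
      ok <- FALSE
      for (attempt in seq_len(100L)) {
        u <- c(cos(theta), sin(theta), 0)
        center <- anchors[i, ] + u * offset
        clash <- FALSE
        for (p in placed) {
          if (sqrt(sum((center - p$center)^2)) < rh + p$radius + 0.02) {
            clash <- TRUE
            break
          }
        }
        if (!clash) {
          ok <- TRUE
          break
        }
        theta <- stats::runif(1, 0, 2 * pi)
      }
      if (!ok) stop_geometry(sprintf("cannot place spine '%s' without overlap",
                                     spines$spine_id[i]))
      a_psd <- spines$psd_area[i]
      if (spines$perforated[i]) {
        rho_in <- max(0.5 * sqrt(a_psd / pi), 0.6 * t_um)
        rho_out <- sqrt(a_psd / pi + rho_in^2)
      } else {
        rho_in <- 0
        rho_out <- sqrt(a_psd / pi)
      }
      placed[[length(placed) + 1L]] <- list(
        spine_id = spines$spine_id[i], center = center, radius = rh,
        neck_start = anchors[i, ] + u * config$shaft_radius,
        neck_end = anchors[i, ] + u * (config$shaft_radius + spines$neck_length[i]),
        psd_center = center + u * rh, psd_e2 = c(-sin(theta), cos(theta), 0),
        psd_rho_out = rho_out, psd_rho_in = rho_in,
        perforated = spines$perforated[i]
      )
    }
  }
  z_top <- max(axis[, "z"]) + margin
  structure(list(dendrite_id = dendrite$dendrite_id, axis = axis,
                 arc_length = dendrite$arc_length,
                 shaft_radius = config$shaft_radius, margin = margin,
                 z_top = z_top, spines = placed),
            class = "dendrite_scene")
}

# regular polygon approximating a circle, vertex count set by a sagitta
# tolerance (the in-plane digitization resolution)
circle_polygon <- function(center_xy, r, tol) {
  n <- if (r <= tol) 12L else min(max(ceiling(pi / acos(1 - tol / r)), 12L), 64L)
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center_xy[1] + r * cos(ang), center_xy[2] + r * sin(ang))
}

#' Slice a dendrite scene into a serial-section trace series
#'
#' Cross-sections every solid with the section planes z = k * thickness:
#' shaft and head cross-sections become closed polygonal contours (digitized
#' at the pixel-size sagitta tolerance), PSD discs become open chord traces
#' (two disjoint chords where a plane crosses the annular hole). Cross
#' sections below twice the pixel size are dropped (one summary warning).
#'
#' @param scene a [build_geometry()] scene.
#' @param config the group [synth_group_config()].
#' @return a validated `spine_series`.
#' @export
slice_to_series <- function(scene, config) {
  t_um <- config$section_thickness_nm / 1000
  px_um <- config$pixel_size_nm / 1000
  n_sections <- ceiling(scene$z_top / t_um) + 1L
  z_planes <- (seq_len(n_sections) - 1L) * t_um
  md <- series_metadata(config$pixel_size_nm, config$section_thickness_nm,
                        n_sections, scene$dendrite_id)
  contours <- list()
  dropped <- 0L
  add <- function(ct) contours[[length(contours) + 1L]] <<- ct
  shaft_id <- scene$dendrite_id
  zr <- range(scene$axis[, "z"])
  ks <- which(z_planes >= zr[1] & z_planes <= zr[2])
  cent <- axis_interp(scene$axis, z_planes[ks], "z")
  for (j in seq_along(ks)) {
    add(contour(ks[j] - 1L, shaft_id,
                circle_polygon(cent[j, 1:2], scene$shaft_radius, px_um)))
  }
  hier <- list(data.frame(id = shaft_id, kind = "shaft", parent_id = NA_character_,
                          stringsAsFactors = FALSE))
  for (sp in scene$spines) {
    hier[[length(hier) + 1L]] <- data.frame(
      id = c(sp$spine_id, paste0(sp$spine_id, "_psd")),
      kind = c("spine_head", "psd"),
      parent_id = c(shaft_id, sp$spine_id), stringsAsFactors = FALSE)
    kz <- which(abs(z_planes - sp$center[3]) < sp$radius)
    emitted <- 0L
    for (k in kz) {
      r_slice <- sqrt(sp$radius^2 - (z_planes[k] - sp$center[3])^2)
      if (r_slice < 2 * px_um) {
        dropped <- dropped + 1L
        next
      }
      add(contour(k - 1L, sp$spine_id, circle_polygon(sp$center[1:2], r_slice, px_um)))
      emitted <- emitted + 1L
    }
    if (emitted == 0L) {
      stop_geometry(sprintf("spine '%s' produced no head cross-section", sp$spine_id))
    }
    # PSD disc/annulus: plane at height a0 above the disc centre cuts the
    # chord(s) |b| in [rho_in, rho_out] along the in-plane direction e2
    kp <- which(abs(z_planes - sp$psd_center[3]) < sp$psd_rho_out)
    for (k in kp) {
      a0 <- z_planes[k] - sp$psd_center[3]
      w <- sqrt(sp$psd_rho_out^2 - a0^2)
      e2 <- sp$psd_e2[1:2]
      c_xy <- sp$psd_center[1:2]
      chords <- if (sp$psd_rho_in > 0 && abs(a0) < sp$psd_rho_in) {
        w_in <- sqrt(sp$psd_rho_in^2 - a0^2)
        list(c(w_in, w), c(-w, -w_in))
      } else {
        list(c(-w, w))
      }
      for (ch in chords) {
        if (abs(ch[2] - ch[1]) < 2 * px_um) {
          dropped <- dropped + 1L
          next
        }
        pts <- rbind(c_xy + ch[1] * e2, c_xy + ch[2] * e2)
        add(contour(k - 1L, paste0(sp$spine_id, "_psd"), pts, closed = FALSE))
      }
    }
  }
  if (dropped > 0L) {
    warning(sprintf("%s: %d degenerate cross-section(s) below pixel resolution dropped",
                    scene$dendrite_id, dropped), call. = FALSE)
  }
  spine_series(md, contours, do.call(rbind, hier), validate = FALSE)
}

#' Generate a full synthetic dataset
#'
#' One series JSON file per dendrite, a manifest binding files to groups, and
#' ground-truth tables. Byte-identical output for a fixed seed.
#'
#' @param configs list of [synth_group_config()] (e.g.
#'   [striatal_msn_presets()]); group labels must be unique.
#' @param out_dir output directory (created).
#' @param seed master seed for all randomness.
#' @return (invisibly) list with `dir`, `manifest`, `truth_spines`,
#'   `truth_dendrites`.
#' @export
generate_dataset <- function(configs, out_dir, seed = 1L) {
  labels <- vapply(configs, function(cf) paste0(cf$genotype, "_", cf$age_months), "")
  if (anyDuplicated(labels)) {
    stop_validation(sprintf("duplicate group label '%s'", labels[duplicated(labels)][1L]))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  manifest <- list()
  truth_s <- list()
  truth_d <- list()
  for (cf in configs) {
    truth <- sample_spine_population(cf)
    for (i in seq_len(nrow(truth$dendrites))) {
      drow <- truth$dendrites[i, ]
      srows <- truth$spines[truth$spines$dendrite_id == drow$dendrite_id, , drop = FALSE]
      scene <- build_geometry(drow, srows, cf)
      series <- slice_to_series(scene, cf)
      fname <- paste0(drow$dendrite_id, ".json")
      write_series(series, file.path(out_dir, fname))
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        file = fname, genotype = cf$genotype, age_months = cf$age_months,
        dendrite_id = drow$dendrite_id)
    }
    truth_s[[length(truth_s) + 1L]] <- truth$spines
    truth_d[[length(truth_d) + 1L]] <- truth$dendrites
  }
  manifest <- dplyr::bind_rows(manifest)
  truth_spines <- dplyr::bind_rows(truth_s)
  truth_dendrites <- dplyr::bind_rows(truth_d)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(truth_spines, file.path(out_dir, "truth_spines.csv"), row.names = FALSE)
  utils::write.csv(truth_dendrites, file.path(out_dir, "truth_dendrites.csv"),
                   row.names = FALSE)
  invisible(list(dir = out_dir, manifest = manifest,
                 truth_spines = truth_spines, truth_dendrites = truth_dendrites))
}
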