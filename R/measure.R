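# Morphometric measurement of a loaded trace series: applies the planimetric
# estimators to every traced object and assembles per-spine and per-dendrite
# record tables.

#' Measure every object in a spine series
#'
#' For each spine head: volume (section areas x thickness), surface area
#' (perimeters x thickness plus end caps), PSD area (trace lengths x
#' thickness), perforation flag, neck length (explicit neck trace if present,
#' otherwise the head-base to shaft-surface anchor surrogate), boundary flag
#' and size class. For each dendrite: centroid-polyline path length, spine
#' count and density.
#'
#' @param series a `spine_series` (from [load_series()] or the generator).
#' @param config a [morphometry_config()].
#' @return list of tibbles `spines` and `dendrites`.
#' @export
measure_series <- function(series, config = morphometry_config()) {
  md <- series$metadata
  t_um <- md$section_thickness_nm / 1000
  h <- series$hierarchy
  by_object <- split(seq_along(series$contours),
                     vapply(series$contours, function(ct) ct$object_id, ""))
  sec_of <- vapply(series$contours, function(ct) ct$section, integer(1))

  shaft_ids <- h$id[h$kind == "shaft"]
  shafts <- list()
  for (sid in shaft_ids) {
    idx <- by_object[[sid]]
    if (is.null(idx)) stop_validation(sprintf("shaft '%s' has no contours", sid))
    secs <- sec_of[idx]
    ord <- order(secs)
    cts <- lapply(series$contours[idx[ord]], `[[`, "points")
    len <- dendrite_path_length(cts, secs[ord], t_um)
    cent <- t(vapply(cts, contour_centroid, numeric(2)))
    shafts[[sid]] <- list(
      length = len,
      axis = cbind(cent, secs[ord] * t_um),
      radii = sqrt(vapply(cts, contour_area, numeric(1), check = FALSE) / pi),
      sections = secs[ord]
    )
  }

  spine_ids <- h$id[h$kind == "spine_head"]
  parent_of <- stats::setNames(h$parent_id, h$id)
  psd_parent <- stats::setNames(h$parent_id[h$kind == "psd"], h$id[h$kind == "psd"])
  neck_parent <- stats::setNames(h$parent_id[h$kind == "spine_neck"],
                                 h$id[h$kind == "spine_neck"])

  rows <- lapply(spine_ids, function(sid) {
    idx <- by_object[[sid]]
    if (is.null(idx)) stop_validation(sprintf("spine '%s' has no head contours", sid))
    secs <- sec_of[idx]
    ord <- order(secs)
    cts <- lapply(series$contours[idx[ord]], `[[`, "points")
    areas <- vapply(cts, contour_area, numeric(1), check = FALSE)
    vol <- sum(areas) * t_um
    surf <- object_surface_area(cts, t_um, include_end_caps = config$include_end_caps,
                                check = FALSE)
    cent <- t(vapply(cts, contour_centroid, numeric(2)))
    zs <- secs[ord] * t_um
    head_center <- c(colSums(cent * areas), sum(zs * areas)) / sum(areas)
    head_radius <- sqrt(max(areas) / pi)

    # PSD
    pid <- names(psd_parent)[psd_parent == sid]
    psd <- 0
    perf <- FALSE
    if (length(pid)) {
      pidx <- by_object[[pid[1L]]]
      if (!is.null(pidx)) {
        traces <- lapply(series$contours[pidx], `[[`, "points")
        psd <- psd_area(traces, t_um)
        perf <- detect_perforation(traces, sec_of[pidx])
      }
    }

    # neck: explicit trace wins, else anchor surrogate against the parent shaft
    nid <- names(neck_parent)[neck_parent == sid]
    shaft <- shafts[[parent_of[[sid]]]]
    if (length(nid) && !is.null(by_object[[nid[1L]]])) {
      nidx <- by_object[[nid[1L]]]
      nord <- order(sec_of[nidx])
      pts3 <- do.call(rbind, lapply(nidx[nord], function(j) {
        ct <- series$contours[[j]]
        cbind(ct$points, ct$section * t_um)
      }))
      neck <- if (nrow(pts3) >= 2L) neck_length(pts3) else NA_real_
    } else if (!is.null(shaft)) {
      near <- which.min(abs(shaft$axis[, 3] - head_center[3]))
      neck <- neck_length_from_anchors(head_center, head_radius, shaft$axis,
                                       shaft$radii[near])
    } else {
      neck <- NA_real_
    }

    touches <- min(secs) == 0L || max(secs) == (md$n_sections - 1L)
    tibble::tibble(
      spine_id = sid, dendrite_id = parent_of[[sid]],
      head_volume_um3 = vol, surface_area_um2 = surf,
      neck_length_um = neck, psd_area_um2 = psd, perforated = perf,
      size_class = classify_size(vol, config$size_cutoff),
      touches_boundary = touches, n_head_sections = length(idx)
    )
  })
  spines <- dplyr::bind_rows(rows)

  dendrites <- dplyr::bind_rows(lapply(shaft_ids, function(sid) {
    n_sp <- if (nrow(spines)) sum(spines$dendrite_id == sid) else 0L
    tibble::tibble(dendrite_id = sid,
                   path_length_um = shafts[[sid]]$length,
                   n_spines = n_sp,
                   spine_density_per_um = spine_density(n_sp, shafts[[sid]]$length))
  }))
  list(spines = spines, dendrites = dendrites)
}

#' Measure every series of a generated/traced dataset
#'
#' Loads each series named by the manifest, measures it, and attaches the
#' group labels.
#'
#' @param dir dataset directory containing series files and `manifest.csv`
#'   (or supply `manifest`).
#' @param config a [morphometry_config()]; its `boundary_policy` decides
#'   whether boundary-touching spines are kept in the tables.
#' @param manifest optional manifest tibble (`file`, `genotype`,
#'   `age_months`, `dendrite_id`).
#' @return list of tibbles `spines` and `dendrites` with group columns.
#' @export
measure_dataset <- function(dir, config = morphometry_config(), manifest = NULL) {
  if (is.null(manifest)) {
    mpath <- file.path(dir, "manifest.csv")
    if (!file.exists(mpath)) stop_io(sprintf("no manifest.csv in '%s'", dir))
    manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  }
  if (!nrow(manifest)) stop_io("empty manifest: no series files to measure")
  sp <- list()
  dd <- list()
  for (i in seq_len(nrow(manifest))) {
    series <- load_series(file.path(dir, manifest$file[i]), check_geometry = FALSE)
    m <- measure_series(series, config)
    m$spines$genotype <- manifest$genotype[i]
    m$spines$age_months <- manifest$age_months[i]
    m$dendrites$genotype <- manifest$genotype[i]
    m$dendrites$age_months <- manifest$age_months[i]
    sp[[i]] <- m$spines
    dd[[i]] <- m$dendrites
  }
  spines <- dplyr::bind_rows(sp)
  if (config$boundary_policy == "exclude_touching" && nrow(spines)) {
    spines <- spines[!spines$touches_boundary, , drop = FALSE]
  }
  list(spines = spines, dendrites = dplyr::bind_rows(dd))
}
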