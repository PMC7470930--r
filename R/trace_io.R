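# Serial-section trace data model and its JSON/CSV interfaces.
#
# On disk, contour coordinates are stored in pixels and converted to
# micrometres on load via metadata$pixel_size_nm; z of section k is
# k * section_thickness. In memory everything is in micrometres.

OBJECT_KINDS <- c("shaft", "spine_head", "spine_neck", "psd")

#' Series metadata constructor
#'
#' @param pixel_size_nm lateral calibration, nanometres per pixel (> 0).
#' @param section_thickness_nm milling increment / section thickness in
#'   nanometres (> 0).
#' @param n_sections number of sections in the stack (>= 1).
#' @param source_id free-text identifier of the imaging run or dendrite.
#' @return a `series_metadata` list.
#' @export
series_metadata <- function(pixel_size_nm, section_thickness_nm, n_sections,
                            source_id = "") {
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    stop_validation("pixel_size_nm must be positive")
  }
  if (!is.numeric(section_thickness_nm) || section_thickness_nm <= 0) {
    stop_validation("section_thickness_nm must be positive")
  }
  if (!is.numeric(n_sections) || n_sections < 1 || n_sections != round(n_sections)) {
    stop_validation("n_sections must be an integer >= 1")
  }
  structure(list(pixel_size_nm = as.numeric(pixel_size_nm),
                 section_thickness_nm = as.numeric(section_thickness_nm),
                 n_sections = as.integer(n_sections),
                 source_id = as.character(source_id)),
            class = "series_metadata")
}

#' Contour constructor
#'
#' @param section 0-based section index.
#' @param object_id identifier of the traced object.
#' @param points n x 2 matrix of (x, y) coordinates in micrometres.
#' @param closed `TRUE` for closed outlines (shaft, spine head), `FALSE` for
#'   open traces (PSD, neck path).
#' @return a `contour` list.
#' @export
contour <- function(section, object_id, points, closed = TRUE) {
  structure(list(section = as.integer(section),
                 object_id = as.character(object_id),
                 closed = isTRUE(closed),
                 points = as_xy(points)),
            class = "contour")
}

#' Assemble a spine series
#'
#' @param metadata a [series_metadata()] object.
#' @param contours list of [contour()] objects.
#' @param hierarchy data frame with columns `id`, `kind`
#'   (shaft/spine_head/spine_neck/psd) and `parent_id` (`NA` for dendrites).
#' @param validate run [validate_series()] (default `TRUE`).
#' @return a `spine_series` list.
#' @export
spine_series <- function(metadata, contours, hierarchy, validate = TRUE) {
  hierarchy <- as.data.frame(hierarchy, stringsAsFactors = FALSE)
  hierarchy$id <- as.character(hierarchy$id)
  hierarchy$kind <- as.character(hierarchy$kind)
  hierarchy$parent_id <- as.character(hierarchy$parent_id)
  s <- structure(list(metadata = metadata, contours = contours, hierarchy = hierarchy),
                 class = "spine_series")
  if (validate) validate_series(s)
  s
}

#' Validate a spine series
#'
#' Checks metadata positivity, contour well-formedness (closed contours simple
#' with >= 3 points, open traces with >= 2 points, section indices inside the
#' stack), object kinds, parent links (spine head -> shaft, PSD -> spine head,
#' neck -> spine head, at most one neck per spine) and absence of reference
#' cycles. Raises a classed validation error naming the offending id.
#'
#' @param series a `spine_series`.
#' @param check_geometry also test closed contours for self-intersection
#'   (default `TRUE`).
#' @return the series, invisibly.
#' @export
validate_series <- function(series, check_geometry = TRUE) {
  md <- series$metadata
  if (!inherits(md, "series_metadata")) {
    md <- do.call(series_metadata, md[c("pixel_size_nm", "section_thickness_nm",
                                        "n_sections", "source_id")])
  }
  h <- series$hierarchy
  if (anyDuplicated(h$id)) {
    stop_validation(sprintf("duplicate object id '%s'", h$id[duplicated(h$id)][1L]))
  }
  bad_kind <- setdiff(unique(h$kind), OBJECT_KINDS)
  if (length(bad_kind)) stop_validation(sprintf("unknown object kind '%s'", bad_kind[1L]))
  kind_of <- stats::setNames(h$kind, h$id)
  parent_of <- stats::setNames(h$parent_id, h$id)
  for (i in seq_len(nrow(h))) {
    id <- h$id[i]; kind <- h$kind[i]; parent <- h$parent_id[i]
    if (kind == "shaft") {
      if (!is.na(parent) && nzchar(parent)) {
        stop_validation(sprintf("shaft '%s' must not have a parent", id))
      }
      next
    }
    if (is.na(parent) || !nzchar(parent)) {
      stop_validation(sprintf("%s '%s' has no parent", kind, id))
    }
    if (!parent %in% h$id) {
      stop_validation(sprintf("%s '%s' references missing parent '%s'", kind, id, parent))
    }
    want <- if (kind == "spine_head") "shaft" else "spine_head"
    if (kind_of[[parent]] != want) {
      stop_validation(sprintf("%s '%s' must attach to a %s, not '%s'",
                              kind, id, want, kind_of[[parent]]))
    }
  }
  # cycle check on the parent map
  for (id in h$id) {
    seen <- character()
    cur <- id
    while (!is.na(parent_of[cur]) && nzchar(parent_of[cur])) {
      if (cur %in% seen) stop_validation(sprintf("hierarchy cycle involving '%s'", id))
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
      if (!cur %in% h$id) break
    }
  }
  necks <- h$id[h$kind == "spine_neck"]
  if (length(necks)) {
    np <- parent_of[necks]
    if (anyDuplicated(np)) {
      stop_validation(sprintf("spine '%s' has more than one neck trace",
                              np[duplicated(np)][1L]))
    }
  }
  for (ct in series$contours) {
    if (ct$section < 0L || ct$section >= md$n_sections) {
      stop_validation(sprintf("contour of '%s' has section %d outside 0..%d",
                              ct$object_id, ct$section, md$n_sections - 1L))
    }
    if (!ct$object_id %in% h$id) {
      stop_validation(sprintf("contour references unknown object '%s'", ct$object_id))
    }
    npts <- nrow(ct$points)
    if (ct$closed) {
      if (npts < 3L) {
        stop_validation(sprintf("closed contour of '%s' has %d < 3 points",
                                ct$object_id, npts))
      }
      if (check_geometry && !is_simple_polygon(ct$points)) {
        stop_validation(sprintf("closed contour of '%s' (section %d) self-intersects",
                                ct$object_id, ct$section))
      }
    } else if (npts < 2L) {
      stop_validation(sprintf("open trace of '%s' has %d < 2 points", ct$object_id, npts))
    }
  }
  invisible(series)
}

#' Read a spine series from its JSON file
#'
#' Coordinates are converted from pixels to micrometres with the stored pixel
#' size. The loaded series is validated.
#'
#' @param path path to a series JSON file.
#' @param check_geometry passed to [validate_series()].
#' @return a validated `spine_series`.
#' @export
load_series <- function(path, check_geometry = TRUE) {
  if (!file.exists(path)) stop_io(sprintf("series file '%s' does not exist", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop_io(sprintf("malformed JSON in '%s': %s",
                                                      path, conditionMessage(e))))
  for (key in c("metadata", "objects", "contours")) {
    if (is.null(raw[[key]])) stop_validation(sprintf("series file missing '%s'", key))
  }
  m <- raw$metadata
  md <- series_metadata(m$pixel_size_nm, m$section_thickness_nm, m$n_sections,
                        if (is.null(m$source_id)) "" else m$source_id)
  um_per_px <- md$pixel_size_nm / 1000
  hierarchy <- data.frame(
    id = vapply(raw$objects, function(o) as.character(o$id), character(1)),
    kind = vapply(raw$objects, function(o) as.character(o$kind), character(1)),
    parent_id = vapply(raw$objects, function(o) {
      if (length(o$parent_id) != 1L) NA_character_ else as.character(o$parent_id)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  contours <- lapply(raw$contours, function(ct) {
    pts <- do.call(rbind, lapply(ct$points, function(p) c(p[[1]], p[[2]])))
    contour(ct$section, ct$object_id, pts * um_per_px, isTRUE(ct$closed))
  })
  s <- spine_series(md, contours, hierarchy, validate = FALSE)
  validate_series(s, check_geometry = check_geometry)
  s
}

#' Write a spine series to JSON
#'
#' Inverse of [load_series()]: coordinates are stored in pixels; a load of the
#' written file reproduces the series (round-trip identity at numerical
#' precision).
#'
#' @param series a `spine_series` (validated before writing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  validate_series(series, check_geometry = FALSE)
  md <- series$metadata
  px_per_um <- 1000 / md$pixel_size_nm
  payload <- list(
    metadata = list(pixel_size_nm = md$pixel_size_nm,
                    section_thickness_nm = md$section_thickness_nm,
                    n_sections = md$n_sections,
                    source_id = md$source_id),
    objects = lapply(seq_len(nrow(series$hierarchy)), function(i) {
      o <- series$hierarchy[i, ]
      if (is.na(o$parent_id)) list(id = o$id, kind = o$kind)
      else list(id = o$id, kind = o$kind, parent_id = o$parent_id)
    }),
    contours = lapply(series$contours, function(ct) {
      list(section = ct$section, object_id = ct$object_id, closed = ct$closed,
           points = unname(apply(ct$points * px_per_um, 1L, function(p) list(p[1], p[2]),
                                 simplify = FALSE)))
    })
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop_io(sprintf("cannot write series to '%s'", path))
  invisible(path)
}

#' Export per-spine and per-dendrite tables to CSV
#'
#' Writes `spines.csv` (one row per spine, all derived metrics plus parent
#' dendrite) and `dendrites.csv` (path length, spine count, density). Numeric
#' columns keep full double precision (>= 6 significant digits).
#'
#' @param spines tibble of spine records as produced by [measure_series()].
#' @param dendrites tibble of dendrite records.
#' @param dir output directory (created if missing).
#' @return named character vector of the two file paths, invisibly.
#' @export
export_spine_table <- function(spines, dendrites, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(spines) == 0L) warning("no spine records: writing header-only CSV", call. = FALSE)
  spine_cols <- c("spine_id", "dendrite_id", "head_volume_um3", "surface_area_um2",
                  "neck_length_um", "psd_area_um2", "perforated", "size_class",
                  "touches_boundary")
  dend_cols <- c("dendrite_id", "path_length_um", "n_spines", "spine_density_per_um")
  sp <- as.data.frame(spines)[, intersect(spine_cols, colnames(spines)), drop = FALSE]
  dd <- as.data.frame(dendrites)[, intersect(dend_cols, colnames(dendrites)), drop = FALSE]
  paths <- c(spines = file.path(dir, "spines.csv"),
             dendrites = file.path(dir, "dendrites.csv"))
  utils::write.csv(sp, paths[["spines"]], row.names = FALSE)
  utils::write.csv(dd, paths[["dendrites"]], row.names = FALSE)
  invisible(paths)
}
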