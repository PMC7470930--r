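# End-to-end orchestration: generate (or read) a dataset, measure it,
# classify, run the statistical battery, and write the report bundle.

#' Run configuration
#'
#' @param input directory of series files + manifest, or `NULL` to generate
#'   from `preset`.
#' @param preset name of a generator preset (`"striatal_msn_aging"`) or a list
#'   of [synth_group_config()] objects.
#' @param out_dir output directory.
#' @param size_cutoff small/large head-volume cutoff, um^3 (default 0.04).
#' @param bin_width histogram bin width, um^3 (default 0.04).
#' @param alpha significance level for the battery (default 0.05), in (0,1).
#' @param boundary_policy see [morphometry_config()].
#' @param seed master seed for generation.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, preset = "striatal_msn_aging",
                       out_dir = "spinemorph_out", size_cutoff = 0.04,
                       bin_width = 0.04, alpha = 0.05,
                       boundary_policy = "exclude_touching", seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0,1)")
  if (size_cutoff <= 0 || bin_width <= 0) {
    stop_validation("size_cutoff and bin_width must be positive")
  }
  structure(list(input = input, preset = preset, out_dir = out_dir,
                 size_cutoff = size_cutoff, bin_width = bin_width, alpha = alpha,
                 boundary_policy = boundary_policy, seed = as.integer(seed)),
            class = "run_config")
}

resolve_preset <- function(preset) {
  if (is.character(preset)) {
    if (!identical(preset, "striatal_msn_aging")) {
      stop_validation(sprintf("unknown preset '%s'", preset))
    }
    striatal_msn_presets()
  } else {
    preset
  }
}

group_key <- function(genotype, age_months) paste0(genotype, "_", age_months, "mo")

#' Full analysis of a spine dataset
#'
#' Sequences generation (when no input directory is given), measurement,
#' classification and the statistical battery, and writes `spines.csv`,
#' `dendrites.csv`, `frequency_tables.csv`, `histogram.csv`,
#' `stats_report.json`, a human-readable `summary.txt` and `run.log` into the
#' output directory.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `spines`, `dendrites`, `frequency_tables`,
#'   `summaries`, `stats`, `paths`.
#' @export
run_full_analysis <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("spinemorph %s", as.character(utils::packageVersion("spinemorph"))),
                 sprintf("seed: %d", config$seed), sprintf("start: %s", Sys.time()))
  if (is.null(config$input)) {
    gen_dir <- file.path(config$out_dir, "traces")
    gen <- suppressWarnings(
      generate_dataset(resolve_preset(config$preset), gen_dir, seed = config$seed))
    input <- gen_dir
    log_lines <- c(log_lines,
                   sprintf("generated %d series files", nrow(gen$manifest)))
  } else {
    input <- config$input
    if (!dir.exists(input)) stop_io(sprintf("input directory '%s' does not exist", input))
  }
  mcfg <- morphometry_config(size_cutoff = config$size_cutoff,
                             boundary_policy = config$boundary_policy)
  meas <- measure_dataset(input, mcfg)
  spines <- meas$spines
  dendrites <- meas$dendrites
  if (!nrow(spines)) stop_io("no spines measured: nothing to analyze")

  export_spine_table(spines, dendrites, config$out_dir)
  spines$group <- group_key(spines$genotype, spines$age_months)
  dendrites$group <- group_key(dendrites$genotype, dendrites$age_months)

  freq <- dplyr::bind_rows(lapply(split(spines, spines$group), function(g) {
    frequency_table(g$size_class, g$perforated, g$genotype[1L], g$age_months[1L])
  }))
  utils::write.csv(freq, file.path(config$out_dir, "frequency_tables.csv"),
                   row.names = FALSE)

  hist_rows <- dplyr::bind_rows(lapply(split(spines, spines$group), function(g) {
    hb <- bin_volumes(g$head_volume_um3, config$bin_width)
    hb$genotype <- g$genotype[1L]
    hb$age_months <- g$age_months[1L]
    hb
  }))
  utils::write.csv(hist_rows, file.path(config$out_dir, "histogram.csv"),
                   row.names = FALSE)

  stats_rep <- analyze_spine_table(spines, dendrites, alpha = config$alpha,
                                   bin_width = config$bin_width,
                                   cutoff = config$size_cutoff)
  jsonlite::write_json(stats_rep$json, file.path(config$out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (nrow(stats_rep$pairwise_csv)) {
    utils::write.csv(stats_rep$pairwise_csv,
                     file.path(config$out_dir, "pairwise_comparisons.csv"),
                     row.names = FALSE)
  }

  summaries <- stats_rep$summaries
  txt <- c(sprintf("spinemorph analysis: %d dendrites, %d spines, %d groups",
                   nrow(dendrites), nrow(spines), length(unique(spines$group))), "")
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    txt <- c(txt, sprintf(
      "%s %smo %s: %.3g ± %.3g (median = %.3g, range = %.3g–%.3g, n = %d)",
      s$genotype, s$age_months, s$metric, s$mean, s$sem, s$median, s$min, s$max, s$n))
  }
  txt <- c(txt, "", report_frequencies(freq))
  writeLines(txt, file.path(config$out_dir, "summary.txt"))
  log_lines <- c(log_lines,
                 sprintf("measured %d dendrites / %d spines", nrow(dendrites), nrow(spines)),
                 sprintf("end: %s", Sys.time()))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(spines = spines, dendrites = dendrites, frequency_tables = freq,
                 summaries = summaries, stats = stats_rep, histogram = hist_rows,
                 paths = config$out_dir))
}

#' Statistical battery over the measured tables
#'
#' Per metric and genotype: per-group descriptives and the gated multi-group
#' comparison across ages (spines are the unit for head volume, neck length
#' and PSD area; dendrites for spine density); WT-vs-mutant two-sample
#' comparisons at matching ages; the large-spine head-volume KS comparison
#' between the two oldest ages per genotype; Spearman PSD-vs-volume
#' correlation per group.
#'
#' @param spines,dendrites measured tables with `genotype`/`age_months`.
#' @param alpha normality-gate level.
#' @param bin_width histogram bin width (recorded in the report).
#' @param cutoff size cutoff used for the large-spine KS subset.
#' @return list with `json` (nested report), `summaries`, `pairwise_csv`.
#' @export
analyze_spine_table <- function(spines, dendrites, alpha = 0.05, bin_width = 0.04,
                                cutoff = 0.04) {
  metrics <- list(
    head_volume = list(data = spines, col = "head_volume_um3", unit = "spine"),
    neck_length = list(data = spines, col = "neck_length_um", unit = "spine"),
    psd_area = list(data = spines, col = "psd_area_um2", unit = "spine"),
    spine_density = list(data = dendrites, col = "spine_density_per_um",
                         unit = "dendrite")
  )
  summaries <- list()
  report <- list(alpha = alpha, bin_width = bin_width, size_cutoff = cutoff)
  pairwise_csv <- list()

  stat_to_list <- function(st) {
    out <- list(test = st$test_name, statistic = st$statistic, p_value = st$p_value)
    if (!is.null(st$pairwise)) out$pairwise <- st$pairwise
    out
  }

  for (mname in names(metrics)) {
    m <- metrics[[mname]]
    df <- m$data
    vals <- df[[m$col]]
    keep <- !is.na(vals)
    df <- df[keep, , drop = FALSE]
    vals <- vals[keep]
    entry <- list(unit = m$unit)
    for (gt in unique(df$genotype)) {
      sub <- df[df$genotype == gt, , drop = FALSE]
      ages <- sort(unique(sub$age_months))
      for (a in ages) {
        summaries[[length(summaries) + 1L]] <-
          summarize_metric(sub[[m$col]][sub$age_months == a], gt, a, mname)
      }
      if (length(ages) >= 3L) {
        groups <- lapply(ages, function(a) sub[[m$col]][sub$age_months == a])
        cm <- compare_many(groups, labels = paste0(ages, "mo"), alpha_normality = alpha)
        entry[[paste0(gt, "_across_ages")]] <- stat_to_list(cm)
        pw <- cm$pairwise
        pw$metric <- mname
        pw$genotype <- gt
        pw$omnibus <- cm$test_name
        pairwise_csv[[length(pairwise_csv) + 1L]] <- pw
      }
    }
    gts <- unique(df$genotype)
    if (length(gts) == 2L) {
      for (a in sort(unique(df$age_months))) {
        x <- df[[m$col]][df$genotype == gts[1L] & df$age_months == a]
        y <- df[[m$col]][df$genotype == gts[2L] & df$age_months == a]
        if (length(x) >= 3L && length(y) >= 3L) {
          entry[[sprintf("%s_vs_%s_%smo", gts[1L], gts[2L], a)]] <-
            stat_to_list(compare_two(x, y, labels = gts, alpha_normality = alpha))
        }
      }
    }
    report[[mname]] <- entry
  }

  # distribution shift of large (mushroom-type) spine head volumes between the
  # two oldest ages, per genotype
  for (gt in unique(spines$genotype)) {
    sub <- spines[spines$genotype == gt & spines$size_class == "large", , drop = FALSE]
    ages <- sort(unique(sub$age_months))
    if (length(ages) >= 2L) {
      a1 <- ages[length(ages) - 1L]
      a2 <- ages[length(ages)]
      x <- sub$head_volume_um3[sub$age_months == a1]
      y <- sub$head_volume_um3[sub$age_months == a2]
      if (length(x) && length(y)) {
        report[[sprintf("large_spine_volume_ks_%s_%svs%smo", gt, a2, a1)]] <-
          stat_to_list(ks_two_sample(x, y, labels = paste0(c(a1, a2), "mo")))
      }
    }
  }

  # PSD area vs head volume, per group
  corr <- list()
  for (key in unique(group_key(spines$genotype, spines$age_months))) {
    sub <- spines[group_key(spines$genotype, spines$age_months) == key, , drop = FALSE]
    if (nrow(sub) >= 4L) {
      sc <- spearman_corr(sub$head_volume_um3, sub$psd_area_um2)
      corr[[key]] <- list(r = sc$statistic, p_value = sc$p_value, n = nrow(sub))
    }
  }
  report$psd_volume_spearman <- corr

  summaries <- dplyr::bind_rows(summaries)
  report$group_summaries <- summaries
  list(json = report, summaries = summaries,
       pairwise_csv = dplyr::bind_rows(pairwise_csv))
}

#' Formatted frequency report with fold-change block
#'
#' Per-group small/large/perforated percentages (one decimal) and, per
#' genotype, the perforation fold change of every older-vs-younger age pair
#' (two decimals). A single group yields no fold block.
#'
#' @param tables frequency tibble from [frequency_table()] rows.
#' @return character vector of report lines.
#' @export
report_frequencies <- function(tables) {
  if (!nrow(tables)) stop_validation("no frequency tables to report")
  lines <- c("Relative frequencies (% of spines):")
  for (i in seq_len(nrow(tables))) {
    g <- tables[i, ]
    lines <- c(lines, sprintf(
      "  %s %smo: small %.1f%% (n = %d/%d), large %.1f%%, perforated %.1f%%",
      g$genotype, g$age_months, g$pct_small, g$n_small, g$n_total,
      g$pct_large, g$pct_perforated))
  }
  for (gt in unique(tables$genotype)) {
    sub <- tables[tables$genotype == gt, , drop = FALSE]
    sub <- sub[order(sub$age_months), , drop = FALSE]
    if (nrow(sub) < 2L) next
    lines <- c(lines, sprintf("Perforation fold changes, %s:", gt))
    for (j in seq_len(nrow(sub) - 1L)) {
      for (i in seq.int(j + 1L, nrow(sub))) {
        if (sub$pct_perforated[j] <= 0) next
        lines <- c(lines, sprintf(
          "  %smo vs %smo: %.2f-fold",
          sub$age_months[i], sub$age_months[j],
          fold_change(sub$pct_perforated[i], sub$pct_perforated[j])))
      }
    }
  }
  lines
}
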