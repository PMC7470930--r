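# Reference group parameters: a FIB/SEM survey of medium spiny neuron
# dendrites in the dorsolateral striatum of wild-type (WT) and A53T-BAC-SNCA
# mice at 1, 3, 6 and 22 months. These printed group summaries are both the
# bookkeeping reference (counts, frequencies, fold changes) and the generative
# parameters of the synthetic-data presets. Spreads are given as SEM in the
# source; the generator needs sd, recovered as sd = SEM * sqrt(n).

#' Reference per-group counts and summaries for the striatal MSN aging survey
#'
#' One row per (genotype, age) group: dendrite/spine counts, printed
#' small/large spine counts where available (small counts were not reported
#' for the A53T 1-month group), perforation percentages, and the group means
#' that parameterize the synthetic presets. Units: lengths um, volumes um^3,
#' densities spines/um.
#'
#' @return tibble with 8 rows.
#' @export
striatal_msn_counts <- function() {
  tibble::tibble(
    genotype = rep(c("WT", "A53T"), each = 4L),
    age_months = rep(c(1L, 3L, 6L, 22L), 2L),
    n_dendrites = c(7L, 8L, 7L, 11L, 7L, 8L, 7L, 10L),
    n_spines = c(132L, 177L, 109L, 156L, 148L, 251L, 151L, 161L),
    n_small = c(96L, 86L, 49L, 69L, NA, 145L, 92L, 93L),
    n_large = c(36L, 91L, 60L, 87L, NA, 106L, 59L, 68L),
    pct_perforated = c(1.52, 4.52, 6.42, 21.15, 2.70, 9.96, 5.96, 9.94),
    dendrite_length_mean = c(9.2, 12.4, 11.8, 13.4, 8.7, 13.8, 11.0, 11.7),
    dendrite_length_sem = c(0.61, 0.52, 0.85, 0.83, 0.75, 1.20, 0.72, 1.49),
    spine_density_mean = c(2.0, 1.8, 1.3, 1.1, 2.5, 2.4, 2.0, 1.4),
    spine_density_sem = c(0.14, 0.17, 0.14, 0.06, 0.22, 0.21, 0.14, 0.21),
    head_volume_mean = c(0.050, 0.074, 0.084, 0.143, 0.077, 0.089, 0.088, 0.089),
    head_volume_median = c(0.027, 0.041, 0.045, 0.047, 0.042, 0.032, 0.028, 0.030),
    neck_length_mean = c(1.00, 1.13, 0.98, 1.03, 1.14, 1.11, 1.21, 1.11),
    neck_length_sem = c(0.045, 0.043, 0.054, 0.043, 0.047, 0.036, 0.052, 0.045)
  )
}

#' Synthetic-data presets matched to the striatal MSN aging survey
#'
#' Builds one [synth_group_config()] per (genotype, age) group from
#' [striatal_msn_counts()]: lognormal head volumes moment-matched to the
#' printed mean and median, truncated-normal neck lengths, Poisson spine
#' counts at the printed density, linear PSD-area coupling, and a
#' volume-dependent perforation model calibrated so the expected perforation
#' rate equals the printed group percentage.
#'
#' @param section_thickness_nm milling increment (default 50 nm, within the
#'   40-50 nm acquisition range).
#' @param pixel_size_nm lateral calibration (default 4.5 nm/pixel).
#' @return named list of 8 `synth_group_config` objects
#'   (names `"WT_1mo"`, ..., `"A53T_22mo"`).
#' @export
striatal_msn_presets <- function(section_thickness_nm = 50, pixel_size_nm = 4.5) {
  counts <- striatal_msn_counts()
  cfgs <- lapply(seq_len(nrow(counts)), function(i) {
    g <- counts[i, ]
    synth_group_config(
      genotype = g$genotype,
      age_months = g$age_months,
      n_dendrites = g$n_dendrites,
      dendrite_length_mean = g$dendrite_length_mean,
      dendrite_length_sd = g$dendrite_length_sem * sqrt(g$n_dendrites),
      spine_density = g$spine_density_mean,
      head_volume_mean = g$head_volume_mean,
      head_volume_median = g$head_volume_median,
      neck_length_mean = g$neck_length_mean,
      neck_length_sd = g$neck_length_sem * sqrt(g$n_spines),
      perforation_rate = g$pct_perforated / 100,
      section_thickness_nm = section_thickness_nm,
      pixel_size_nm = pixel_size_nm
    )
  })
  names(cfgs) <- paste0(counts$genotype, "_", counts$age_months, "mo")
  cfgs
}
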