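# Categorical spine analyses: small/large (thin/mushroom) size classes by a
# head-volume cutoff, macular/perforated PSD types by trace topology, binned
# head-volume distributions, relative frequencies and fold changes.

#' Classify a spine as small or large by head volume
#'
#' Spines are split at a head-volume cutoff (default 0.04 um^3, roughly the
#' median head volume of adult wild-type striatal spines). "Small" corresponds
#' to thin-type and "large" to mushroom-type spines. The boundary is ambiguous
#' in the source convention (printed small ranges end at 0.040 and one large
#' range starts at 0.040); here volume <= cutoff is deterministically "small".
#'
#' @param head_volume spine head volume(s), cubic micrometres (> 0).
#' @param cutoff size cutoff in cubic micrometres (default 0.04).
#' @return character vector, `"small"` or `"large"`.
#' @export
classify_size <- function(head_volume, cutoff = 0.04) {
  if (!is.numeric(head_volume) || any(head_volume <= 0)) {
    stop_validation("head_volume must be positive")
  }
  if (cutoff <= 0) stop_validation("cutoff must be positive")
  ifelse(head_volume <= cutoff, "small", "large")
}

#' Detect a perforated PSD from its traces
#'
#' A PSD is perforated (as opposed to macular) when it shows a discontinuity:
#' either some section contains two or more disjoint traces of the same
#' synapse, or a trace closes on itself enclosing an untraced hole (the
#' doughnut-shaped PSD). With no traces the PSD is reported macular with a
#' warning.
#'
#' @param traces list of open-trace point matrices (micrometres).
#' @param sections 0-based section index per trace.
#' @param ring_tol endpoint-coincidence tolerance (micrometres) for the
#'   closed-ring test (default 1e-6).
#' @return logical: `TRUE` if perforated.
#' @export
detect_perforation <- function(traces, sections, ring_tol = 1e-6) {
  if (!length(traces)) {
    warning("synapse has no PSD traces: reported as macular", call. = FALSE)
    return(FALSE)
  }
  if (length(traces) != length(sections)) {
    stop_validation("traces and sections must have equal length")
  }
  if (any(tabulate(sections - min(sections) + 1L) >= 2L)) return(TRUE)
  for (tr in traces) {
    m <- as_xy(tr, "PSD trace")
    n <- nrow(m)
    if (n >= 4L && sqrt(sum((m[1L, ] - m[n, ])^2)) <= ring_tol &&
        contour_area(m, check = FALSE) > 0) {
      return(TRUE)
    }
  }
  FALSE
}

#' Relative frequency as a percentage
#'
#' @param n class count.
#' @param n_total total count (> 0).
#' @param digits decimals to report (default 1, half-up rounding).
#' @return percentage, `100 * n / n_total`.
#' @export
relative_frequency <- function(n, n_total, digits = 1) {
  if (any(n_total <= 0)) stop_validation("n_total must be positive")
  if (any(n < 0) || any(n > n_total)) stop_validation("n must lie in [0, n_total]")
  round_half_up(100 * n / n_total, digits)
}

#' Fold change between two percentages
#'
#' @param p_a numerator percentage.
#' @param p_b denominator percentage (> 0).
#' @param digits decimals to report (default 2, half-up rounding).
#' @return ratio `p_a / p_b`.
#' @export
fold_change <- function(p_a, p_b, digits = 2) {
  if (any(p_b <= 0)) stop_validation("denominator percentage must be positive")
  round_half_up(p_a / p_b, digits)
}

#' Frequency table of size classes and perforation for one group
#'
#' @param size_class character vector of `"small"`/`"large"`.
#' @param perforated logical vector, same length.
#' @param genotype,age_months group labels.
#' @return one-row tibble with counts and percentages; invariant
#'   `n_small + n_large = n_total`.
#' @export
frequency_table <- function(size_class, perforated, genotype = NA, age_months = NA) {
  if (!length(size_class)) stop_validation("empty group")
  if (length(size_class) != length(perforated)) {
    stop_validation("size_class and perforated must have equal length")
  }
  n_total <- length(size_class)
  n_small <- sum(size_class == "small")
  n_large <- sum(size_class == "large")
  stopifnot(n_small + n_large == n_total)
  tibble::tibble(
    genotype = genotype, age_months = age_months, n_total = n_total,
    n_small = n_small, n_large = n_large, n_perforated = sum(perforated),
    pct_small = relative_frequency(n_small, n_total),
    pct_large = relative_frequency(n_large, n_total),
    pct_perforated = relative_frequency(sum(perforated), n_total)
  )
}

#' Bin head volumes into a relative-frequency histogram
#'
#' Left-closed, right-open bins of fixed width starting at zero, matching the
#' binned head-volume distributions used to compare mushroom-type spines
#' between ages.
#'
#' @param volumes head volumes, cubic micrometres.
#' @param bin_width bin width in cubic micrometres (default 0.04).
#' @return tibble with `bin_lo`, `bin_hi`, `count`, `rel_freq`
#'   (frequencies sum to 1).
#' @export
bin_volumes <- function(volumes, bin_width = 0.04) {
  if (!length(volumes)) stop_validation("empty volume list")
  if (bin_width <= 0) stop_validation("bin_width must be positive")
  if (any(volumes < 0)) stop_validation("volumes must be nonnegative")
  idx <- floor(volumes / bin_width)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  k <- seq_along(counts) - 1L
  tibble::tibble(bin_lo = k * bin_width, bin_hi = (k + 1L) * bin_width,
                 count = counts, rel_freq = counts / length(volumes))
}
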