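# Normality-gated statistical battery for group comparisons.
#
# Two samples: Shapiro-Wilk on each sample; both normal -> Student's t,
# otherwise Mann-Whitney U. Three or more groups: all groups normal -> one-way
# ANOVA with pooled-variance pairwise t tests, otherwise Kruskal-Wallis with
# Dunn rank tests; pairwise p-values Bonferroni-adjusted and capped at 1
# (which is why equal groups report p = 1.00). Distribution shifts use the
# asymptotic two-sample Kolmogorov-Smirnov test, correlations Spearman's rank
# order test with midranks.

new_stat_result <- function(test_name, statistic, p_value, groups, pairwise = NULL,
                            normality = NULL) {
  structure(list(test_name = test_name,
                 statistic = unname(statistic),
                 p_value = unname(p_value),
                 groups = groups,
                 pairwise = pairwise,
                 normality = normality),
            class = "spine_stat")
}

#' @export
print.spine_stat <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test_name, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Bonferroni-adjusted):\n")
    print(as.data.frame(x$pairwise), ...)
  }
  invisible(x)
}

shapiro_passes <- function(x, alpha) {
  # constant samples (Shapiro-Wilk undefined) are treated as non-normal
  if (length(unique(x)) < 2L) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

#' Descriptive summary of one metric in one group
#'
#' Mean, SEM (sample sd over sqrt(n)), median and range, the "mean +- SEM
#' (median = ..., range = ...)" descriptives used for every group-level metric.
#'
#' @param values numeric vector (nonempty).
#' @param genotype,age_months,metric optional labels carried into the row.
#' @return one-row tibble (`n`, `mean`, `sem`, `median`, `min`, `max`).
#' @export
summarize_metric <- function(values, genotype = NA, age_months = NA, metric = NA) {
  if (!length(values)) stop_stat("cannot summarize an empty sample")
  if (anyNA(values)) values <- values[!is.na(values)]
  if (!length(values)) stop_stat("cannot summarize an all-NA sample")
  n <- length(values)
  sem <- if (n == 1L) {
    message("single observation: SEM reported as 0 by convention")
    0
  } else {
    stats::sd(values) / sqrt(n)
  }
  tibble::tibble(genotype = genotype, age_months = age_months, metric = metric,
                 n = n, mean = mean(values), sem = sem,
                 median = stats::median(values), min = min(values), max = max(values))
}

#' Two-sample comparison with a normality gate
#'
#' Shapiro-Wilk is applied to each sample at `alpha_normality`; if both pass, a
#' two-sided Student's t test (equal variances) is used, otherwise a two-sided
#' Mann-Whitney U test. The result records which path was taken.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param labels length-2 character group labels.
#' @param alpha_normality significance level of the normality gate (default
#'   0.05).
#' @return a `spine_stat` with `test_name` either `"Student's t"` or
#'   `"Mann-Whitney U"`.
#' @export
compare_two <- function(x, y, labels = c("x", "y"), alpha_normality = 0.05) {
  if (length(x) < 3L || length(y) < 3L) {
    stop_stat("each sample needs n >= 3 (Shapiro-Wilk undefined below that)")
  }
  norm <- c(shapiro_passes(x, alpha_normality), shapiro_passes(y, alpha_normality))
  if (all(norm)) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    res <- new_stat_result("Student's t", ht$statistic, ht$p.value, labels)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    res <- new_stat_result("Mann-Whitney U", ht$statistic, min(ht$p.value, 1), labels)
  }
  res$normality <- tibble::tibble(group = labels, normal = norm)
  res
}

# pooled-variance pairwise t tests after one-way ANOVA (SPSS-style Bonferroni
# post hoc: t on the ANOVA mean-square error, df = N - k)
pairwise_pooled_t <- function(values, groups, labels) {
  k <- length(labels)
  n <- tapply(values, groups, length)[labels]
  m <- tapply(values, groups, mean)[labels]
  v <- tapply(values, groups, stats::var)[labels]
  df <- sum(n) - k
  mse <- sum((n - 1) * v) / df
  pairs <- utils::combn(labels, 2L)
  n_pairs <- ncol(pairs)
  out <- lapply(seq_len(n_pairs), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    tt <- (m[[a]] - m[[b]]) / sqrt(mse * (1 / n[[a]] + 1 / n[[b]]))
    p_raw <- 2 * stats::pt(-abs(tt), df)
    tibble::tibble(group_a = a, group_b = b, statistic = tt, p_raw = p_raw)
  })
  out <- do.call(rbind, out)
  out$p_adj <- pmin(out$p_raw * n_pairs, 1)
  out
}

# Dunn rank tests after Kruskal-Wallis, with tie correction and Bonferroni
dunn_pairwise <- function(values, groups, labels) {
  n_tot <- length(values)
  r <- rank(values)
  n <- tapply(r, groups, length)[labels]
  rbar <- tapply(r, groups, mean)[labels]
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  s2 <- n_tot * (n_tot + 1) / 12 - tie_term
  pairs <- utils::combn(labels, 2L)
  n_pairs <- ncol(pairs)
  out <- lapply(seq_len(n_pairs), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt(s2 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    tibble::tibble(group_a = a, group_b = b, statistic = z,
                   p_raw = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, out)
  out$p_adj <- pmin(out$p_raw * n_pairs, 1)
  out
}

#' Multi-group comparison with a normality gate and pairwise post hoc
#'
#' All groups pass Shapiro-Wilk -> one-way ANOVA with pooled-variance pairwise
#' t tests; any group fails -> Kruskal-Wallis with Dunn rank tests. Pairwise
#' p-values are Bonferroni-adjusted and capped at 1.
#'
#' @param groups list of >= 3 numeric samples, each n >= 3.
#' @param labels character labels, one per group.
#' @param alpha_normality normality-gate level (default 0.05).
#' @return a `spine_stat` with omnibus statistic/p and a `pairwise` tibble.
#' @export
compare_many <- function(groups, labels = names(groups), alpha_normality = 0.05) {
  if (length(groups) < 3L) {
    stop_stat("compare_many needs >= 3 groups; use compare_two for two")
  }
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 3L)) stop_stat("each group needs n >= 3")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, integer(1))), levels = labels)
  normal <- vapply(groups, shapiro_passes, logical(1), alpha = alpha_normality)
  if (all(normal)) {
    fit <- stats::anova(stats::lm(values ~ g))
    res <- new_stat_result("one-way ANOVA", fit$`F value`[1L], fit$`Pr(>F)`[1L], labels,
                           pairwise = pairwise_pooled_t(values, g, labels))
  } else {
    ht <- stats::kruskal.test(values, g)
    res <- new_stat_result("Kruskal-Wallis", ht$statistic, ht$p.value, labels,
                           pairwise = dunn_pairwise(values, g, labels))
  }
  res$normality <- tibble::tibble(group = labels, normal = unname(normal))
  res
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided statistic with the asymptotic Smirnov p-value (the "Z test"
#' form), used to compare head-volume distributions between ages.
#'
#' @param x,y numeric samples (each nonempty).
#' @param labels length-2 character labels.
#' @return a `spine_stat`.
#' @export
ks_two_sample <- function(x, y, labels = c("x", "y")) {
  if (!length(x) || !length(y)) stop_stat("KS test needs nonempty samples")
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  new_stat_result("Kolmogorov-Smirnov", ht$statistic, ht$p.value, labels)
}

#' Spearman rank-order correlation
#'
#' Rank correlation with midranks for ties and the asymptotic p-value, used
#' for the PSD-area versus head-volume relation.
#'
#' @param x,y paired numeric samples (n >= 4).
#' @return a `spine_stat`; `statistic` is the correlation r in `[-1, 1]`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop_stat("x and y must be paired")
  if (length(x) < 4L) stop_stat("Spearman correlation needs n >= 4")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop_stat("correlation undefined for constant input")
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  res <- new_stat_result("Spearman rank correlation", ht$estimate, ht$p.value,
                         c("x", "y"))
  res$statistic <- unname(ht$estimate)
  res
}
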