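Package: spinemorph
Title: Serial-Section Dendritic Spine Morphometry and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Morphometric analysis of dendritic spines reconstructed from
    serial-section electron microscopy traces. Computes spine head volume and
    surface area by section planimetry, postsynaptic density (PSD) area from
    per-section trace lengths, spine neck length, dendrite path length and
    spine density; classifies spines into small/large (thin/mushroom) types by
    a head-volume cutoff and PSDs into macular/perforated types by trace
    topology; and runs a normality-gated statistical battery (Student's t /
    Mann-Whitney U, one-way ANOVA / Kruskal-Wallis with Bonferroni-adjusted
    pairwise comparisons, two-sample Kolmogorov-Smirnov, Spearman rank
    correlation) over age and genotype groups. Includes a synthetic
    serial-section dendrite generator with known ground truth so the full
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
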