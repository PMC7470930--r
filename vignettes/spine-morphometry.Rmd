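---
title: "Serial-section spine morphometry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-section spine morphometry: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

## The measurement problem

Serial-section electron microscopy (FIB/SEM and similar block-face methods)
images tissue as an aligned stack of sections tens of nanometres apart.
Dendritic shafts, spine heads and postsynaptic densities (PSDs) are traced as
planar contours, section by section. All downstream biology — spine density,
head volume, neck length, PSD area, the balance of thin vs mushroom spines,
the abundance of perforated synapses — is computed from those contour stacks.
`spinemorph` implements that computation as a reusable, tested pipeline, plus
the group-level statistics used to compare genotypes and ages, plus a
synthetic trace generator so every stage can be validated against known
ground truth without microscopy data.

## Estimators

All estimators follow the serial-section reconstruction convention (the one
used by Reconstruct-style software): per-section planar quantities are
multiplied by the section thickness $t$ and summed.

* **Volume** of a traced solid: $V = \sum_k A_k\, t$, the rectangle rule over
  traced sections ($A_k$ by the shoelace formula, absolute value so traced
  orientation is irrelevant). No interpolation between sections; each traced
  section contributes its full slab. For a sphere of radius $r$ the estimate
  is unbiased over section phase and converges as $t \to 0$; our tests
  require < 5 % error at $t = r/20$ and monotone convergence over the
  thickness ladder 0.1, 0.05, 0.025 µm.
* **Surface area**: lateral stair-step term $\sum_k P_k\, t$ (contour
  perimeters) plus, by default, the two extremal contour areas as end caps.
  This convention is *not* consistent for oblique surfaces: for a sphere the
  lateral term converges to $\pi^2 r^2$, a $\pi/4$ underestimate of
  $4\pi r^2$, because perimeter × thickness measures the projected band, not
  the slant band. We keep the convention (it is what the reconstruction
  software the field uses reports) and document rather than correct the bias;
  it is exact for surfaces perpendicular to the cutting planes (tested on a
  cylinder).
* **PSD area**: $t \times$ (summed in-plane trace length over consecutive
  sections). For a planar disc of radius $\rho$ sliced perpendicular to its
  plane this is the chord integral $\int 2\sqrt{\rho^2 - z^2}\,dz = \pi\rho^2$,
  which the tests verify on a shrinking-thickness ladder.
* **Neck length and dendrite length** are 3D polyline lengths. The dendrite
  axis is the polyline through per-section shaft contour centroids, z of
  section $k$ at $k\,t$; no spline smoothing. When a spine has an explicit
  neck trace its 3D path length is used. When it does not (the common case in
  practice, where neck length was measured manually against a reference
  square), we use a deterministic surrogate: distance from the spine head
  centre (area-weighted centroid of its contours) to the dendrite axis, minus
  the head radius (from the largest head section, $r = \sqrt{A_{max}/\pi}$)
  and the local shaft radius, floored at zero for sessile spines. We chose the
  anchor surrogate over emitting synthetic per-section neck traces because
  open traces quantize z to the section grid, which systematically inflates
  the length of oblique polylines (a Manhattan-in-z artifact of up to ~40 %
  at 45°); the anchor construction is exact for straight necks of any
  obliquity.
* **Spine density** = spine count / dendrite path length; multiplying back
  recovers the integer count exactly.

## Classification

* **Small vs large** (thin vs mushroom type): head volume against a cutoff,
  default 0.04 µm³ — the approximate median head volume of young-adult
  wild-type striatal spines, so the cutoff bisects an adult population.
  Printed reference ranges make the boundary itself ambiguous (small ranges
  end at 0.040, a large range begins at 0.040), so the tie rule is fixed
  deterministically: volume ≤ cutoff is small.
* **Macular vs perforated PSD**: purely trace-topological, since traces are
  the input. A PSD is perforated when some section holds ≥ 2 disjoint traces
  of the same synapse, or a trace closes into a ring enclosing untraced area
  (the doughnut-shaped PSD sliced in its own plane). A sliced annulus always
  produces the two-trace signature whenever its hole spans a section plane.
* **Histograms** of head volume use left-closed bins of width 0.04 µm³
  starting at zero; relative frequencies sum to one.
* Percentages are reported half-up to one decimal, fold changes of
  percentages to two decimals, matching conventional reporting precision.

## Statistical battery

The battery mirrors SPSS-style practice for this kind of data:

* Normality is gated per sample by Shapiro–Wilk at $\alpha = 0.05$
  (constant samples, where the test is undefined, are treated as non-normal).
* Two groups: both normal → two-sided Student's *t* (equal variances);
  otherwise Mann–Whitney *U* (normal approximation with continuity
  correction). The result records which path was taken.
* Three or more groups: all normal → one-way ANOVA with pooled-variance
  pairwise *t* tests on the ANOVA error term; any group non-normal →
  Kruskal–Wallis with Dunn rank *z* tests (midranks, tie correction). If any
  group fails the gate the whole comparison goes nonparametric, matching the
  binary parametric/nonparametric split of the reference workflow. Pairwise
  p-values are Bonferroni-multiplied and capped at 1 — the cap is why equal
  groups report exactly p = 1.00.
* Distribution shifts use the two-sample Kolmogorov–Smirnov test with the
  asymptotic ("Z test") p-value, not small-sample enumeration.
* Correlations use Spearman's rank-order test (midranks for ties, asymptotic
  p), which equals Pearson's r on midranks — an identity the tests verify.

Tests are built on the `stats` primitives (`shapiro.test`, `t.test`,
`wilcox.test`, `lm`/`anova`, `kruskal.test`, `ks.test`, `cor.test`); the
gating logic and both post hoc procedures are implemented here. Operating
characteristics are tested by simulation: type-I error of every gated path
within 0.05 ± 0.02 over 1000 null replicates, and the KS statistic equal to a
brute-force ECDF-gap oracle for n ≤ 20.

The unit of analysis is the spine for head volume, neck length and PSD area,
and the dendrite for spine density. Both tables are exposed, so either unit
can be re-analyzed.

## The synthetic generator

The generator emulates exactly the statistical structure the analysis
assumes, at the scale of the reference survey (eight (genotype × age) groups,
7–11 dendrites each, 65 dendrites and ~1300 spines in total):

* **Head volumes** are lognormal. Only a mean and a median are printed per
  group; for a lognormal these two numbers identify the distribution
  ($\mu = \ln m_{med}$, $\sigma = \sqrt{2\ln(m/m_{med})}$), and lognormal is
  the standard model for right-skewed spine-volume data with mean ≫ median.
  Sampled volumes are floored at 0.001 µm³, the smallest head volume in the
  reference ranges.
* **Spine counts** per dendrite are Poisson(density × length); dendrite arc
  lengths are normal, truncated to the reconstructable 5–25 µm range. Group
  sd's are recovered from printed SEMs as $sd = SEM\sqrt{n}$.
* **Neck lengths** are normal truncated below at 0.05 µm.
* **PSD area** couples to head volume as $c\,V^b \times e^{\varepsilon}$,
  $\varepsilon \sim N(0, 0.3^2)$, with $b = 1$ (pure linear, per the observed
  positive linear PSD–volume relation) and $c = 1$ µm²/µm³, a realistic
  near-proportional scale for striatal synapses; both are exposed for
  sensitivity analyses. With these defaults every group's Spearman r exceeds
  0.8, reproducing the qualitative correlation result.
* **Perforation** is Bernoulli with probability
  $\mathrm{logit}^{-1}(b_0 + 0.9\,(\ln V - \mu))$, encoding that perforated
  PSDs concentrate in large spines; $b_0$ is calibrated by numerical
  integration so the population rate equals the printed group percentage.
  Perforation is only assigned to PSDs large enough that an annular
  discontinuity of at least the digitization resolution can exist
  (≈ 0.0025 µm² at 50 nm sections / 4.5 nm pixels); the induced bias on group
  rates is far below one standard error, and it keeps ground-truth flags
  identical to what sliced geometry can express.
* **Geometry**: the shaft is a 0.3 µm-radius tube around a smooth sinusoidal
  axis of exactly the sampled arc length, running through the stack with a
  z-margin larger than any head radius (so no synthetic spine touches the
  stack boundary); heads are spheres of radius $(3V/4\pi)^{1/3}$ displaced
  laterally by shaft radius + neck length + head radius (overlaps resolved by
  re-drawing the azimuth, at most 100 attempts); PSDs are planar discs
  (annuli when perforated) of the sampled area, tangent to the head opposite
  the neck. Discs are oriented with their plane containing the z axis, which
  makes the chord-integral identity exact for the PSD estimator.
* **Slicing** digitizes circles as inscribed polygons with sagitta tolerance
  equal to the pixel size (12–64 vertices); cross-sections under two pixels
  are dropped with a warning. Coordinates are stored in pixels at 4.5 nm, the
  stated acquisition resolution; section thickness defaults to 50 nm (within
  the stated 40–50 nm acquisition range).

What the generator deliberately does **not** emulate: non-spherical head
shapes, curved or tapering necks, within-dendrite clustering of spine
properties (spines are exchangeable within a group), stubby spines attached
without a neck, boundary-truncated spines, or tracing noise/misalignment.
Passing parameter recovery therefore validates the estimator chain and the
statistics, not robustness to tracing error on real material.

## Numerical and policy choices

* z of section $k$ is $k\,t$ (section 0 at z = 0); image y-axis points down;
  areas are absolute values, so contour orientation never flips signs.
* Closed contours must be simple; validation uses a convexity fast path and
  an $O(n^2)$ proper-intersection test otherwise.
* Spines flagged `touches_boundary` (head traced on the first or last
  section) are excluded from spine-level statistics by default
  (`boundary_policy = "exclude_touching"`), since truncated heads bias
  volumes low; they still count toward spine density, because a truncated
  head is still a spine on the dendrite. `include_all` is available.
* Head-volume floors, tie rules, rounding conventions and the perforation
  detectability constraint are all documented above at the point they arise.
* Reproducibility: all randomness flows from one master seed; identical
  (configs, seed) produce byte-identical series files, manifests and
  reports.

## Problem sizes used in the tests

The packaged test suite exercises the full eight-group, 65-dendrite preset
once at a fixed seed for end-to-end parameter recovery, 1000-replicate null
simulations for the size of each gated test path, and small purpose-built
scenes for the geometry oracles. These sizes match the reference survey's
scale; recovery tolerances are three standard errors of each generative
quantity at the realized group sizes.

## Known limitations

* The neck-length surrogate assumes a roughly straight neck; strongly curved
  necks would be underestimated (straight-line anchors) — consistent with
  the generator, which builds straight necks.
* The stair-step surface-area convention underestimates oblique surfaces by
  up to $\pi/4$; compare surface areas only within this convention.
* Perforation detection is topological on traces; a perforation whose hole
  never spans a section plane is invisible at the acquisition thickness, in
  the generator as in real stacks.
* The statistical battery intentionally implements only the reference
  workflow (no effect sizes, no mixed models accounting for within-dendrite
  correlation of spine metrics).
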