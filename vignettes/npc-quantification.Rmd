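---
title: "Counting nuclear pores from localization microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting nuclear pores from localization microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcquant)
```

## The scientific problem

Nuclear pore complexes (NPCs) are ~100 nm, eight-fold symmetric protein
assemblies perforating the nuclear envelope. A recurring question in
cell-state comparisons (for example progenitor versus differentiated
keratinocytes, or nucleoporin knockdown versus control) is whether the
*number* of pores per unit nuclear surface changes, or only the
*composition* of individual pores. Diffraction-limited imaging cannot
resolve single pores; stochastic optical reconstruction microscopy
(STORM) can, by accumulating sparse single-molecule localizations (SML)
of photo-switching dyes over tens of thousands of frames, reaching
~25 nm resolution.

`npcquant` implements the downstream quantification: it starts from a
localization table (one fitted blink position per row, as exported by
standard PSF-fitting software), cleans it, extracts individual NPCs by
density-based clustering, and summarizes each nucleus by four metrics
that can be compared between groups:

* **NPC density** — detected pores per µm² of nuclear area;
* **SML density** — all localization events per µm² (clustered or not);
* **SML per cluster** — mean localizations per pore, a proxy for how
  much of the labelled protein each pore carries;
* **cluster diameter** — a size statistic of each pore's localization
  cloud.

The package also covers the two companion assays used in such studies:
FRAP recovery kinetics for nucleocytoplasmic transport, and
nuclear-to-cytoplasmic (N:C) intensity ratios for transcription-factor
localization. A synthetic-data module generates all three data types
with known ground truth, so every stage is testable without microscope
data.

## Preprocessing

**PSF-width filtering.** Out-of-focus molecules fit with a wide point
spread function; localizations with fitted width sigma > 200 nm are
rejected (`filter_by_sigma()`, threshold configurable). The filter is
order-preserving and idempotent.

**Drift correction.** Slow stage motion is estimated by
cross-correlation of temporally binned reconstructions
(`estimate_drift()`): the movie is split into `n_bins = 10` contiguous
frame bins, each bin is rendered as a 2-D histogram at
`render_px = 20` nm (about twice the localization noise, a standard
choice), and the shift of each bin against the first is the
cross-correlation peak, refined to sub-pixel precision by a 3×3
intensity centroid around the peak. Per-frame drift interpolates
linearly between bin midpoints with constant extrapolation at the ends.
Two numerical notes:

* shifts are measured against the first bin rather than by redundant
  pairwise least squares — the simplest scheme consistent with a
  one-line description of the method; the redundant variant is a
  documented extension point;
* the 3×3 centroid slightly shrinks sub-pixel offsets toward the peak
  pixel. For estimating a *linear* drift total this hardly matters
  because `drift_total()` fits a least-squares slope through all ten
  bin shifts and extrapolates over the full frame range; recovered
  totals on simulated 100 nm drifts are accurate to a few nm (the
  package's tests verify < 15 nm per axis).

The canonical pipeline order is drift correction, then filtering; the
two stages commute for all practical purposes and the order is exposed
as a configuration switch (`pipeline_config(drift_correct = )`).

## Pore extraction: HDBSCAN

Localizations are clustered with HDBSCAN (hierarchical density-based
spatial clustering of applications with noise) with Excess-of-Mass
(EOM) cluster selection, on the Euclidean 2-D coordinates. The
implementation is native to the package (no R implementation of the
algorithm was available among its dependencies): an Rcpp core computes
per-point core distances (distance to the `min_samples`-th nearest
neighbour, the point itself counting as the first — the convention of
the scikit-learn implementation, against which the package is
cross-checked in its test suite) and a Prim minimum spanning tree of
the mutual-reachability graph in O(n²) time and O(n) memory, which is
the right trade-off at the ~10⁴ localizations a single nucleus yields;
R code then condenses the single-linkage hierarchy at
`min_cluster_size`, computes cluster stabilities, and selects clusters
by EOM. The root (all-points) cluster is never selectable, matching the
reference behaviour when a single global cluster is not an admissible
answer. Duplicate-point degeneracies are handled by clamping merge
distances away from zero before taking density levels `lambda = 1/d`.

The single tunable the method exposes is `min_cluster_size` (the
neighbourhood size `min_samples` is tied to it unless overridden).

### Monte-Carlo tuning of the minimum cluster size

`optimize_min_cluster_size()` chooses `min_cluster_size` by simulation:
fields with known pore positions are generated, the full
preprocess-and-cluster pipeline is run for each candidate, recovered
cluster centroids are greedily matched to true pore centres within
75 nm (each side matched at most once), and the candidate with the best
mean F1 (harmonic mean of precision and recall) wins, ties toward the
smaller candidate. Greedy rather than optimal assignment is adequate
because pore separations are large compared with the match radius.

The default candidate grid is `4:16`, a fine unit-step scan: with ~19
SML per pore expected at the default emitter statistics, the plausible
range of thresholds is narrow and the score is cheap to evaluate, so
nothing is gained by a coarse grid. On default fields the optimum sits
at `min_cluster_size = 7`–8 with mean F1 ≈ 0.90–0.92.

### What limits clustering fidelity

Two failure modes dominate, and both are informative:

* **Merging.** Pores closer than ~200 nm have overlapping localization
  clouds (ring radius ~54 nm plus noise), and a fraction of such pairs
  is returned as one cluster. This is the main recall loss at the
  default pore density of 4/µm².
* **Splitting.** At small `min_cluster_size` the eight corner sites of
  a ring — each carrying several blinks of the same dye — can be split
  into per-corner sub-clusters, inflating counts.

A consequence worth stating explicitly: any fixed admission threshold
sits somewhere in the left tail of the per-pore localization-count
distribution. If two groups differ in labelling or blinking efficiency,
that tail mass differs between groups, so detection efficiency is
never exactly equal. At the synthetic defaults used here (mean 19 vs 14
SML per pore for a 0.72× blink scaling), the residual efficiency gap is
about 7–11% for every configuration we examined — large enough that a
10-nuclei-per-group t test on NPC density reliably detects it. Real
data with brighter pores (localization counts far above the threshold)
do not suffer from this; it is a property of the dim-emitter regime,
not of the clustering implementation (the scikit-learn reference
implementation scores identically on the same fields).

## Per-cluster and per-nucleus statistics

`summarize_cluster()` reports the centroid, the member count and the
**diameter**, defined as twice the mean Euclidean distance of members
from their centroid. This definition is exact for points evenly spaced
on an ideal circle, well defined for dot-like clusters, and needs no
circle fitting. Under localization noise it *overestimates* an ideal
ring's diameter by about sigma²/r (the Rician mean radial distance),
~2 nm at the defaults; estimating the centroid from the same points
*shrinks* it by a factor ≈ sqrt(1 − 1/n). Both biases are small and are
verified quantitatively in the tests against a numerically integrated
ring-plus-Gaussian expectation.

`nucleus_stats()` divides by the nuclear area: from a supplied ROI
polygon (shoelace formula, nm² converted to µm²) or, by default, the
convex hull of the localizations — appropriate because pores cover the
imaged nuclear surface densely. Noise localizations count toward SML
density (a literal reading of dividing *all* localization events by the
nuclear area) but never toward per-cluster means.

## The synthetic-data generator

`simulate_npc_field()` emulates the statistical structure the analysis
assumes:

* pore centres: Poisson count at `npc_density = 4`/µm² over a disk ROI
  of radius 5 µm, thinned by dart throwing to a minimum separation of
  150 nm;
* each pore: 8 corner sites equally spaced on a ring of diameter
  107 nm (the canonical NPC scaffold diameter) at a random rotation;
  each site labelled with probability 0.6; each labelled site emits
  `1 + Poisson(mean_blinks − 1)` localizations (`mean_blinks = 4`), or
  exactly `mean_blinks` in the zero-variance mode used for exact
  counting tests;
* localization noise: isotropic Gaussian with sigma 10.6 nm — a 25 nm
  resolution figure read as a FWHM, 25/2.355;
* uniform background at 40/µm² with a broader PSF-width distribution
  (uniform 100–300 nm, so part of it is removed by the 200 nm filter,
  as in real data), signal widths uniform 100–180 nm;
* frames assigned uniformly over 20,000 acquisition frames; optional
  linear (or sinusoidal, for stress tests) drift added per frame;
* dot-like (rather than ring-like) labelling patterns are obtained by
  shrinking `ring_diameter` relative to `sigma_loc`; there is no
  separate emitter model.

What it deliberately does **not** model: blink dwell-time photophysics,
repeated localizations of one blink across consecutive frames, the z
dimension, camera noise, or labelling with multiple dyes per site.
Passing tests therefore demonstrate correctness of the *analysis* under
a clean emitter model, not robustness to every artefact of real
acquisitions.

`simulate_frap_trace()` samples an exponential association curve on a
0–500 s grid at 10 s steps with additive Gaussian noise, and
`simulate_nc_image()` builds two-compartment intensity images with
nested nucleus/cell masks.

## FRAP kinetics

`fit_recovery()` fits `I(t) = f0 + (plateau − f0)(1 − exp(−k t))` by
Levenberg–Marquardt least squares, with self-starting initial values
(floor = first sample, plateau = last, `k` from the half-span
crossing). A three-parameter fit is used rather than pinning the floor
at the bleach minimum — robust to incomplete bleaching. Flat or
non-recovering traces are flagged as failures with diagnostics, never
silently defaulted. The half-time is `ln 2 / k`; on the default
sampling grid with 2% noise, the rate is recovered with a median bias
under 2% and the fit covariance yields honest ~95% confidence
intervals (verified by simulation).

`diffusion_coefficient()` converts a fit to
`D = gamma · w² / (4 · t_half)` with `gamma = 0.88` (uniform circular
beam). A square bleach region of side L, as used in practice, is mapped
to the equal-area circle, `w = L/sqrt(pi)`; the circular-beam theory
the formula comes from has no exact square counterpart, and the
equal-area mapping is the conventional, documented choice
(`bleach_geometry()` makes it explicit and configurable).

Whether traces are normalized to pre-bleach intensity first
(`normalize_trace()`) does not affect the half-time: the fit is
equivariant under affine intensity transforms.

## N:C ratios

`compute_nc_ratio()` integrates (sums) intensities over the nucleus
mask and the whole-cell mask; cytoplasmic signal is the difference, and
the ratio divides nuclear by cytoplasmic signal. Integrated rather than
mean intensity is the default because subtracting a nuclear *signal*
from a whole-cell *signal* is only meaningful for integrals; a
mean-based mode exists behind a flag for labs that report mean-based
N:C. The ratio is invariant to detector gain but not to additive
offsets, which motivates the optional constant background subtraction.
Masks are inputs (hand-drawn or otherwise provided); segmentation is
out of scope.

## Group comparison

`two_sample_t()` defaults to the classic pooled-variance Student's t
test, matching the analysis convention of the studies this package
serves; Welch's variant is exposed because group sizes are often
unequal (11 vs 9, 15 vs 11 nuclei) and heteroscedasticity is plausible.
Two degenerate-variance conventions: identical constant samples give
p = 1; constant samples with unequal means are an error rather than an
infinite t. For three or more groups `compare_anova()` passes through
to one-way ANOVA with Tukey HSD as the post-hoc procedure.
`build_report()` assembles per-metric comparisons, mean ± s.d.
summaries and scatter figures from a tidy per-nucleus (or per-cell)
table. No multiple-testing correction is applied across the four
metrics, matching common practice in this literature; interpret
accordingly.

## Problem sizes and numerical choices

The simulation experiments shipped in the tests and acceptance script
use: ten nuclei per group at the default field (≈310 pores, ≈9,000
localizations per nucleus); five replicate fields per candidate during
tuning; five held-out fields for fidelity scoring; 200 traces for FRAP
bias; 10,000 replicates for the t-test size check. These sizes keep
Monte-Carlo error comfortably below the tolerances being asserted.

Other numerical conventions: lengths are nm internally with areas
reported in µm² (one conversion boundary at I/O); localization CSVs are
written with 17 significant digits so round trips are bit-faithful;
drift histograms pad their extent by 4 pixels; merge distances are
clamped at 1e-12 nm before inversion to density levels; the FRAP
optimizer runs at most 500 iterations with 1e-10 tolerances.

## Known limitations

* Detection efficiency depends on per-pore localization counts; in the
  dim-emitter regime, group comparisons of *density* can be confounded
  by *labelling* differences (quantified above). The package makes the
  shared-configuration constraint explicit but cannot remove the
  physics.
* Pores closer than ~200 nm are sometimes merged; counts at densities
  well above ~4/µm² will be biased low.
* The diameter statistic is a radial moment, not a fitted ring
  diameter; comparisons between conditions are meaningful, absolute
  values carry the documented ~±2 nm biases.
* Drift correction assumes structure-rich fields; sparse fields
  (< ~50 localizations per temporal bin) are rejected rather than
  guessed at.
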