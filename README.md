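# npcquant

Quantification of nuclear pore complex (NPC) numbers from
single-molecule localization microscopy (STORM/SMLM), for cell-state
comparisons: does a treatment or a differentiation program change how
many pores a nucleus carries, or only what each pore is made of?

The package is aimed at microscopists and image analysts who already
have localization tables (one row per fitted blink: frame, x, y, fitted
PSF width sigma) and want a reproducible, tested pipeline from there to
per-nucleus statistics and group-level p-values. It also quantifies the
two companion assays typically run alongside: FRAP transport kinetics
and nuclear-to-cytoplasmic (N:C) intensity ratios.

## What it computes

Given localization tables for a set of nuclei, the pipeline applies,
identically to every nucleus:

1. **drift correction** — cross-correlation of temporally binned
   renderings (10 bins, 20 nm pixels, sub-pixel peak refinement);
2. **quality filtering** — out-of-focus localizations rejected at
   sigma > 200 nm;
3. **pore extraction** — HDBSCAN (hierarchical density-based clustering
   with Excess-of-Mass selection), implemented natively (Rcpp
   mutual-reachability MST + condensed-tree selection) and
   cross-checked against the scikit-learn reference implementation;
4. **statistics** — per cluster: centroid, localization count, diameter
   (2 × mean radial distance from the centroid); per nucleus: NPC
   density and SML density over the nuclear area (supplied ROI polygon
   or convex hull), mean SML per cluster, mean diameter.

The one free parameter, HDBSCAN's minimal points per cluster *m*, is
tuned by Monte-Carlo simulation: synthetic fields with known pore
positions are clustered for each candidate *m*, recovered centroids are
greedily matched to truth within 75 nm, and *m* maximizing mean
F1 = 2PR/(P+R) is selected.

Group comparisons use the pooled-variance Student's t test (Welch
optional), or one-way ANOVA + Tukey HSD for three or more groups.

FRAP traces are fit with the exponential association
I(t) = f0 + (plateau − f0)(1 − e^(−kt)); the half-time is ln2/k and
diffusion coefficients follow the uniform circular-beam formula
D = γ·w²/(4·t½) with γ = 0.88 and w the effective bleach radius
(side/√π for a square region). N:C ratios follow the
subtract-then-divide rule: cytoplasmic signal = whole-cell integral −
nuclear integral; ratio = nuclear / cytoplasmic.

A first-class synthetic-data module (`simulate_npc_field()`,
`simulate_frap_trace()`, `simulate_nc_image()`) generates all inputs
with ground truth: blinking emitters on 8-corner rings (107 nm
diameter, 10.6 nm localization noise, 20,000 frames), uniform
background, optional drift.

## Worked example

```r
library(npcquant)

# one synthetic nucleus at the default field statistics
sim <- simulate_npc_field(npc_field_params(seed = 42))
nrow(sim$table)                 # 9452 localizations
nrow(sim$truth$npc_centers)     # 337 true pores

res <- run_npc_pipeline(list(sim$table),
                        pipeline_config(min_cluster_size = 7))
res$per_nucleus
#>   nucleus_id n_npc area_um2 npc_density sml_density mean_sml_per_cluster mean_diameter_nm
#> 1 sim-seed42   317    77.49       4.091       101.4                21.62            115.8
```

317 detected vs 337 true pores (−5.9%), a density of 4.09 pores/µm²
against a generating density of 4.0/µm², ~22 localizations per pore,
and a mean cluster diameter of ~116 nm for 107 nm rings blurred by
10.6 nm noise plus a background-inclusion bias. For a FRAP trace:

```r
fit <- fit_recovery(simulate_frap_trace(0.2, 1, k = 0.01,
                                        noise_sd = 0.02, seed = 1))
fit
#> <frap_fit> k = 0.01015 /s, half-time = 68.3 s, f0 = 0.198, plateau = 1
diffusion_coefficient(fit, bleach_geometry("square", 5))
#> [1] 0.02564233   # um^2/s
```

The half-time of 68.3 s recovers the generating k = 0.01/s (true
half-time 69.3 s) within the noise, and the 5 µm square bleach region
maps to an effective radius of 2.82 µm.

See the vignette (`vignettes/npc-quantification.Rmd`) for the models,
parameter defaults, and known limitations.

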