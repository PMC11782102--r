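---
title: "DP-ratio morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DP-ratio morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement

Main pancreatic duct dilation (MPDD) and pancreatic parenchymal atrophy
(PPA) are imaging findings associated with early pancreatic cancer. Both
change the same local quantity: on a plane cut perpendicular to the course
of the pancreas, the cross-sectional area of the main pancreatic duct (MPD)
grows relative to the area of the surrounding parenchyma — either because
the duct widens (MPDD) or because the parenchyma thins around it (PPA).
`dpratio` measures this **duct-to-parenchyma area ratio (DP ratio)** along
the organ and summarises the per-section profile by its **90th percentile**
(the *90th DP ratio*), a single score sensitive to both findings.

The package consumes a pair of co-registered binary segmentation masks
(pancreas region, MPD region) with physical geometry — how those masks are
produced (manual annotation, CNNs, ...) is outside its scope. The pipeline
is:

1. **Centerline estimation.** A spacing-aware Euclidean distance transform
   assigns each pancreas voxel its depth (mm to the nearest background
   voxel). Endpoints are found by the two-pass geodesic farthest-point
   rule, ordered so the tail is the patient-left end (the anatomical
   position of the pancreatic tail). Dijkstra's routing algorithm then
   finds the minimum-cost path on the 26-connected foreground graph with
   edge cost `step_mm / (1 + depth)^p`, `p = 2`, which draws the route onto
   the medial ridge.
2. **Centerline conditioning.** The voxel path is smoothed by a moving
   average (two points before and after each point and the point itself),
   then linearly resampled at 0.5 mm arc steps.
3. **Frames.** The tangent at each point is the unit chord to the point
   10 mm further along the curve: a short chord would inherit the fine
   vibration that segmentation defects leave in the centerline, and tilted
   section planes produce outlier ratios. Points whose lookahead overruns
   the head use the chord to the final point, and the last point copies its
   predecessor's tangent. Normals and binormals are propagated with the
   double-reflection rotation-minimizing scheme.
4. **Cross-sections and the score.** Each mask is resampled
   (nearest-neighbour) on an 81 mm x 81 mm grid of 0.5 mm pixels spanned by
   the normal and binormal. 2-D connected components of the pancreas
   section that the centerline does not pass through are removed, as are
   duct components not touching the retained pancreas; this suppresses
   other structures the plane happens to slice. The DP ratio of a section
   is `duct_area / parenchyma_area`; the score is the 90th percentile of
   the per-section ratios.

## Parameters and defaults

| parameter | default | why |
|---|---|---|
| `resample_step_mm` | 0.5 | resolves shape change at CT pixel-spacing level |
| `tangent_lookahead_mm` | 10 | suppresses centerline vibration from local segmentation defects |
| `smoothing_half_width` | 2 points | five-point moving average of the voxel path |
| `section_half_extent_mm` | 40 | covers any pancreas cross-section |
| `in_plane_step_mm` | 0.5 | matches the along-axis resolution |
| `percentile_level` | 90 | reacts to focal elevation, discounts the few sections corrupted by segmentation or centerline defects |
| `dijkstra_exponent` | 2 | strength of the medial attraction in the routing cost |

The **denominator convention** is configurable. The MPD is segmented
inside the pancreas region, so "parenchyma" is read as the non-duct
tissue: `dp = duct / (pancreas - duct)` (default,
`parenchyma_excludes_duct`). The `whole_pancreas` alternative divides by
the full retained pancreas-plus-duct area; the two are related by
`dp_whole = dp_excl / (1 + dp_excl)`, so scores are monotonically
equivalent. Sections where no duct is detected score 0 rather than being
skipped — under-segmentation of the duct therefore biases the score
*downward*, which is the conservative direction for a screening feature.
Sections with no retained parenchyma are marked invalid and excluded from
the percentile rather than being given an infinite ratio.

Several choices are deliberate degenerate-input policies: masks with
satellite foreground components use the largest component (with a
warning); Dijkstra ties break on voxel scan order so results are
bit-reproducible; the moving-average window shrinks *symmetrically* at the
curve ends (`h_i = min(2, i-1, n-i)`), which keeps the filter an exact
identity on straight equally spaced input — one-sided clipping would drag
the endpoints inward.

## The phantom generator

`phantom_spec()` / `generate_phantom()` build a curved tube (straight,
planar arc, or planar sinusoid) of parenchyma radius `R(s)` containing an
inner duct tube of radius `r(s)`, optionally displaced off-axis,
voxelized on a configurable grid. Cross-sections are circular by design,
so the DP ratio has the closed form

> `DP(s) = r(s)^2 / (R(s)^2 - r(s)^2)`

and every pipeline stage can be checked against an exact oracle. The
defaults emulate a healthy adult organ: a 120 mm tube of 10 mm
half-thickness with a 1.5 mm-radius duct, voxelized at 1.0 mm (typical
portal-phase CT). Cohort positives multiply `r` by 3 (dilation) or `R` by
0.6 (atrophy) over a random contiguous span of 25–50% of the organ.

What the phantoms do *not* emulate: non-circular and lobulated
cross-sections, radius variation at the organ head/neck, CT intensity and
contrast-phase effects, and realistic CNN error modes beyond smooth
surface jitter and disconnected speckle satellites. Passing phantom tests
therefore demonstrates the *measurement* is faithful to the masks it is
given, not that any segmentation upstream is accurate.

Numerical choices in the generator worth knowing about:

* **Lattice anchoring.** Voxel centres sit on the global lattice
  `k * spacing - spacing/2`. The half-voxel offset keeps centres off the
  analytic surfaces when radii are integer multiples of the spacing (a
  degenerate alignment that biases the strict inside test), and anchoring
  means enlarging the field of view — e.g. when speckle satellites extend
  the bounding box — never re-samples the tube itself.
* **Off-axis test ducts.** A duct centred exactly on the lattice symmetry
  point makes whole rings of boundary voxels drop in or out together as
  `r(s)` sweeps through special values, the worst case for voxel-counted
  areas. Profile-recovery studies therefore use a modestly off-axis duct
  (offset ~1 mm), which is also the anatomically generic configuration;
  concentric phantoms are kept where a test pins them.
* **End caps.** The distance rule `|x - curve| < R` produces hemispherical
  caps extending `R` beyond each curve end; `cap = "flat"` cuts the tube
  at the end planes instead, which is the right geometry when the quantity
  under test is the centerline arc length.

## Accuracy and known limitations

* Voxel-counted areas of small ducts are quantized: at 1 mm voxels a
  1.5 mm-radius duct is carried by only ~4–9 voxels per slice, so absolute
  ratios are biased low at coarse spacing. Detection contrast (dilated vs
  baseline) is preserved; comparisons across resolutions are not.
* The raw Dijkstra path wobbles transversally by about one voxel and
  overestimates arc length by up to ~10% on oblique curves; the smoothed,
  resampled centerline — the curve the method actually measures on — is
  accurate to a few percent. Arc-length validation uses a thin tube
  because the geodesic-diameter endpoints sit on the end-face rim, adding
  length that scales with the tube radius.
* Exact in-plane rotation invariance of the score holds for 90-degree
  rotations of the section grid (the square sampling grid maps onto
  itself); arbitrary rotations agree only up to voxelization error.
* Problem sizes in the test-suite studies (tubes of 40–120 mm at 0.5–1 mm
  voxels, cohorts of 20) were chosen so the full suite runs comfortably on
  a laptop while keeping every analytic margin wide.

## Cohort evaluation

`run_cohort()` scores each case and reproduces the evaluation design used
with this feature: Welch's t-test between cases with and without each
finding (alpha 0.05), the ROC curve obtained by sweeping the score
threshold (positive when `score >= threshold`), its AUROC (equal to
pairwise concordance), the two operating points with sensitivity or
specificity at least 90% (ties resolved toward the larger threshold), and
the Bonferroni-corrected three-group comparison — both findings, MPDD
only, neither — at alpha/3 (0.0167, conventionally printed 0.016).
Per-case failures are excluded with a notice rather than aborting the
cohort, and a finding with only one class present is skipped explicitly.

```{r}
library(dpratio)
cohort <- generate_cohort(10, 10, "mpdd", phantom_spec(), seed = 0)
res <- run_cohort(cohort)
res$evaluation
```
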