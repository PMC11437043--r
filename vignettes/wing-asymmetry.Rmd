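---
title: "Quantifying insect wing asymmetry with wingasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying insect wing asymmetry with wingasym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingasym)
```

## The measurement problem

Fluctuating asymmetry — small random deviations from perfect bilateral
symmetry — is widely used as an indicator of developmental stability in
insects. Landmark-based morphometrics struggles here: homologous landmarks
must exist and be identifiable on both wings, which fails for mutated or
damaged wings and across distantly related taxa. `wingasym` instead treats
the venation network itself as the measurement substrate. A wing image is
segmented into its membrane *cells* (regions enclosed by veins — not
biological cells), and asymmetry is quantified from the full set of
cell-level descriptors rather than from a handful of landmarks.

The pipeline for one wing pair is:

1. **Binarize** each grayscale image at a fixed threshold (default 0.54 on
   [0, 1] intensities, strictly-greater rule), with veins dark and
   membranes light; mirror the left wing so both share one orientation.
2. **Segment** the membrane phase by region growing: each 8-connected
   light component becomes a cell, light components touching the image
   border are background, and the vein pixels adjacent to each cell are
   recorded as its boundary.
3. **Measure** each cell: area (pixel count), length (maximum pairwise
   distance between boundary pixels), width (area / length), and
   circularity $C = 4\pi A / P^2$, with the perimeter $P$ the traced
   8-connected contour length (axial steps 1, diagonal steps $\sqrt 2$).
4. **Skeletonize** the vein phase (two-subiteration Zhang–Suen thinning)
   and detect **junctions**: skeleton pixels with at least three skeleton
   neighbors and crossing number $\ge 3$, clustered so each anatomical
   branch point yields one junction.
5. **Superimpose** the wings rigidly — translation and rotation only,
   deliberately no scaling, so that genuine size asymmetry survives the
   alignment — by particle swarm optimization on the mean nearest-neighbor
   distance between outlines resampled at equal arc length.
6. **Compare**: cells (and junctions) are matched by nearest centroid in
   both reference directions, and asymmetry is summarized by per-metric
   ordinary least squares regression and NRMSE, distance statistics, and
   signed count/size differences.

## Superimposition

The wing outline is the external boundary of the silhouette (the
complement of the border-connected light background). Both outlines are
resampled to $N = 200$ points at equal arc length; the PSO objective is
the one-directional mean distance from the moving wing's resampled points
to the nearest reference point, which is cheap and monotone with alignment
quality, while the symmetric average of both directions is the outline
distance that gets reported.

The swarm uses the standard configuration: 3 variables $(x, y, \theta)$,
40 iterations, 30 particles, inertia weight $w = 1$ damped by 0.95 per
iteration, and cognitive/social coefficients $C_1 = C_2 = 1.2$. Particles
are initialized uniformly inside the bounds; velocity starts at zero; the
RNG seed defaults to 0 so runs are reproducible. Choices the method
description leaves open were fixed as follows:

* **Rotation pivot** — the moving wing's outline centroid, which
  decouples $\theta$ from the translation components.
* **Bounds** — $x, y$ within $\pm W/4$ (image width $W$) around the
  centroid-aligning translation, $\theta \in \pm 30^\circ$; wings
  pre-aligned by centroid need only small corrections.
* The per-iteration global best is recorded, so the objective history is
  non-increasing by construction.

## Asymmetry metrics

For each reference direction, every reference cell is matched to the
nearest target cell by centroid distance; several reference cells may
share a target (the bidirectional protocol handles surplus cells, rather
than forcing an injective assignment). For each of area, length, width and
circularity, the matched value pairs enter an OLS fit of target on
reference — slope, intercept and $r^2$ are all reported, since a
perfectly symmetric pair gives the identity line with $r^2 = 1$ — and the
NRMSE, i.e. the RMSE of the matched differences divided by the reference
range. Range normalization makes the four metrics comparable despite
their different units and is invariant under a common rescaling of both
wings.

Distance statistics (mean and *population* SD, divisor $n$) are computed
per category: matched cell centroids, matched junctions, and resampled
outline distances. Count and whole-wing differences (cells, junctions,
wing area/length/width/perimeter) are signed wing1 − wing2 values. No
significance machinery is included by design; the tables are meant to be
exported into dedicated statistics software.

Cells can further be partitioned into up to five disjoint **cell sets**
(each at least three cells), by explicit id lists or by polygons applied
to centroids; sets correspond across wings by index, and the full
regression/NRMSE battery is repeated per set for localized comparisons.

## The synthetic wing generator

Because validation needs exact ground truth, the package ships a
deterministic generator rather than relying on scanned specimens. A
centroidally relaxed Voronoi tessellation of an ellipse-like, tip-tapered
blade is rasterized with dark vein strokes (default 3 px) on a light
background; the tessellation provides exact cell areas, centroids and
vertex positions. Default study conditions: 320 × 480 px, 25 cells (10
minimum), 20 Lloyd iterations. Left/right perturbations:

* per-cell area changes via multiplicative Voronoi weights (log-normal,
  SD `cell_scale_sd`);
* vertex-level shape noise via Gaussian jitter of the seeds;
* a global area ratio via geometric scaling by $\sqrt{\text{area\_scale}}$
  (a fixed silhouette cannot scale every cell at constant total area, so a
  uniform inflation is necessarily a whole-wing scaling);
* a rigid offset $(x, y, \theta)$, rendered exactly by evaluating the
  tessellation at inverse-transformed pixel coordinates;
* salt-and-pepper noise (pixelwise, half salt half pepper) and Gaussian
  blur applied to the intensity image. The blur parameter is the Gaussian
  $\sigma$ in px; the robustness scenario uses $\sigma = 1$, the
  package's reading of a one-pixel blur radius.

What the generator does *not* emulate: realistic vein-tree topology,
pigmentation, corrugation, scanning artifacts other than the two above, or
vein-width variation. Passing tests therefore demonstrate that the
*measurement contracts* hold — counts, areas, slopes and distances are
recovered at known effect sizes — not that segmentation succeeds on
arbitrary real scans, which still require reasonably clean, high-contrast
images.

```{r example, eval = FALSE}
pair <- generate_pair(synth_config(seed = 1, area_scale = 1.15))
res <- run_pair(pair$right, pair$left, mirror = "second")
res$result$metrics   # area slope in direction 1 recovers ~1.15
```

## Numerical choices and edge cases

* **Connectivity** — membranes 8-connected, with the complementary phase
  effectively 4-connected (the standard dual pairing that avoids
  topological paradoxes).
* **Threshold boundary** — a pixel exactly at the threshold counts as
  vein (strictly-greater rule), erring toward vein-network connectivity.
* **RGB input** — collapsed to luminance with ITU-R 601 weights
  (0.299, 0.587, 0.114) before thresholding.
* **Despeckle** — `run_pair()` applies one 3 × 3 binary majority pass
  after binarization (`clean = FALSE` disables). Single-pixel
  salt-and-pepper flips otherwise notch cell contours and inflate traced
  perimeters, to which circularity is disproportionately sensitive; the
  filter leaves veins of width ≥ 2 px and membrane interiors unchanged.
* **Minimum cell area** — 8 px (configurable); suppresses speckle
  components that survive despeckling.
* **Cell length** — computed from the recorded *vein* boundary pixels, as
  defined; this inflates lengths by roughly one pixel relative to using
  interior extremes. Degenerate regions use length = max(1 px, maximum
  boundary distance) to keep width finite. The diameter is computed
  exactly via the convex hull of the boundary.
* **Spur pruning** — before junction detection, skeleton tips (crossing
  number ≤ 1) are eroded for 5 iterations, deleting free-ended thinning
  spurs shorter than 5 px entirely (including stubs attached diagonally
  to a trunk) while closed loops and through-lines are untouched.
* **Coordinates** — (row, col), 1-based, origin top-left, row increasing
  downward; centroids are real-valued arithmetic means. Cell ids follow
  row-major discovery order, so they are deterministic across runs.
* **Ties** — nearest-neighbor ties resolve to the first candidate in id
  order; nearest distances are recomputed directly from the coordinates
  of the argmin so that identical points give exactly zero.
* **Degenerate inputs** — an all-background image yields a zero-cell
  geometry with a warning; an image with no foreground at all is an
  error; multiple disjoint silhouettes keep the largest with a warning;
  constant reference vectors make regression/NRMSE error out rather than
  return misleading values.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic
material at desk scale: wings of 224 × 320 to 320 × 480 px with 15–25
cells, 10 seeds for the symmetry fixed point, 100 random masks for the
flood-fill oracle, all 256 neighborhood patterns for the junction rule,
20 swarm runs for rigid-offset recovery (offsets up to 15 px and 10°),
and 2–3 rendered pairs per effect-size and robustness scenario. These
sizes were chosen so the whole battery completes in a few minutes while
every contract is still exercised end to end.

## Known limitations

* Length/width via the maximum-distance definition approximates elongated
  cells poorly (the diagonal, not the major axis); ellipse-based axes are
  a possible refinement and circularity carries no anisotropy direction.
* Images must have clean, closed venation: transparent veins or
  low-contrast regions break region growing, and there is no automatic
  vein-gap repair.
* Matching is purely nearest-centroid after rigid alignment; strong
  shape asymmetry or very different cell counts can produce many-to-one
  matches, which the bidirectional protocol mitigates but does not
  eliminate.
* No statistical inference: outputs are descriptive tables intended for
  downstream analysis.
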