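# wingasym

Landmark-free quantification of bilateral asymmetry in insect wings from
paired 2-D images.

Fluctuating asymmetry — small random left/right deviations from perfect
bilateral symmetry — is a standard indicator of developmental stability,
but landmark-based morphometrics needs homologous landmarks on every wing,
which mutated, damaged, or taxonomically distant wings often lack.
`wingasym` instead measures the venation network itself: each wing image is
segmented into its membrane **cells** (regions enclosed by veins), and
asymmetry is quantified over the whole cell population. It is aimed at
entomologists and morphometricians comparing left/right (or fore/hind)
wing pairs within and across species.

## Method

For a pair of same-sized grayscale images (veins dark, membranes light):

1. **Binarization** at threshold 0.54 on [0, 1] intensities
   (strictly-greater rule); the left wing is mirrored into the right
   wing's orientation; one 3×3 binary majority pass removes
   salt-and-pepper speckle.
2. **Region-growing segmentation** of the membrane phase (8-connected):
   border-touching light components are background, the rest are cells.
   Per cell: area *A* (pixel count), length *L* (max pairwise boundary
   distance), width *A*/*L*, and circularity

   C = 4π A / P²,

   with *P* the traced 8-connected contour length. The wing outline is the
   external boundary of the silhouette; vein **junctions** are branch
   points of the Zhang–Suen skeleton (≥ 3 skeleton neighbors and crossing
   number ≥ 3, clustered).
3. **Rigid superimposition** — translation + rotation, deliberately *no*
   scaling so true size asymmetry is preserved — by particle swarm
   optimization (40 iterations, 30 particles, w = 1, wDamp = 0.95,
   C1 = C2 = 1.2) of the mean nearest-point distance between outlines
   resampled at equal arc length.
4. **Asymmetry metrics**: cells and junctions matched by nearest centroid
   in both reference directions; per metric (area, length, width,
   circularity) an OLS regression (slope, intercept, r²) and the NRMSE
   (RMSE normalized by the reference range); mean ± SD distances for
   centroids, junctions and outlines; signed count and whole-wing
   differences. Cells can be split into up to five **cell sets** (≥ 3
   cells each) for localized comparison, and multiple pairs aggregate
   into cross-pair tables.

A deterministic synthetic-wing generator (centroidally relaxed Voronoi
venation over a blade silhouette, with controllable per-cell scaling,
vertex jitter, rigid offsets, salt-and-pepper noise and Gaussian blur)
provides exact ground truth for every stage.

## Worked example

Generate a synthetic pair whose left wing has every cell area inflated by
15%, run the full pipeline, and read the asymmetry report:

```r
library(wingasym)
pair <- generate_pair(synth_config(seed = 1, n_cells = 20,
                                   height = 256, width = 384,
                                   area_scale = 1.15))
res <- run_pair(pair$right, pair$left, label = "demo",
                mirror = "second", pso = pso_config(seed = 0))
res
#> <wa_pair> 'demo': 20 vs 20 cells
#> <wa_pair_result>
#>   transform: x = 0.072388 y = 0.9414 theta = -0.21706 deg
#>   area         r2 = 0.9997  nrmse = 0.3870  slope = 1.1529
#>   length       r2 = 0.9611  nrmse = 0.4044  slope = 1.0452
#>   width        r2 = 0.9894  nrmse = 0.2194  slope = 1.0898
#>   circularity  r2 = 0.9570  nrmse = 0.0648  slope = 1.0563
#>   mean symmetric outline distance: 7.2492
#>   delta cells: 0  delta junctions: 0
```

The area regression slope recovers the planted 1.15 inflation; length
scales by √1.15 ≈ 1.072 as geometry dictates; circularity (a pure shape
descriptor) stays near the identity line; cell and junction counts are
equal. `write_reports()` exports all of this, per wing and per reference
direction, as CSV and TXT. A command-line front end is included:

```sh
Rscript inst/cli/wingasym.R synth --seed 2 --cells 15 --out-dir demo
Rscript inst/cli/wingasym.R run --pair demo/left.png,demo/right.png \
        --mirror-left --out demo_out
```

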