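Package: wingasym
Title: Automated Insect Wing Asymmetry and Morphometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-free quantification of bilateral asymmetry in insect
    wings from paired binary images. Segments the venation network into
    membrane cells by region growing, extracts the wing outline, detects
    vein junctions on a thinned skeleton, rigidly superimposes the two wings
    of a pair (translation and rotation, deliberately no scaling) with
    particle swarm optimization on outline distance, and quantifies
    asymmetry through per-cell regression and normalized root mean square
    error of area, length, width and circularity, centroid/junction/outline
    distance statistics, and count differences. Includes a deterministic
    synthetic wing-pair generator with exact ground truth for validation,
    per-region cell-set comparisons, multi-pair project aggregation and
    CSV/TXT report writing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
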