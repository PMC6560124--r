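Package: sulcmorph
Title: Sulcal Width and Depth Morphometry from FreeSurfer Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the width and depth of individual cortical sulci from
    the surface reconstructions produced by FreeSurfer.  Reads the binary
    triangle surface, annotation, and per-vertex scalar overlay formats;
    isolates a Destrieux-labelled sulcus as a submesh; extracts the closed
    boundary edge loop between sulcus and adjacent gyri; measures width as
    the median of distances bridging the sulcus between opposite stretches
    of that loop, and depth as the median Euclidean distance from the sulcal
    fundus to the smoothed enclosing (outer) surface.  Includes a synthetic
    subject generator with analytically known ground truth, a batch pipeline
    over a subjects directory with cohort quality control, and the companion
    statistics layer: ICC(1,1) test-retest reliability with 95% confidence
    intervals, Pearson and partial correlations, and cohort summarisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
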