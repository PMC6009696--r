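Package: ctRadial
Title: Chromosome Territory Radial Positioning from 3D Confocal Stacks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the radial position of chromosome territories in
    interphase nuclei from multichannel 3D confocal stacks using the
    percent radial distance statistic (distance from nucleus centre to
    territory centre, expressed as a percentage of the distance from the
    nucleus centre to the nuclear boundary along the same ray). Provides
    nucleus and territory segmentation on anisotropic voxel grids,
    ray-marching boundary intersection, binned radial-distance
    distributions, Mann-Whitney condition comparisons and median shift
    tables; per-chromosome transcriptional deregulation summaries from
    gene-level FPKM/fold-change tables; nuclear-envelope line-scan
    intensity profiling of 2D mid-sections; and a ground-truthed
    synthetic microscopy and expression simulator so the whole pipeline
    is testable without real acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
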