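Package: lung4dxv
Title: Regional Lung Function from 4D X-Ray Velocimetry CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of respiratory-gated 4D lung CT for regional
    lung function: ventilator-gated projection binning and small-scale
    cone-beam FDK reconstruction, Frangi-style multiscale airway segmentation
    with skeletonization into a rooted airway tree, windowed 3D
    cross-correlation velocimetry (XV) with subvoxel peak fitting, regional
    expansion mapping from displacement gradients, and Airway Tree Link (ATL)
    analysis producing per-branch airflow series, cumulative aeration maps
    and expiratory time constants. Includes a synthetic breathing-lung
    phantom with a known airway tree, closed-form displacement and expansion
    fields and known regional airflow, so the whole pipeline is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    tiff,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
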