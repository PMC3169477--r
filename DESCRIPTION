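Package: cardiovol
Title: Short-Axis and Rotational Long-Axis Cardiac Volumetry on Digital Heart Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to compare short-axis (Simpson slice-summation) and rotational
    long-axis quantification of left-ventricular and left-atrial volumes,
    ejection fraction, and left-ventricular mass from planar contour sets.
    Provides a parametric digital heart phantom with analytically known chamber
    volumes and myocardial mass, short-axis and radial long-axis slicing with
    clinically realistic thickness/gap protocols, a correlated contour
    perturbation model emulating observer variability (including basal-slice
    misassignment), a brute-force voxel-counting volume oracle, Bland-Altman
    agreement statistics, and a reproducible end-to-end phantom study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
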