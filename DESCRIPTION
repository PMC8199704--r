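Package: secrisk
Title: Secondary Cancer Risk Evaluation for Radiotherapy Dose Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates radiotherapy-induced secondary cancer risk from 3D dose
    distributions and organ contours. Reads and writes DICOM-RT objects
    (CT series, RTSTRUCT, RTDOSE, RTPLAN), rasterizes contours to voxel
    masks, resamples dose grids, computes differential dose-volume
    histograms, and evaluates organ equivalent dose (linear, plateau and
    bell dose-response models), excess absolute and relative risk, and
    lifetime attributable risk under the BEIR VII formalism with
    user-supplied life tables and baseline incidence rates. Also provides
    the stoichiometric Hounsfield-unit calibration (CT number to elemental
    composition and mass density) and GATE-dialect material-database
    export that feed an external Monte Carlo dose engine, VMAT plan to
    per-segment macro export, and fully synthetic phantom fixtures so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
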