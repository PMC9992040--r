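Package: perfopulse
Title: Perforating-Artery Velocity Pulsatility from 2D Phase-Contrast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of cerebral perforating arteries in velocity-encoded
    2D cine phase-contrast MRI of the basal ganglia and quantification of
    their hemodynamics: number of detected vessels, mean blood-flow velocity,
    and velocity pulsatility index. Includes the per-pixel noise estimation,
    SNR and velocity-significance masking, clustering, circularity and
    proximity filters of the detection algorithm; test-retest and inter-rater
    agreement statistics (Bland-Altman limits of agreement, coefficient of
    repeatability, intraclass correlation, Dice overlap, paired t-tests,
    power calculations); and a synthetic cine phase-contrast generator with
    known ground truth for end-to-end validation without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
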