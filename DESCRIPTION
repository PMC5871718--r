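Package: proteodyn
Title: Multiplexed Proteome Dynamics Profiling and Thermal Stability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of multiplexed proteome dynamics profiling (mPDP)
    experiments combining dynamic SILAC labelling with isobaric mass tags.
    Quantifies mature and nascent protein pools from PSM-level reporter-ion
    tables, calls treatment-induced degradation and synthesis changes with a
    replicate-based robust Z-test framework, estimates protein decay rates and
    half-lives with cell-division correction, fits thermal proteome profiling
    melting curves and two-dimensional dose-response curves, and classifies
    chaperone (HSP90) dependence. Ships a seeded synthetic-data generator with
    known ground truth so every analysis stage is testable without raw mass
    spectrometry data.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
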