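Package: cladeqpcr
Title: Clade-Specific qPCR Quantification of Symbiodinium Communities in
    Coral Hosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for absolute quantification of multi-clade Symbiodinium
    communities inside coral hosts from clade-specific 28S qPCR assays.
    Covers assay validation (log-linear standard curves, amplification
    efficiency, limits of quantification, cross-amplification specificity
    scoring, pairwise regression-coefficient tests), plate processing
    (technical-replicate quality control, interplate calibration,
    positive-call rules with melting-temperature checks), copy-number
    estimation with symbiont-to-host (S/H) ratio normalization,
    community composition analysis (dominant versus background clade
    classification, clade-pattern combinatorics, discriminant analysis
    of principal components), and a synthetic plate generator that
    emulates the study design for end-to-end parameter-recovery testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
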