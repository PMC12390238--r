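Package: ssdrisk
Title: Species Sensitivity Distributions and Ecological Risk Assessment
    with Interspecies Toxicity Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens chronic aquatic toxicity data, extrapolates toxicity to
    additional species through log-linear interspecies correlation estimation
    (ICE) models, fits species sensitivity distributions (log-normal,
    log-logistic, log-Gumbel) by maximum likelihood with Anderson-Darling,
    Kolmogorov-Smirnov and AIC goodness-of-fit assessment, derives hazard
    concentrations (HC5) with parametric-bootstrap confidence intervals and
    predicted no-effect concentrations (PNEC), and classifies per-site risk
    quotients (RQ) for surface-water monitoring tables. Ships curated
    bisphenol (BPA/BPS/BPF) toxicity, ICE-model and occurrence fixtures and
    seeded generators for synthetic datasets with the same statistical
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fitdistrplus,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
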