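Package: rrmsim
Title: Agent-Based Simulation of Teff-Treg Cross-Regulation in
    Relapsing-Remitting Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic lattice simulation of autoreactive effector T cells
    (Teff), regulatory T cells (Treg) and a viral trigger acting on a patch
    of myelinated white matter. Resting T cells enter by stochastic pulse
    trains, are activated by virus contact (molecular mimicry), and play out
    a spatial predator-prey dynamic: active Teff attack myelin and duplicate,
    active Treg suppress Teff and duplicate on success. Per-patch myelin loss
    is recoverable until a patch is fully demyelinated, after which the
    lesion is permanent. Each random seed is a virtual patient; cohort tools
    compare healthy individuals against individuals with impaired Treg
    duplication ("hill" scenario) via final-damage medians and the
    two-sample Kolmogorov-Smirnov statistic, and extract relapse episodes
    from the permanent-damage record.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
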