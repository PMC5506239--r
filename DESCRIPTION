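Package: radnp
Title: Radiation Survival Modelling and Nanoparticle Radio-Enhancement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying radio-enhancement by metallic nanoparticles in
    radioresistant bacteria. Implements a multi-target radiation-survival model
    with dose-dependent repair saturation, a staged nonlinear least-squares
    fitting procedure for clonogenic dose-response data, sensitization
    enhancement ratios and fixed-dose amplification metrics, deterministic
    nanoparticle exposure/uptake dosimetry, CFU-based toxicity normalization
    with minimal-inhibitory-concentration logic, growth-curve doubling-time
    estimation, two-factor ANOVA with Tukey comparisons, and seeded synthetic
    generators for clonogenic, toxicity and growth assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    withr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    minpack.lm,
    emmeans,
    car,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
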