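Package: amles
Title: Simulation and Metrics for Additive Versus Multiplicative Risk Factor Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates case-control cohorts in which dichotomous risk factors act
    through latent causal components (synergism, heterogeneity of causes,
    multifactorial threshold, population-stratification confounders and
    additive schemes), and measures how the joint effect of two or three
    factors compares with the additive and multiplicative null models.
    Provides the additive-to-multiplicative linear effect scale (AMLES),
    its signed-square variant, the threshold fraction and its square-root
    interpolation between the additive and multiplicative expectations,
    RERI, stratified Pearson correlations, replicate experiments with
    bootstrap confidence intervals of medians, permutation-based
    randomization controls for observed factor tables, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
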