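Package: lemmafrag
Title: Bayesian Analysis of Barley Husk Fragmentation from Impact Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models fragmentation of the barley lemma (the larger husk organ)
    under controlled impact as a readout of husk material properties. Fragment
    counts per lemma are fitted with a Poisson model under a vague conjugate
    Gamma prior; individual fragment areas are fitted with a Gamma likelihood
    by Metropolis-within-Gibbs sampling, with the mean fragment area mu =
    alpha/beta as the parameter of interest. Groups (variety by growth stage)
    are compared through highest-density intervals of posterior differences.
    Includes narrowest-window and analytic HDI estimators, Gelman-Rubin,
    effective-sample-size and Monte-Carlo-standard-error diagnostics,
    posterior predictive checks, a two-component Gamma mixture for
    parent/child fragment populations, a Weibull alternative likelihood, a
    synthetic impact-assay generator with an area-conserving sequential
    breakage mode, particle measurement of binary fragment masks with a
    minimum-area threshold, and a frequentist stage (two-way ANOVA, Tukey HSD
    with compact letters, bootstrap ratio-of-means intervals) for structural
    traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    car,
    EBImage
Config/testthat/edition: 3
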