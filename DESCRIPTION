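Package: pleioflux
Title: Allele-Resolution Pleiotropy in Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the pleiotropy of metabolic genes from genome-scale
    (and synthetic) constraint-based models. Estimates a wildtype flux
    distribution with parsimonious flux balance analysis, caps all fluxes at
    their wildtype values, and counts how many biomass components lose
    maximal production capacity when a gene's reactions are restricted to a
    fraction of wildtype flux, across an allele grid from full function to
    full knockout. Includes an essentiality variant with free flux
    redistribution, currency-metabolite mediation analysis via free-cofactor
    reactions, bipartite gene-trait network modularity (Barber's Q, LP&BRIM,
    degree-preserving rewiring nulls), a randomization test linking knockout
    pleiotropy to the number of stepwise pleiotropy increases, SBML
    import/export, and seeded synthetic network generators with brute-force
    oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    optparse,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
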