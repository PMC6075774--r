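Package: nestQG
Title: Quantitative Genetics for Colonial-Nesting Birds from Microsatellite Pedigrees
Version: 0.1.0
Authors@R: person("Juan", "Ferreyra", email = "jferreyra@example.org", role = c("aut", "cre"))
Description: Tools for estimating heritability, maternal and nest effects of
    morphological traits in wild bird colonies. Reconstructs pedigrees from
    codominant microsatellite genotypes (locus diagnostics, null-allele
    adjustment, exclusion probabilities, likelihood-based parentage and
    full-sib partitioning), builds the additive (numerator) relationship
    matrix by the tabular method, and fits Bayesian pedigree mixed models
    ("animal models") by Gibbs sampling, with posterior-mode/HPD reporting,
    genetic correlations from bivariate fits and DIC-based selection of
    random-effect structures. Includes a synthetic colony simulator
    (communal nests with multiple brood chambers, extra-pair paternity,
    intra-brood parasitism, null alleles) so every stage is testable
    without field data, plus an end-to-end pipeline and report renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
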