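Package: brumate
Title: Phylogenetic Comparative Analysis of Brumation and Tissue Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how hibernation (brumation) duration shapes
    the evolution of brain, fat, testis and muscle investment across anuran
    species. Estimates species-specific brumation periods from daily
    temperature series and experimentally derived activity thresholds,
    fits phylogenetic generalized least-squares regressions with maximum
    likelihood estimation of Pagel's lambda and bootstrapped standardized
    coefficients, computes phylogenetic partial correlations, analyses
    body-mass allocation as an Aitchison composition (clr/ilr transforms
    and a multivariate phylogenetic regression with a permutation MANOVA),
    performs phylogenetically informed principal component analysis,
    confirmatory path analysis via d-separation with CICc model ranking
    and averaging, and directional (Pagel) tests of correlated evolution
    between binary traits. A synthetic-data generator reproduces the
    statistical structure of the study design so the full pipeline can be
    exercised without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
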