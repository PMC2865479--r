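Package: sexconstraint
Title: Simulation-Based Tests of Sexual Constraint on Dimorphic Ornaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Phylogenetic comparative framework for deciding whether the
    similarity of male and female ornament scores across a clade is best
    explained by sexual constraint acting on females, on males, or on both
    sexes. Trait pairs evolve by Brownian motion along a rooted speciational
    tree; three competing constraint models (constraint on females,
    constraint on males, mutual constraint) block reversed dimorphism and
    pull the sexes together by a calibrated proportion of their difference.
    Observed data are compared against 1000-run simulated null distributions
    of three summary statistics (difference of standard deviations, pooled
    Zg1 skew, difference of reciprocal regression slopes) with two-tailed
    95% confidence-interval rejection and pairwise type-II-error
    (discriminability) matrices. Includes eigenvalue-weighted composite
    ornament scoring from colour-measurement matrices (broken-stick or
    Kaiser retention) and synthetic-data generators for every input.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
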