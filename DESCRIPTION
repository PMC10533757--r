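Package: rgsel
Title: Genomic Prediction Evaluation for Recurrent Selection with
    Multi-Location Sparse Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to design and evaluate recurrent genomic selection
    schemes in selfing crop populations phenotyped across locations and
    generations. Provides a synthetic-population generator (bulk-selfing
    generation advance, two-location lattice trials), marker filtering and
    the VanRaden genomic relationship matrix, REML variance decomposition
    and broad-sense heritability, per-trial BLUEs, Bayesian GBLUP with
    three genotype-by-environment kernel structures fitted by Gibbs
    sampling, CDmean training-set optimization with a genetic algorithm,
    replicated calibration/validation scenarios with Fisher-Z model
    comparison, and a deterministic scenario cost ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    multcomp,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
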