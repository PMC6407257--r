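Package: gtmap
Title: Probabilistic Ancestry Mapping with Generative Topographic Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for visualising and classifying genetic ancestry from
    genotype matrices. Implements a generative topographic mapping (GTM)
    engine trained by expectation-maximisation on PCA-reduced minor-allele
    count matrices, a Bayesian ancestry classifier built on GTM node
    responsibilities that yields per-individual and per-population ancestry
    membership probabilities, a 2D-PCA k-nearest-neighbour baseline, a
    repeated stratified cross-validation harness with class-weighted F1
    scoring and principal-component sweeps, and a seeded Balding-Nichols
    simulator of structured multi-population genotypes (with optional
    admixture) so the whole pipeline runs without external data. Reads plink
    .raw text exports and a plain TSV genotype dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
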