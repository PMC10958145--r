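Package: selconv
Title: Branch-Partitioned dN/dS Tests and Convergent Substitution Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting convergent molecular adaptation in
    protein-coding genes, motivated by the repeated selenocysteine-to-cysteine
    exchange in mammalian GPX6. Implements a GY94-style codon substitution
    model with branch-partitioned dN/dS (one-ratio, partition and free-ratio
    fits with likelihood-ratio tests), marginal empirical-Bayes ancestral
    sequence reconstruction under empirical amino-acid models, detection of
    convergent and parallel amino-acid substitutions between lineages with
    model-based expected counts and a phylogenetic simulation null,
    branch-site positive-selection fits with site posteriors and enrichment
    tests at convergent sites, and a synthetic-data generator with full ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    knitr
Config/testthat/edition: 3
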