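Package: lseselect
Title: Positive Selection in Lineage-Specific Expanded Gene Families
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-scale detection of positive selection in lineage-specific
    expanded (LSE) gene families relative to single-copy reference genes.
    Provides LCA gene-tree/species-tree reconciliation with ultraparalog (UP)
    and superortholog (SO) cluster extraction, codon-level GY94 site-model
    fitting (M1a/M2a/M8a/M8) with likelihood-ratio tests and empirical-Bayes
    identification of positively selected codons, per-branch dN/dS via
    expectation-based substitution mapping, size-stratified comparative
    statistics (Fisher, Mann-Whitney, sliding-window dS, Spearman), and a
    seeded synthetic-study generator so the full pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
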