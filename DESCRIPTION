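Package: soilnetfun
Title: Soil Microbial Co-Occurrence Networks, Robustness and Multifunctionality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain linking forest stand density to soil ecosystem
    multifunctionality through the soil microbiome: synthetic generators for
    ASV count tables and soil-property tables under a density-by-depth design;
    alpha and beta diversity (Chao1, ACE, Shannon, Simpson, Pielou, Good's
    coverage, Bray-Curtis, PCoA, PERMANOVA, Mantel); Spearman co-occurrence
    network construction with prevalence filtering and topology summaries;
    natural-connectivity robustness under random node removal with stability
    slopes; averaging (M-index) and threshold (T-index) multifunctionality;
    and diversity-function linkage via random-forest permutation importance
    and partial least squares path modeling with bootstrap confidence
    intervals and direct/indirect effect decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
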