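Package: pancore
Title: Pan-Genome Core Gene Analysis and Metagenome Recruitment Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bacterial pan-genome analysis at the protein level:
    greedy identity/coverage clustering of multi-strain protein sets into
    orthologous gene clusters, classification of clusters into core,
    dispensable and strain-specific genes, gene accumulation curves,
    genus-level core gene extraction, COG functional-category weighting and
    core-versus-specific enrichment, interpolated Markov-model genomic
    signatures with principal component separation, Poisson-corrected
    neighbor-joining trees of concatenated core genes with bootstrap
    support, average-linkage clustering of shared-gene patterns, and
    core-gene recruitment profiling of metagenome gene sets.  A synthetic
    pan-genome generator with known core/dispensable/specific structure
    provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    cluster,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
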