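Package: crossqtl
Title: QTL Mapping of Domestication Traits in F2 Crosses with
    Cross-Species Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of crop
    domestication in an F2 cross between a crop and its wild progenitor:
    simulation of F2 genotypes and quantitative traits, genetic linkage map
    construction (EM recombination-fraction estimation, LOD-based grouping,
    seriation with ripple refinement, segregation-distortion diagnostics),
    composite interval mapping with stepwise cofactor selection and
    genome-wide permutation thresholds, multiple-interval-mapping model
    refinement under a BIC-type information criterion, a genome-wide
    two-locus epistasis scan with orthogonal contrasts, trait-level
    statistics (parental comparisons, Spearman correlations with sequential
    Bonferroni, transgressive segregation), and comparative QTL
    colocalization across species bridged through an intermediary genome
    (BLAST hit filtering, synteny blocks, interval projection,
    hypergeometric and Fisher combined probability tests).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
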