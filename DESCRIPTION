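Package: genecontext
Title: Genome Context Methods for Functional-Linkage Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores pairs of genes in a target genome for functional
    relatedness from the genomic context of their homologs across a list of
    reference genomes. Implements the four classic genome-context method
    families: phylogenetic profiles (Jaccard, Pearson, mutual information,
    hypergeometric p-value, weighted hypergeometric p-value, and the
    runs-corrected weighted p-value), gene neighbor (lnX, normalized lnX and
    the Gamma-tail p-value), gene cluster (normalized intergenic distance)
    and gene fusion (Rosetta-Stone hypergeometric p-value). Adds row-wise
    z-score and quantile normalization of pairwise score matrices with
    composed variants, reference-organism selection by profile clustering
    with distortion pruning, score combination by confidence-product and
    bagged decision trees with similarity-grouped cross-validation, ROC and
    top-percent evaluation utilities, and a synthetic pangenome generator
    that emulates the full input data model for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pROC,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
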