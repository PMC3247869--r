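#' Bundled table of example bacterial target genomes
#'
#' Gene counts and gold-standard sizes for ten well-curated bacterial
#' target genomes commonly used to benchmark genome-context methods:
#' total genes, genes with known function, small-molecule-enzyme genes,
#' the number of evaluation pairs among the sm-enzyme genes, the percent
#' of positive pairs among them, and a similarity weight to E. coli K-12.
#' For most rows the pair count equals e(e-1)/2 for e sm-enzyme genes;
#' the ECK12 and SHIG rows deviate slightly from that identity in the
#' original curation and are kept as printed.
#'
#' @return data.frame with columns `short_name`, `n_genes`,
#'   `n_known_function`, `n_sm_enzyme`, `n_pairs_sm`, `pct_positive`,
#'   `weight`.
#' @export
target_genome_table <- function() {
  utils::read.table(system.file("extdata", "target_genomes.tsv",
                                package = "genecontext"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
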