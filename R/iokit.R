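#' genecontext: genome context methods for functional-linkage prediction
#'
#' Tools to score gene pairs of a target genome for functional relatedness
#' from the genomic context of their homologs in a list of reference
#' genomes: phylogenetic-profile similarity, gene-neighbor distance
#' statistics, gene-cluster intergenic distance, Rosetta-Stone gene fusion,
#' score-matrix normalization, reference-organism selection, score
#' combination, evaluation utilities and a synthetic pangenome generator.
#'
#' All pairwise scores are stored in [score_matrix] objects that obey a
#' single orientation contract: higher always means more related. Methods
#' whose natural output runs the other way (p-values, distances) are negated
#' at the matrix boundary and each scorer documents its raw sign.
#'
#' @docType package
#' @name genecontext-package
#' @aliases genecontext
#' @import stats
#' @import utils
"_PACKAGE"

# ---------------------------------------------------------------------------
# Homology table ------------------------------------------------------------

#' Construct and validate a homology-hit table
#'
#' A homology table holds one record per (target gene, reference organism,
#' reference gene) BLAST-style hit, with the E-value of the match and the
#' percent of the target gene's sequence covered by it. It is the single
#' homology input consumed by the phylogenetic-profile, gene-neighbor and
#' gene-fusion scorers.
#'
#' @param df data.frame with columns `target_gene`, `organism`, `ref_gene`,
#'   `e_value`, `coverage_pct`.
#' @return the validated data.frame with class `homology_hits`.
#' @export
homology_hits <- function(df) {
  need <- c("target_gene", "organism", "ref_gene", "e_value", "coverage_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("homology table lacks column(s): ", paste(miss, collapse = ", "))
  df$target_gene <- as.character(df$target_gene)
  df$organism    <- as.character(df$organism)
  df$ref_gene    <- as.character(df$ref_gene)
  df$e_value     <- as.numeric(df$e_value)
  df$coverage_pct <- as.numeric(df$coverage_pct)
  if (anyNA(df$e_value) || any(df$e_value < 0))
    stop("e_value must be a non-negative number")
  if (anyNA(df$coverage_pct) || any(df$coverage_pct < 0 | df$coverage_pct > 100))
    stop("coverage_pct must lie in [0, 100]")
  class(df) <- c("homology_hits", "data.frame")
  df
}

#' Read a homology table from TSV
#'
#' Expects a tab-separated file with header
#' `target_gene organism ref_gene e_value coverage_pct`. Hits with
#' `e_value > e_cap` are dropped and duplicate (target gene, organism,
#' reference gene) rows are collapsed to the minimum E-value and maximum
#' coverage, the best-hit convention.
#'
#' Percent-similarity/identity pre-filters are assumed applied upstream by
#' whatever produced the table; only an optional coverage filter is exposed.
#'
#' @param path TSV file path.
#' @param e_cap drop hits with E-value above this cap (default `Inf`).
#' @param min_coverage optional coverage filter in percent (default 0).
#' @return a [homology_hits] data.frame.
#' @export
read_homology_table <- function(path, e_cap = Inf, min_coverage = 0) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  need <- c("target_gene", "organism", "ref_gene", "e_value", "coverage_pct")
  if (!all(need %in% names(raw)))
    stop("homology table header must contain: ", paste(need, collapse = ", "))
  ev <- suppressWarnings(as.numeric(raw$e_value))
  cv <- suppressWarnings(as.numeric(raw$coverage_pct))
  bad <- which(is.na(ev) | ev < 0 | is.na(cv) | cv < 0 | cv > 100)
  if (length(bad))
    stop("malformed homology row at line ", bad[1] + 1L,
         " (counting the header as line 1)")
  raw$e_value <- ev
  raw$coverage_pct <- cv
  raw <- raw[ev <= e_cap & cv >= min_coverage, , drop = FALSE]
  if (nrow(raw)) {
    key <- paste(raw$target_gene, raw$organism, raw$ref_gene, sep = "\r")
    ord <- order(key, raw$e_value, -raw$coverage_pct)
    raw <- raw[ord, , drop = FALSE]
    best_e  <- tapply(raw$e_value, key[ord], min)
    best_cv <- tapply(raw$coverage_pct, key[ord], max)
    raw <- raw[!duplicated(key[ord]), , drop = FALSE]
    k <- paste(raw$target_gene, raw$organism, raw$ref_gene, sep = "\r")
    raw$e_value <- as.numeric(best_e[k])
    raw$coverage_pct <- as.numeric(best_cv[k])
  }
  rownames(raw) <- NULL
  homology_hits(raw)
}

#' Write a homology table to TSV
#' @param hits a [homology_hits] data.frame.
#' @param path output file path.
#' @export
write_homology_table <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Genome annotation ----------------------------------------------------------

#' Construct a genome annotation
#'
#' Bundles per-gene records (coordinates, strand, and the 1-based rank of
#' each gene along its replicon by ascending start) with per-replicon
#' metadata (length and circularity). Coordinates are 1-based inclusive.
#'
#' @param genes data.frame with columns `gene_id`, `organism`, `replicon_id`,
#'   `start`, `end`, `strand`.
#' @param replicons data.frame with columns `replicon_id`, `organism`,
#'   `length_bases`, `circular`.
#' @return an object of class `genome_annotation`: a list with elements
#'   `genes` (ranks added) and `replicons`.
#' @export
genome_annotation <- function(genes, replicons) {
  need_g <- c("gene_id", "organism", "replicon_id", "start", "end", "strand")
  if (!all(need_g %in% names(genes)))
    stop("gene table lacks column(s): ",
         paste(setdiff(need_g, names(genes)), collapse = ", "))
  need_r <- c("replicon_id", "organism", "length_bases", "circular")
  if (!all(need_r %in% names(replicons)))
    stop("replicon table lacks column(s): ",
         paste(setdiff(need_r, names(replicons)), collapse = ", "))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  replicons$length_bases <- as.integer(replicons$length_bases)
  replicons$circular <- as.logical(replicons$circular)
  # span check
  for (r in unique(genes$replicon_id)) {
    len <- replicons$length_bases[match(r, replicons$replicon_id)]
    if (is.na(len)) stop("gene on unknown replicon: ", r)
    if (max(genes$end[genes$replicon_id == r]) > len)
      stop("replicon ", r, " shorter than the span of its genes")
  }
  genes <- assign_ranks(genes)
  structure(list(genes = genes, replicons = replicons),
            class = "genome_annotation")
}

# rank per replicon by ascending start; equal starts broken by gene_id
assign_ranks <- function(genes) {
  ord <- order(genes$replicon_id, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$replicon_id,
                           FUN = seq_along)
  rownames(genes) <- NULL
  genes
}

#' Read genome annotation from GFF3 or the internal TSV dialect
#'
#' For `dialect = "gff3"` the file must carry `##sequence-region` pragmas
#' (replicon lengths), optional `Is_circular=true` on region-type features,
#' and `gene` features with an `ID=` attribute; coordinates are the GFF3
#' 1-based inclusive convention. The internal TSV dialect is a single file
#' with `#replicon <TAB> replicon_id organism length_bases circular` header
#' lines followed by a gene table with header
#' `gene_id organism replicon_id start end strand`.
#'
#' @param path file path.
#' @param dialect `"gff3"` or `"tsv"`.
#' @param organism organism identifier; required for gff3 (a GFF3 file
#'   describes one genome), ignored for tsv (taken from the column).
#' @return a [genome_annotation].
#' @export
read_annotation <- function(path, dialect = c("tsv", "gff3"), organism = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") read_annotation_tsv(path) else
    read_annotation_gff3(path, organism)
}

read_annotation_tsv <- function(path) {
  lines <- readLines(path)
  rep_lines <- grep("^#replicon\t", lines, value = TRUE)
  if (!length(rep_lines)) stop("tsv annotation lacks #replicon header lines")
  rp <- do.call(rbind, strsplit(rep_lines, "\t", fixed = TRUE))
  replicons <- data.frame(replicon_id = rp[, 2], organism = rp[, 3],
                          length_bases = as.integer(rp[, 4]),
                          circular = as.logical(rp[, 5]),
                          stringsAsFactors = FALSE)
  body <- lines[!startsWith(lines, "#replicon\t")]
  genes <- utils::read.table(text = body, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "")
  if (any(!genes$strand %in% c("+", "-")))
    stop("missing or invalid strand in annotation")
  genome_annotation(genes, replicons)
}

read_annotation_gff3 <- function(path, organism) {
  if (is.null(organism)) stop("organism must be given for gff3 input")
  lines <- readLines(path)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(sr)) stop("gff3 file lacks ##sequence-region pragmas")
  srf <- strsplit(trimws(sr), "[ \t]+")
  replicons <- data.frame(
    replicon_id = vapply(srf, `[`, "", 2L),
    organism = organism,
    length_bases = as.integer(vapply(srf, `[`, "", 4L)),
    circular = FALSE, stringsAsFactors = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(body, "\t", fixed = TRUE)
  f <- f[lengths(f) == 9L]
  typ <- vapply(f, `[`, "", 3L)
  attr9 <- vapply(f, `[`, "", 9L)
  circ <- vapply(f, `[`, "", 1L)[typ %in% c("region", "chromosome") &
                                   grepl("Is_circular=true", attr9)]
  replicons$circular <- replicons$replicon_id %in% circ
  gi <- typ == "gene"
  if (!any(gi)) stop("gff3 file contains no gene features")
  ids <- sub(".*ID=([^;]+).*", "\\1", attr9[gi])
  strand <- vapply(f[gi], `[`, "", 7L)
  if (any(!strand %in% c("+", "-")))
    stop("gene feature with missing strand")
  genes <- data.frame(
    gene_id = ids, organism = organism,
    replicon_id = vapply(f[gi], `[`, "", 1L),
    start = as.integer(vapply(f[gi], `[`, "", 4L)),
    end = as.integer(vapply(f[gi], `[`, "", 5L)),
    strand = strand, stringsAsFactors = FALSE)
  genome_annotation(genes, replicons)
}

#' Write genome annotation in the internal TSV dialect
#' @param annotation a [genome_annotation].
#' @param path output file path.
#' @export
write_annotation <- function(annotation, path) {
  rp <- annotation$replicons
  hdr <- sprintf("#replicon\t%s\t%s\t%d\t%s", rp$replicon_id, rp$organism,
                 rp$length_bases, ifelse(rp$circular, "TRUE", "FALSE"))
  g <- annotation$genes[, c("gene_id", "organism", "replicon_id",
                            "start", "end", "strand")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(g, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Score matrices -------------------------------------------------------------

#' Construct a pairwise score matrix
#'
#' A `score_matrix` is a symmetric gene-by-gene real matrix with `NA` as the
#' missing-value sentinel and a fixed orientation: higher always means more
#' related. The diagonal is always missing. Raw row-normalized intermediates
#' (see [znorm_rows], [rnorm_rows]) may be asymmetric; every published
#' matrix is symmetric.
#'
#' @param values square numeric matrix with identical row and column gene
#'   names.
#' @param method short label for the scorer that produced it.
#' @param check validate symmetry of the non-missing pattern (default TRUE).
#' @return the matrix with class `score_matrix` and a `method` attribute.
#' @export
score_matrix <- function(values, method = "unknown", check = TRUE) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("score_matrix needs a square matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("score_matrix needs gene names as dimnames")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column gene order must agree")
  diag(values) <- NA_real_
  if (check && !isTRUE(all.equal(values, t(values))))
    stop("score matrix is not symmetric")
  structure(values, class = c("score_matrix", "matrix", "array"),
            method = method)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d genes, method '%s', %d scored pairs\n",
              nrow(x), attr(x, "method"),
              sum(!is.na(x[upper.tri(x)]))))
  invisible(x)
}

#' Genes of a score matrix
#' @param x a [score_matrix].
#' @return character vector of gene identifiers.
#' @export
score_genes <- function(x) rownames(x)

#' Extract upper-triangle pair scores from a score matrix
#'
#' @param x a [score_matrix] (or any symmetric matrix with gene dimnames).
#' @param drop_missing drop NA pairs (default FALSE).
#' @return data.frame `gene_a`, `gene_b`, `score` with `gene_a < gene_b`
#'   lexicographically.
#' @export
pair_scores <- function(x, drop_missing = FALSE) {
  g <- rownames(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  a <- g[ut[, 1]]; b <- g[ut[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b, score = x[ut],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  if (drop_missing) out <- out[!is.na(out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pair scores as long-format TSV
#'
#' Emits `gene_a gene_b score` rows with `gene_a < gene_b`
#' lexicographically. Missing pairs are omitted or written with a literal
#' `NA` according to `missing`.
#'
#' @param matrix a [score_matrix].
#' @param path output file path.
#' @param missing `"omit"` (default) or `"na"`.
#' @export
write_pair_scores <- function(matrix, path, missing = c("omit", "na")) {
  missing <- match.arg(missing)
  out <- pair_scores(matrix, drop_missing = missing == "omit")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pair scores written by [write_pair_scores]
#'
#' @param path TSV file with header `gene_a gene_b score`.
#' @param genes optional full gene list; defaults to the genes seen in the
#'   file. Pairs absent from the file are missing.
#' @param method label for the resulting matrix.
#' @return a [score_matrix].
#' @export
read_pair_scores <- function(path, genes = NULL, method = "file") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"),
                          quote = "", na.strings = "NA")
  if (is.null(genes)) genes <- sort(unique(c(df$gene_a, df$gene_b)))
  m <- matrix(NA_real_, length(genes), length(genes),
              dimnames = list(genes, genes))
  ia <- match(df$gene_a, genes); ib <- match(df$gene_b, genes)
  if (anyNA(ia) || anyNA(ib)) stop("pair file names a gene outside 'genes'")
  m[cbind(ia, ib)] <- df$score
  m[cbind(ib, ia)] <- df$score
  score_matrix(m, method = method)
}

#' Read a gold-standard pair-label file
#'
#' TSV with header `gene_a gene_b label`; label is `positive` or
#' `negative`. Self-pairs are an error; duplicate unordered pairs are an
#' error.
#'
#' @param path TSV file path.
#' @return data.frame `gene_a`, `gene_b`, `label` with class `pair_labels`,
#'   `gene_a < gene_b` lexicographically.
#' @export
read_pair_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  pair_labels(df)
}

#' Construct a pair-label table
#' @param df data.frame with columns `gene_a`, `gene_b`, `label`.
#' @return validated data.frame of class `pair_labels`.
#' @export
pair_labels <- function(df) {
  need <- c("gene_a", "gene_b", "label")
  if (!all(need %in% names(df)))
    stop("label table lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$gene_a == df$gene_b))
    stop("self-pair in label file: ", df$gene_a[df$gene_a == df$gene_b][1])
  if (!all(df$label %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  key <- paste(df$gene_a, df$gene_b)
  if (anyDuplicated(key)) stop("duplicate pair in label file")
  df <- df[order(df$gene_a, df$gene_b), c("gene_a", "gene_b", "label")]
  rownames(df) <- NULL
  class(df) <- c("pair_labels", "data.frame")
  df
}

#' Write pair labels as TSV
#' @param labels a [pair_labels] data.frame.
#' @param path output file path.
#' @export
write_pair_labels <- function(labels, path) {
  utils::write.table(as.data.frame(labels), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an organism list (one identifier per line)
#' @param path file path.
#' @return character vector of organism ids.
#' @export
read_organism_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_organism_list
#' @param organisms character vector to write.
#' @export
write_organism_list <- function(organisms, path) {
  writeLines(organisms, path)
  invisible(path)
}

#' Align a gold standard with a score matrix
#'
#' Looks up the score of every labeled pair whose genes are present in the
#' matrix. Missing scores are kept as `NA`; downstream evaluation ranks
#' them last.
#'
#' @param matrix a [score_matrix].
#' @param labels a [pair_labels] table.
#' @return list with `score`, `label` (0/1), `gene_a`, `gene_b`.
#' @export
match_scores_labels <- function(matrix, labels) {
  g <- rownames(matrix)
  keep <- labels$gene_a %in% g & labels$gene_b %in% g
  lab <- labels[keep, , drop = FALSE]
  s <- matrix[cbind(match(lab$gene_a, g), match(lab$gene_b, g))]
  list(score = s, label = as.integer(lab$label == "positive"),
       gene_a = lab$gene_a, gene_b = lab$gene_b)
}
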