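# Restricted-coverage methods: gene cluster and gene fusion.
#
# Gene cluster scores only pairs that are adjacent in rank and transcribed
# on the same strand of the target genome; gene fusion scores only pairs
# for which a Rosetta-Stone fused gene exists in some reference genome.
# All other pairs carry the missing sentinel, semantically "infinitely
# distant" (gc) or "p-value 1" (gf).

#' Intergenic normalization factor of a genome
#'
#' `m` = number of genes divided by the total number of intergenic bases.
#' Gaps are measured between consecutive genes per replicon (by rank);
#' circular replicons include the wrap-around gap; overlapping genes
#' contribute a gap of 0. Multiplying a base distance by m makes it
#' genome-independent.
#'
#' @param annotation a [genome_annotation].
#' @return positive real m.
#' @export
intergenic_factor <- function(annotation) {
  g <- annotation$genes
  if (nrow(g) < 2) stop("need at least 2 genes")
  total_gap <- 0
  for (rep_id in unique(g$replicon_id)) {
    gr <- g[g$replicon_id == rep_id, , drop = FALSE]
    gr <- gr[order(gr$rank), , drop = FALSE]
    if (nrow(gr) >= 2)
      total_gap <- total_gap +
        sum(pmax(0, gr$start[-1] - gr$end[-nrow(gr)] - 1))
    rp <- annotation$replicons
    if (rp$circular[match(rep_id, rp$replicon_id)] && nrow(gr) >= 1) {
      len <- rp$length_bases[match(rep_id, rp$replicon_id)]
      total_gap <- total_gap +
        max(0, (len - gr$end[nrow(gr)]) + (gr$start[1] - 1))
    }
  }
  if (total_gap <= 0) stop("genome has no intergenic bases")
  nrow(g) / total_gap
}

#' Gene-cluster scores (restricted coverage)
#'
#' For each pair of genes adjacent in rank on the same replicon and coded
#' on the same strand, the raw score is the intergenic distance in bases
#' multiplied by the genome factor m (see [intergenic_factor]); smaller
#' means more related, so the stored value is negated. Circular replicons
#' include the wrap-around adjacency. All other pairs are missing. For an
#' N-gene single-replicon genome at most N pairs are scored.
#'
#' @param annotation target-genome [genome_annotation].
#' @return a [score_matrix] over the target genes.
#' @export
gene_cluster_scores <- function(annotation) {
  g <- annotation$genes
  m_fac <- intergenic_factor(annotation)
  genes <- sort(g$gene_id)
  n <- length(genes)
  out <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (rep_id in unique(g$replicon_id)) {
    gr <- g[g$replicon_id == rep_id, , drop = FALSE]
    gr <- gr[order(gr$rank), , drop = FALSE]
    k <- nrow(gr)
    if (k < 2) next
    rp <- annotation$replicons
    circ <- rp$circular[match(rep_id, rp$replicon_id)]
    len <- rp$length_bases[match(rep_id, rp$replicon_id)]
    i1 <- seq_len(k - 1); i2 <- i1 + 1L
    gap <- pmax(0, gr$start[i2] - gr$end[i1] - 1)
    same <- gr$strand[i1] == gr$strand[i2]
    if (circ && k >= 2) {
      i1 <- c(i1, k); i2 <- c(i2, 1L)
      gap <- c(gap, max(0, (len - gr$end[k]) + (gr$start[1] - 1)))
      same <- c(same, gr$strand[k] == gr$strand[1])
    }
    sel <- which(same)
    if (!length(sel)) next
    ia <- match(gr$gene_id[i1[sel]], genes)
    ib <- match(gr$gene_id[i2[sel]], genes)
    v <- -(gap[sel] * m_fac)
    out[cbind(ia, ib)] <- pmax(out[cbind(ia, ib)], v, na.rm = TRUE)
    out[cbind(ib, ia)] <- out[cbind(ia, ib)]
  }
  score_matrix(out, method = "gc")
}

#' Find Rosetta-Stone fusion candidates for a gene pair
#'
#' A reference gene is a Rosetta Stone for target genes g1 and g2 when both
#' hit it with coverage >= Q percent of each query and E-value <= E (both
#' thresholds inclusive).
#'
#' @param hits a [homology_hits] table.
#' @param g1,g2 distinct target gene ids.
#' @param Q minimum percent coverage, in (0, 100\] (default 50).
#' @param E maximum E-value (default 1e-4).
#' @return data.frame `ref_gene, organism, cov1, cov2, e1, e2`, zero rows
#'   when no candidate exists.
#' @export
find_rosetta <- function(hits, g1, g2, Q = 50, E = 1e-4) {
  if (g1 == g2) stop("g1 and g2 must differ")
  if (Q <= 0 || Q > 100) stop("Q must lie in (0, 100]")
  h <- hits[hits$e_value <= E & hits$coverage_pct >= Q &
              hits$target_gene %in% c(g1, g2), , drop = FALSE]
  h1 <- h[h$target_gene == g1, , drop = FALSE]
  h2 <- h[h$target_gene == g2, , drop = FALSE]
  k1 <- paste(h1$organism, h1$ref_gene, sep = "\r")
  k2 <- paste(h2$organism, h2$ref_gene, sep = "\r")
  shared <- intersect(k1, k2)
  if (!length(shared))
    return(data.frame(ref_gene = character(0), organism = character(0),
                      cov1 = numeric(0), cov2 = numeric(0),
                      e1 = numeric(0), e2 = numeric(0)))
  i1 <- match(shared, k1); i2 <- match(shared, k2)
  data.frame(ref_gene = h1$ref_gene[i1], organism = h1$organism[i1],
             cov1 = h1$coverage_pct[i1], cov2 = h2$coverage_pct[i2],
             e1 = h1$e_value[i1], e2 = h2$e_value[i2],
             stringsAsFactors = FALSE)
}

#' Hypergeometric p-value for the observed number of fusions
#'
#' Out of K candidate reference genes, g1 matches n1 of them and g2 matches
#' n2; f were matched by both (Rosetta Stones). The p-value is the
#' upper-tail hypergeometric probability `P(overlap >= f)`, which penalizes
#' pairs whose fusions could arise by chance from promiscuous matching.
#'
#' @param K total candidate genes scanned across reference genomes.
#' @param n1,n2 genes matched by each target gene alone at (Q, E).
#' @param f observed Rosetta-Stone count.
#' @return value in (0, 1\]. Raw sign: small = more related.
#' @export
gene_fusion_pval <- function(K, n1, n2, f) {
  if (f > min(n1, n2) || max(n1, n2) > K || min(K, n1, n2, f) < 0)
    stop("inconsistent counts: need f <= min(n1, n2) <= K")
  stats::phyper(f - 1, n1, K - n1, n2, lower.tail = FALSE)
}

#' Gene-fusion scores (restricted coverage)
#'
#' Pairs with at least one Rosetta Stone get the negated fusion p-value
#' (higher = more related); all other pairs are missing, semantically a
#' p-value of 1. K is the total number of reference genes matched by any
#' target gene at (Q, E), n1/n2 the per-gene match counts, f the shared
#' count.
#'
#' @param hits a [homology_hits] table.
#' @param genes character vector of target genes (matrix order).
#' @param Q,E Rosetta-Stone thresholds (defaults 50, 1e-4).
#' @param K_total optional override for the candidate universe size K;
#'   defaults to the number of distinct (organism, ref gene) entries
#'   matched by any target gene at (Q, E).
#' @return a [score_matrix].
#' @export
score_all_pairs_gf <- function(hits, genes, Q = 50, E = 1e-4,
                               K_total = NULL) {
  h <- hits[hits$e_value <= E & hits$coverage_pct >= Q &
              hits$target_gene %in% genes, , drop = FALSE]
  n <- length(genes)
  out <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  if (nrow(h)) {
    key <- paste(h$organism, h$ref_gene, sep = "\r")
    K <- if (is.null(K_total)) length(unique(key)) else K_total
    counts <- table(h$target_gene)
    # ref genes matched by >= 2 target genes are fusion candidates
    split_by_ref <- split(h$target_gene, key)
    multi <- split_by_ref[lengths(split_by_ref) >= 2]
    if (length(multi)) {
      fcount <- new.env(parent = emptyenv())
      for (tg in multi) {
        tg <- unique(tg)
        if (length(tg) < 2) next
        cmb <- utils::combn(sort(tg), 2)
        for (c_i in seq_len(ncol(cmb))) {
          k <- paste(cmb[1, c_i], cmb[2, c_i], sep = "\r")
          assign(k, get0(k, envir = fcount, ifnotfound = 0L) + 1L,
                 envir = fcount)
        }
      }
      for (k in ls(fcount)) {
        pr <- strsplit(k, "\r", fixed = TRUE)[[1]]
        f <- get(k, envir = fcount)
        n1 <- as.integer(counts[pr[1]]); n2 <- as.integer(counts[pr[2]])
        pv <- gene_fusion_pval(K, n1, n2, min(f, n1, n2))
        ia <- match(pr[1], genes); ib <- match(pr[2], genes)
        out[ia, ib] <- -pv
        out[ib, ia] <- -pv
      }
    }
  }
  score_matrix(out, method = "gf")
}
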