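# Gene-neighbor scores.
#
# For a pair of target genes, each reference genome containing homologs of
# both contributes the relative rank distance between the closest homologs.
# Under independence the relative distance is uniform on (0, 1], so the
# product over genomes yields the lnX statistic and a Gamma-tail p-value.

#' Minimum rank distance between the homologs of two genes
#'
#' Distance is measured in genes: the number of genes between the two
#' homologs plus one, so adjacent genes are at distance 1. On a circular
#' replicon the shorter arc is used. When the two genes share the same
#' homolog the distance is defined to be 1 (never 0). With several homologs
#' per gene, the minimum over all homolog pairs is taken.
#'
#' @param g1_ranks,g2_ranks integer rank positions of the homologs of each
#'   gene on one replicon.
#' @param n_replicon number of genes on that replicon (wrap modulus).
#' @param circular is the replicon circular?
#' @return integer distance >= 1.
#' @export
pair_rank_distance <- function(g1_ranks, g2_ranks, n_replicon,
                               circular = TRUE) {
  if (!length(g1_ranks) || !length(g2_ranks))
    stop("both rank sets must be non-empty")
  d <- abs(outer(g1_ranks, g2_ranks, "-"))
  if (circular) d <- pmin(d, n_replicon - d)
  max(1L, min(d))
}

#' Relative distance under the uniform null
#'
#' On a circular chromosome of N genes the distance between two independent
#' genes is uniform on 1..(N-1)/2, so `p = 2d/(N-1)`, clipped to 1 when d
#' exceeds (N-1)/2. On a linear replicon the support is 1..(N-1) and
#' `p = d/(N-1)`.
#'
#' @param d rank distance >= 1.
#' @param N genes in the genome.
#' @param circular circular-null form (default TRUE).
#' @return p in (0, 1\], or NA with a warning when N < 3.
#' @export
relative_distance <- function(d, N, circular = TRUE) {
  if (N < 3) {
    warning("genome with fewer than 3 genes skipped")
    return(NA_real_)
  }
  p <- if (circular) 2 * d / (N - 1) else d / (N - 1)
  min(p, 1)
}

#' Gamma-tail p-value for a product of uniforms
#'
#' If X is the product of `M_tilde` independent Uniform(0,1) variables then
#' -log X is Gamma(shape = M_tilde, scale = 1), and
#' `P(X <= x) = x * sum_{k=0}^{M_tilde-1} (-log x)^k / k!`, the regularized
#' upper incomplete gamma function, evaluated here through
#' `pgamma(..., lower.tail = FALSE)` for log-space stability.
#'
#' @param x observed product in (0, 1\].
#' @param M_tilde number of factors (genomes with both homologs).
#' @return value in (0, 1\]; `x = 0` returns 0 with a warning.
#' @export
gamma_tail <- function(x, M_tilde) {
  if (M_tilde < 1) stop("M_tilde must be >= 1")
  if (x < 0 || x > 1) stop("x must lie in (0, 1]")
  if (x == 0) {
    warning("x = 0: returning 0 by continuity")
    return(0)
  }
  gamma_tail_nlx(-log(x), M_tilde)
}

# same, parameterized by -log(x) to avoid underflow for large lnX
gamma_tail_nlx <- function(nlx, M_tilde) {
  stats::pgamma(nlx, shape = M_tilde, lower.tail = FALSE)
}

#' Gene-neighbor scores from per-genome evidence
#'
#' @param p numeric vector of relative distances in (0, 1\], one per genome
#'   containing homologs of both genes.
#' @return list with `M_tilde`, `lnX` (= sum of -log p), `norm_lnX`
#'   (= lnX / M_tilde) and `pval` (Gamma tail of the product). Raw signs:
#'   lnX and norm_lnX are higher = more related, pval smaller = more
#'   related.
#' @export
gn_scores <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no neighbor evidence; the pair has a missing score")
  if (any(p <= 0 | p > 1)) stop("relative distances must lie in (0, 1]")
  lnX <- sum(-log(p))
  M <- length(p)
  list(M_tilde = M, lnX = lnX, norm_lnX = lnX / M,
       pval = gamma_tail_nlx(lnX, M))
}

# Per-organism homolog placements: returns data.frame
# (target_gene, replicon_id, rank, n_replicon, circular) for one organism
homolog_placements <- function(hits, annotation, organism, e_threshold) {
  h <- hits[hits$organism == organism & hits$e_value < e_threshold, ,
            drop = FALSE]
  if (!nrow(h)) return(NULL)
  g <- annotation$genes
  idx <- match(h$ref_gene, g$gene_id)
  keep <- !is.na(idx)
  if (!any(keep)) return(NULL)
  h <- h[keep, , drop = FALSE]; idx <- idx[keep]
  rep_sizes <- table(g$replicon_id)
  rp <- annotation$replicons
  data.frame(target_gene = h$target_gene,
             replicon_id = g$replicon_id[idx],
             rank = g$rank[idx],
             n_replicon = as.integer(rep_sizes[g$replicon_id[idx]]),
             circular = rp$circular[match(g$replicon_id[idx],
                                          rp$replicon_id)],
             stringsAsFactors = FALSE)
}

#' Score all gene pairs with a gene-neighbor variant
#'
#' For every pair of target genes, each reference genome in which both have
#' homologs on a common replicon contributes the minimum rank distance
#' between their homologs; an organism whose homologs sit only on different
#' replicons contributes no evidence (the uniform null assumes a single
#' chromosome). Pairs with no contributing genome carry the missing
#' sentinel.
#'
#' Orientation: `lnX` and `norm-lnX` are stored as-is (higher = more
#' related); `pval` is stored negated.
#'
#' @param hits a [homology_hits] table.
#' @param annotations named list of [genome_annotation], one per reference
#'   organism (names = organism ids).
#' @param genes character vector of target genes (matrix order).
#' @param e_threshold homology E-value threshold (default 1e-4).
#' @param variant `"lnX"`, `"norm-lnX"` or `"pval"`.
#' @param null `"circular"` (default, p = 2d/(N-1)) or `"linear"`
#'   (p = d/(N-1)) uniform null for the relative distance.
#' @return a [score_matrix].
#' @export
score_all_pairs_gn <- function(hits, annotations, genes,
                               e_threshold = 1e-4,
                               variant = c("pval", "lnX", "norm-lnX"),
                               null = c("circular", "linear")) {
  variant <- match.arg(variant)
  null <- match.arg(null)
  n <- length(genes)
  lnX <- matrix(0, n, n, dimnames = list(genes, genes))
  Mt <- matrix(0L, n, n, dimnames = list(genes, genes))
  for (org in names(annotations)) {
    pl <- homolog_placements(hits, annotations[[org]], org, e_threshold)
    if (is.null(pl)) next
    pl <- pl[pl$target_gene %in% genes, , drop = FALSE]
    if (nrow(pl) < 2) next
    N <- nrow(annotations[[org]]$genes)
    if (N < 3) next
    # min distance per gene pair, over replicons and homolog pairs
    ev <- list()
    for (rep_id in unique(pl$replicon_id)) {
      pr <- pl[pl$replicon_id == rep_id, , drop = FALSE]
      if (nrow(pr) < 2) next
      dmat <- abs(outer(pr$rank, pr$rank, "-"))
      if (pr$circular[1]) dmat <- pmin(dmat, pr$n_replicon[1] - dmat)
      ii <- which(upper.tri(dmat), arr.ind = TRUE)
      gi <- match(pr$target_gene, genes)
      ga <- gi[ii[, 1]]; gb <- gi[ii[, 2]]
      ok <- ga != gb
      if (!any(ok)) next
      ev[[length(ev) + 1]] <- cbind(pmin(ga, gb)[ok], pmax(ga, gb)[ok],
                                    pmax(1L, dmat[ii])[ok])
    }
    if (!length(ev)) next
    ev <- do.call(rbind, ev)
    key <- (ev[, 1] - 1) * n + ev[, 2]          # integer pair key
    if (anyDuplicated(key)) {
      agg <- tapply(ev[, 3], key, min)
      key <- as.numeric(names(agg))
      d <- as.numeric(agg)
      ia <- (key - 1) %/% n + 1; ib <- key - (ia - 1) * n
    } else {
      ia <- ev[, 1]; ib <- ev[, 2]; d <- ev[, 3]
    }
    p <- if (null == "circular") pmin(2 * d / (N - 1), 1) else
      pmin(d / (N - 1), 1)
    idx <- cbind(ia, ib)
    lnX[idx] <- lnX[idx] + (-log(p))
    Mt[idx] <- Mt[idx] + 1L
  }
  lnX <- lnX + t(lnX); Mt <- Mt + t(Mt)
  out <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  scored <- Mt > 0
  out[scored] <- switch(variant,
    "lnX" = lnX[scored],
    "norm-lnX" = lnX[scored] / Mt[scored],
    "pval" = -gamma_tail_nlx(lnX[scored], Mt[scored]))
  score_matrix(out, method = paste0("gn-", variant))
}
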