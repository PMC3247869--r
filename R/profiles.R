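# Phylogenetic-profile scores.
#
# A phylogenetic profile is the binary presence/absence vector of a gene's
# homologs across the reference organism list. Rows of the profile matrix
# are gene profiles; columns are organism profiles. Six pairwise similarity
# metrics are implemented: Jaccard, Pearson, mutual information,
# hypergeometric p-value, weighted hypergeometric p-value, and the weighted
# p-value corrected by a runs statistic on the ordered product profile.

#' Build the phylogenetic-profile matrix
#'
#' An entry is 1 iff some homology hit for that (gene, organism) has E-value
#' strictly below `e_threshold`. The strict inequality is deliberate:
#' boundary hits are excluded from the homology call.
#'
#' @param hits a [homology_hits] table.
#' @param genes character vector of target genes (matrix row order).
#' @param organisms character vector of reference organisms (column order).
#' @param e_threshold homology E-value threshold; default `1e-4`.
#' @return binary matrix genes x organisms with class `profile_matrix`.
#' @export
build_profiles <- function(hits, genes, organisms, e_threshold = 1e-4) {
  if (!length(organisms)) stop("organism list is empty")
  if (!length(genes)) stop("gene list is empty")
  m <- matrix(0L, length(genes), length(organisms),
              dimnames = list(genes, organisms))
  h <- hits[hits$e_value < e_threshold &
              hits$target_gene %in% genes &
              hits$organism %in% organisms, , drop = FALSE]
  if (nrow(h))
    m[cbind(match(h$target_gene, genes), match(h$organism, organisms))] <- 1L
  structure(m, class = c("profile_matrix", "matrix", "array"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d genes x %d organisms, density %.3f\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' 2x2 contingency counts for a profile pair
#'
#' @param p1,p2 binary vectors of equal length M.
#' @return list with `M`, `n1_1`, `n2_1` (ones per profile) and `n12`, the
#'   2x2 table indexed `[x+1, y+1]` for x,y in \{0,1\}.
#' @export
pair_counts <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("profiles differ in length")
  M <- length(p1)
  n11 <- sum(p1 == 1 & p2 == 1)
  n10 <- sum(p1 == 1 & p2 == 0)
  n01 <- sum(p1 == 0 & p2 == 1)
  n00 <- M - n11 - n10 - n01
  n12 <- matrix(c(n00, n10, n01, n11), 2, 2,
                dimnames = list(x = c("0", "1"), y = c("0", "1")))
  list(M = M, n1_1 = n11 + n10, n2_1 = n11 + n01, n12 = n12)
}

#' Jaccard similarity of two profiles
#'
#' `n12(1,1) / (M - n12(0,0))`; defined as 0 when both profiles are empty
#' (no evidence).
#'
#' @param counts output of [pair_counts].
#' @return value in \[0, 1\].
#' @export
pp_jaccard <- function(counts) {
  den <- counts$M - counts$n12["0", "0"]
  if (den == 0) return(0)
  unname(counts$n12["1", "1"] / den)
}

#' Pearson correlation of two binary profiles
#'
#' Standard Pearson correlation; 0 if either profile is constant (no
#' evidence rather than NaN).
#'
#' @param p1,p2 binary vectors of equal length.
#' @return value in \[-1, 1\].
#' @export
pp_pearson <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("profiles differ in length")
  if (stats::var(p1) == 0 || stats::var(p2) == 0) return(0)
  stats::cor(p1, p2)
}

#' Mutual information of two profiles (nats)
#'
#' Plug-in mutual information of the empirical 2x2 joint distribution, in
#' natural log units; `0 * log(0/...)` terms contribute 0.
#'
#' @param counts output of [pair_counts].
#' @return value >= 0.
#' @export
pp_mutual_info <- function(counts) {
  M <- counts$M
  joint <- counts$n12 / M
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
  }
  max(unname(mi), 0)
}

#' Hypergeometric p-value of observed profile overlap
#'
#' Upper-tail probability of seeing at least the observed number of common
#' ones when `n1_1` and `n2_1` ones are placed independently at random in M
#' organisms: `P(overlap >= n12(1,1))`. Raw sign: small = more related; the
#' matrix boundary negates it.
#'
#' @param counts output of [pair_counts].
#' @return value in (0, 1\].
#' @export
pp_hypergeom_pval <- function(counts) {
  n11 <- unname(counts$n12["1", "1"])
  stats::phyper(n11 - 1, counts$n1_1, counts$M - counts$n1_1, counts$n2_1,
                lower.tail = FALSE)
}

#' Per-organism weights for the weighted p-value
#'
#' The weight of organism i is the fraction of all target genes contained
#' in genome i, i.e. the column mean of the full profile matrix. Build the
#' profile matrix over the full target gene set, not a subset.
#'
#' @param profiles a [build_profiles] matrix.
#' @return named numeric vector in \[0, 1\].
#' @export
organism_weights <- function(profiles) {
  colMeans(profiles)
}

#' Weighted hypergeometric p-value
#'
#' Relaxes the equal-probability assumption of [pp_hypergeom_pval]:
#' organism i contains a homolog of either gene independently with
#' probability `w_i`. The p-value is
#' `P(co-occurrences >= observed | ones in p1 = n1, ones in p2 = n2)` under
#' that independent-Bernoulli model, computed by a dynamic program over
#' organisms that accumulates the joint law of (ones in p1, ones in p2,
#' co-occurrences) and then conditions on the observed margins. With all
#' weights equal this reduces exactly to the hypergeometric p-value.
#'
#' Weights are clamped to `[1e-6, 1 - 1e-6]` to avoid the underflow that
#' extreme weights cause.
#'
#' @param p1,p2 binary profiles.
#' @param weights per-organism weights (same length).
#' @return value in (0, 1\]. Raw sign: small = more related.
#' @export
pp_weighted_pval <- function(p1, p2, weights) {
  if (length(p1) != length(p2) || length(p1) != length(weights))
    stop("profiles and weights differ in length")
  w <- pmin(pmax(weights, 1e-6), 1 - 1e-6)
  if (length(unique(w)) == 1L && (w[1] <= 1e-6 || w[1] >= 1 - 1e-6))
    warning("all weights at the clamping boundary; p-value may be degenerate")
  cts <- pair_counts(p1, p2)
  n1 <- cts$n1_1; n2 <- cts$n2_1; n11 <- unname(cts$n12["1", "1"])
  if (n11 == 0) return(1)
  # dp[a+1, b+1, c+1] = P(sum x = a, sum y = b, sum xy = c) after processed
  # organisms; x,y ~ Bern(w_i) independent
  dp <- array(0, dim = c(n1 + 1L, n2 + 1L, min(n1, n2) + 1L))
  dp[1, 1, 1] <- 1
  for (wi in w) {
    q00 <- (1 - wi)^2; q10 <- wi * (1 - wi); q11 <- wi^2
    new <- dp * q00
    na <- dim(dp)[1]; nb <- dim(dp)[2]; nc <- dim(dp)[3]
    new[2:na, , ]        <- new[2:na, , ]        + dp[1:(na - 1), , ] * q10
    new[, 2:nb, ]        <- new[, 2:nb, ]        + dp[, 1:(nb - 1), ] * q10
    new[2:na, 2:nb, 2:nc] <- new[2:na, 2:nb, 2:nc] +
      dp[1:(na - 1), 1:(nb - 1), 1:(nc - 1)] * q11
    dp <- new
  }
  cond <- dp[n1 + 1L, n2 + 1L, ]
  tot <- sum(cond)
  if (tot <= 0) return(1)
  min(1, max(sum(cond[(n11 + 1L):length(cond)]) / tot, .Machine$double.xmin))
}

#' Count runs of consecutive ones
#'
#' Number of maximal blocks of consecutive 1s in a binary vector, treated
#' as linear (non-circular). For the runs correction the vector should be a
#' product profile ordered by the swiveled leaf order
#' (see [swivel_leaf_order]).
#'
#' @param x binary vector.
#' @return integer >= 0.
#' @export
count_runs <- function(x) {
  x <- as.integer(x != 0)
  if (!length(x)) return(0L)
  sum(x == 1L & c(0L, x[-length(x)]) == 0L)
}

#' Runs-statistic p-value
#'
#' Tail probability `P(R >= r_obs)` of the number of runs of ones when k
#' ones are placed uniformly at random in M linear positions. The number of
#' arrangements with exactly r runs is `C(k-1, r-1) * C(M-k+1, r)`. Many
#' runs mean co-occurrence scattered across the phylogeny, i.e. stronger
#' independent evidence, which fixes the upper tail. `k = 0` returns 1.
#'
#' @param M positions (organisms).
#' @param k number of ones.
#' @param r_obs observed run count.
#' @return value in (0, 1\].
#' @export
runs_pvalue <- function(M, k, r_obs) {
  if (k < 0 || k > M) stop("k must lie in [0, M]")
  if (k == 0) return(1)
  rmax <- min(k, M - k + 1L)
  if (r_obs <= 1) return(1)
  # beyond the support the exact tail has zero mass; the final max() floors
  # it at the smallest positive double so the score never degenerates
  r <- if (r_obs > rmax) integer(0) else seq.int(r_obs, rmax)
  tail_count <- sum(choose(k - 1, r - 1) * choose(M - k + 1, r))
  p <- tail_count / choose(M, k)
  min(1, max(p, .Machine$double.xmin))
}

#' Weighted p-value with runs correction
#'
#' Ratio of the weighted hypergeometric p-value to the runs p-value of the
#' product profile reordered by `leaf_order`. A product profile whose ones
#' are scattered over the phylogeny (many runs, small runs p-value) is
#' stronger evidence than one with a single clump. Raw sign: small = more
#' related.
#'
#' @param p1,p2 binary profiles (named by organism if `leaf_order` is a
#'   character vector).
#' @param weights per-organism weights.
#' @param leaf_order organism ordering from [swivel_leaf_order]: integer
#'   indices or organism names.
#' @return positive real (can exceed 1 when the runs p-value is small).
#' @export
pp_wpval_with_runs <- function(p1, p2, weights, leaf_order) {
  if (is.character(leaf_order)) {
    if (is.null(names(p1))) stop("profiles must be named to use a named leaf order")
    leaf_order <- match(leaf_order, names(p1))
  }
  prod_pp <- (p1 * p2)[leaf_order]
  if (anyNA(prod_pp)) stop("leaf_order does not match the profiles")
  wp <- pp_weighted_pval(p1, p2, weights)
  rp <- runs_pvalue(length(prod_pp), sum(prod_pp), count_runs(prod_pp))
  wp / rp
}

#' Score all gene pairs with a phylogenetic-profile metric
#'
#' Returns a symmetric [score_matrix] with the orientation contract applied:
#' similarity metrics (jaccard, pearson, mutual-info) are stored as-is;
#' p-value metrics are stored negated so that higher always means more
#' related.
#'
#' @param profiles a [build_profiles] matrix.
#' @param metric one of `"jaccard"`, `"pearson"`, `"mutual-info"`, `"pval"`,
#'   `"wpval"`, `"wpval-with-runs"`.
#' @param weights per-organism weights; required for the wpval metrics
#'   (see [organism_weights]).
#' @param leaf_order organism ordering; required for `"wpval-with-runs"`.
#' @return a [score_matrix].
#' @export
score_all_pairs_pp <- function(profiles,
                               metric = c("jaccard", "pearson", "mutual-info",
                                          "pval", "wpval", "wpval-with-runs"),
                               weights = NULL, leaf_order = NULL) {
  metric <- match.arg(metric)
  if (metric %in% c("wpval", "wpval-with-runs") && is.null(weights))
    stop("metric '", metric, "' needs organism weights")
  if (metric == "wpval-with-runs" && is.null(leaf_order))
    stop("metric 'wpval-with-runs' needs a leaf order")
  if (is.character(leaf_order))
    leaf_order <- match(leaf_order, colnames(profiles))
  genes <- rownames(profiles)
  n <- length(genes)
  m <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1)) {
    p1 <- profiles[i, ]
    for (j in (i + 1):n) {
      p2 <- profiles[j, ]
      v <- switch(metric,
        "jaccard"     = pp_jaccard(pair_counts(p1, p2)),
        "pearson"     = pp_pearson(p1, p2),
        "mutual-info" = pp_mutual_info(pair_counts(p1, p2)),
        "pval"        = -pp_hypergeom_pval(pair_counts(p1, p2)),
        "wpval"       = -pp_weighted_pval(p1, p2, weights),
        "wpval-with-runs" = -pp_wpval_with_runs(p1, p2, weights, leaf_order))
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  score_matrix(m, method = paste0("pp-", metric))
}
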