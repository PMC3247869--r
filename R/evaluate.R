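# Evaluation against a gold standard of functionally related gene pairs.
#
# Scores obey the orientation contract (higher = more related). Pairs with
# a missing score are ranked last, after every scored pair: a
# restricted-coverage method's unscored pairs can never enter a selected
# top set before any scored pair.

#' All unordered gene pairs
#'
#' @param genes character vector (>= 2 genes).
#' @return data.frame `gene_a`, `gene_b` with `gene_a < gene_b`; the row
#'   count is e(e-1)/2 for e genes.
#' @export
enumerate_pairs <- function(genes) {
  if (length(genes) < 2) stop("need at least 2 genes")
  genes <- sort(genes)
  cmb <- utils::combn(genes, 2)
  data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
}

# order scores best-first with the missing-last rule and a stable pair-id
# tie-break; returns the permutation
order_scores <- function(scores, pair_id = seq_along(scores)) {
  key <- ifelse(is.na(scores), -Inf, scores)
  order(-key, pair_id)
}

#' Confusion counts and rates at a score threshold
#'
#' A pair is called positive iff its score is >= t; missing scores never
#' reach any finite threshold.
#'
#' @param scores numeric, higher = more related; NA = missing.
#' @param labels 0/1 (or logical) true labels.
#' @param t threshold.
#' @return list `tp, fp, tn, fn, sensitivity (tp/p), specificity (tn/n)`.
#' @export
confusion_at_threshold <- function(scores, labels, t) {
  labels <- as.integer(labels)
  p <- sum(labels == 1); n <- sum(labels == 0)
  if (p == 0 || n == 0)
    stop("need both positive and negative pairs to compute rates")
  call_pos <- !is.na(scores) & scores >= t
  tp <- sum(call_pos & labels == 1)
  fp <- sum(call_pos & labels == 0)
  list(tp = tp, fp = fp, tn = n - fp, fn = p - tp,
       sensitivity = tp / p, specificity = (n - fp) / n)
}

#' ROC curve over all score thresholds
#'
#' One point per distinct score value plus the two endpoints. Tied scores
#' move together: no ordering is imposed within a tie. Missing scores form
#' the final (worst) block.
#'
#' @param scores numeric, higher = more related; NA = missing.
#' @param labels 0/1 true labels.
#' @return data.frame `threshold`, `sensitivity`, `specificity`;
#'   sensitivity is non-decreasing (and specificity non-increasing) as the
#'   threshold decreases down the rows.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  p <- sum(labels == 1); n <- sum(labels == 0)
  if (p == 0 || n == 0)
    stop("need both positive and negative pairs to compute a ROC curve")
  s <- ifelse(is.na(scores), -Inf, scores)
  ord <- order(-s)
  s <- s[ord]; lab <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)      # last row of each tie block
  tp <- cumsum(lab)[keep]
  fp <- cumsum(1 - lab)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             sensitivity = c(0, tp / p),
             specificity = c(1, 1 - fp / n))
}

#' Area under the ROC curve
#' @param scores,labels as in [roc_curve].
#' @return AUROC in \[0, 1\] (trapezoidal, ties handled by the curve).
#' @export
auroc <- function(scores, labels) {
  r <- roc_curve(scores, labels)
  x <- 1 - r$specificity; y <- r$sensitivity
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Sensitivity when the top p percent of pairs are called positive
#'
#' Selects the k = round(p% of all pairs) best-scoring pairs (missing
#' scores last; ties at the cut resolved by stable pair-id order) and
#' returns the fraction of all positives captured.
#'
#' @param scores,labels as in [roc_curve].
#' @param p_pct percent in (0, 100\].
#' @return sensitivity tp / p_total.
#' @export
sensitivity_at_top <- function(scores, labels, p_pct) {
  if (p_pct <= 0 || p_pct > 100) stop("p_pct must lie in (0, 100]")
  labels <- as.integer(labels)
  k <- round(p_pct / 100 * length(scores))
  k <- max(1L, min(k, length(scores)))
  sel <- order_scores(scores)[seq_len(k)]
  sum(labels[sel] == 1) / sum(labels == 1)
}

#' Precision (cumulative accuracy) in the top p percent
#' @param scores,labels as in [roc_curve].
#' @param p_pct percent in (0, 100\].
#' @return fraction of true positives among the selected pairs.
#' @export
precision_at_top <- function(scores, labels, p_pct) {
  labels <- as.integer(labels)
  k <- max(1L, min(round(p_pct / 100 * length(scores)), length(scores)))
  sel <- order_scores(scores)[seq_len(k)]
  mean(labels[sel] == 1)
}

#' Cumulative accuracy step function
#'
#' Maps each distinct score value t to the fraction of positives among all
#' pairs scoring at or above t (precision among the top-ranked pairs) —
#' the default reading, used by the confidence-map combiner. The literal
#' alternative reading (recall: fraction of all positives found at or
#' above t) is available with `reading = "recall"`.
#'
#' @param scores,labels as in [roc_curve].
#' @param reading `"precision"` (default) or `"recall"`.
#' @return data.frame `score`, `ca`, sorted by decreasing score; missing
#'   scores are excluded.
#' @export
cumulative_accuracy <- function(scores, labels,
                                reading = c("precision", "recall")) {
  reading <- match.arg(reading)
  labels <- as.integer(labels)
  ok <- !is.na(scores)
  s <- scores[ok]; lab <- labels[ok]
  ord <- order(-s)
  s <- s[ord]; lab <- lab[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  ge <- seq_along(s)[keep]
  tp <- cumsum(lab)[keep]
  ca <- if (reading == "precision") tp / ge else tp / sum(lab)
  data.frame(score = s[keep], ca = ca)
}

#' Fold improvement of a precision over the random baseline
#'
#' `precision(%) / prevalence(%)`: how many times better than labeling
#' pairs positive at random.
#'
#' @param precision_pct achieved precision, in percent.
#' @param prevalence_pct fraction of positive pairs, in percent.
#' @return fold improvement.
#' @export
fold_improvement <- function(precision_pct, prevalence_pct) {
  if (prevalence_pct <= 0) stop("prevalence must be positive")
  precision_pct / prevalence_pct
}

#' Evaluate a score matrix against a gold standard
#'
#' @param matrix a [score_matrix].
#' @param labels a [pair_labels] table.
#' @param top_pct percents for top-p selection (default c(1, 5)).
#' @return list with `auroc`, `roc` (data.frame), `top` (data.frame with
#'   sensitivity and precision per percent), `n_pairs`, `prevalence_pct`.
#' @export
evaluate_scores <- function(matrix, labels, top_pct = c(1, 5)) {
  ml <- match_scores_labels(matrix, labels)
  top <- data.frame(
    p_pct = top_pct,
    sensitivity = vapply(top_pct, function(p)
      sensitivity_at_top(ml$score, ml$label, p), numeric(1)),
    precision = vapply(top_pct, function(p)
      precision_at_top(ml$score, ml$label, p), numeric(1)))
  list(auroc = auroc(ml$score, ml$label),
       roc = roc_curve(ml$score, ml$label),
       top = top,
       n_pairs = length(ml$score),
       prevalence_pct = 100 * mean(ml$label == 1))
}
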