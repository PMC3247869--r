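# Score-matrix normalization.
#
# Genome-context scores carry per-gene biases (for example, frequent genes
# inflate lnX simply by multiplying many small relative distances). Forcing
# every row of the gene-by-gene score matrix to share one distribution
# removes the bias attributable to the row gene, exactly as microarray
# per-array normalization does. Normalization always runs on the full
# matrix, even when evaluation later uses a subset of pairs.

# shared row-stat helper: which entries of a row participate
row_active <- function(x) !is.na(x)

#' Row z-score normalization (asymmetric intermediate)
#'
#' Each row is centered and scaled to zero mean and unit standard deviation
#' over its non-missing entries (population SD, divide by n). Missing
#' entries, including the diagonal, are excluded from the statistics and
#' stay missing. A constant row becomes all zeros with a warning.
#'
#' @param matrix a [score_matrix] or plain numeric matrix.
#' @return matrix of the same shape (not symmetric in general).
#' @export
znorm_rows <- function(matrix) {
  out <- unclass(matrix)
  warned <- FALSE
  for (i in seq_len(nrow(out))) {
    act <- row_active(out[i, ])
    v <- out[i, act]
    if (length(v) < 2) next
    s <- stats::sd(v) * sqrt((length(v) - 1) / length(v))
    if (s == 0) {
      out[i, act] <- 0
      warned <- TRUE
    } else {
      out[i, act] <- (v - mean(v)) / s
    }
  }
  if (warned) warning("constant row(s) set to 0")
  out
}

#' Row quantile normalization (asymmetric intermediate)
#'
#' Forces the empirical distribution of every row to coincide with a target
#' distribution: sort each row, average across rows at each sorted position
#' (the "mean" target; "median" and "uniform" available behind the flag),
#' then map each entry to the target value at its within-row rank. Tied
#' entries receive the mean of their tied target positions. Rows with
#' unequal non-missing counts are mapped through matching quantile
#' positions.
#'
#' @param matrix a [score_matrix] or plain numeric matrix.
#' @param target `"mean"` (default), `"median"` or `"uniform"`.
#' @return matrix of the same shape (not symmetric in general).
#' @export
rnorm_rows <- function(matrix, target = c("mean", "median", "uniform")) {
  target <- match.arg(target)
  out <- unclass(matrix)
  counts <- apply(out, 1, function(r) sum(row_active(r)))
  usable <- counts >= 1
  nt <- max(counts)
  sorted <- matrix(NA_real_, sum(usable), nt)
  ri <- 0
  for (i in which(usable)) {
    ri <- ri + 1
    v <- sort(out[i, row_active(out[i, ])])
    if (length(v) == nt) sorted[ri, ] <- v
    else  # unequal count: place on matching quantile grid
      sorted[ri, ] <- stats::approx((seq_along(v) - 0.5) / length(v), v,
                                    xout = (seq_len(nt) - 0.5) / nt,
                                    rule = 2)$y
  }
  tgt <- switch(target,
    "mean" = colMeans(sorted),
    "median" = apply(sorted, 2, stats::median),
    "uniform" = (seq_len(nt) - 0.5) / nt)
  for (i in which(usable)) {
    act <- row_active(out[i, ])
    v <- out[i, act]
    r <- rank(v, ties.method = "average")
    if (length(v) == nt) {
      out[i, act] <- stats::approx(seq_len(nt), tgt, xout = r, rule = 2)$y
    } else {
      p <- (r - 0.5) / length(v)
      out[i, act] <- stats::approx((seq_len(nt) - 0.5) / nt, tgt,
                                   xout = p, rule = 2)$y
    }
  }
  out
}

#' Symmetrize a normalized matrix
#'
#' Elementwise average of the matrix and its transpose. A pair missing on
#' one side takes the present side's value; missing on both sides stays
#' missing.
#'
#' @param matrix square numeric matrix.
#' @return symmetric matrix.
#' @export
symmetrize <- function(matrix) {
  m <- unclass(matrix)
  tm <- t(m)
  avg <- (m + tm) / 2
  one_sided <- is.na(m) & !is.na(tm)
  avg[one_sided] <- tm[one_sided]
  one_sided <- !is.na(m) & is.na(tm)
  avg[one_sided] <- m[one_sided]
  avg
}

#' Normalize a full-coverage score matrix
#'
#' Simple variants row-normalize then symmetrize; composed variants
#' row-normalize, transpose, row-normalize again and then symmetrize,
#' compensating for the bias of the second gene after the first gene's
#' bias has been removed. Restricted-coverage matrices (gene cluster, gene
#' fusion) are rejected: with almost all entries missing, row statistics
#' are meaningless and normalization brings no improvement there.
#'
#' Note that symmetrization perturbs the exact row distributions: rows of a
#' znorm-then-symmetrized matrix are no longer exactly unit variance.
#'
#' @param matrix a full-coverage [score_matrix].
#' @param method `"znorm"`, `"rnorm"`, `"znorm-comp"` or `"rnorm-comp"`.
#' @param rnorm_target target distribution for the rnorm variants.
#' @return a [score_matrix] with method tag `<orig>.<method>`.
#' @export
normalize_scores <- function(matrix,
                             method = c("znorm", "rnorm", "znorm-comp",
                                        "rnorm-comp"),
                             rnorm_target = "mean") {
  method <- match.arg(method)
  src <- attr(matrix, "method")
  if (!is.null(src) && src %in% c("gc", "gf"))
    stop("restricted-coverage matrix ('", src, "') cannot be normalized")
  row_norm <- function(m)
    if (startsWith(method, "znorm")) znorm_rows(m) else
      rnorm_rows(m, target = rnorm_target)
  a <- row_norm(matrix)
  if (endsWith(method, "-comp")) a <- row_norm(t(a))
  out <- symmetrize(a)
  dimnames(out) <- dimnames(matrix)
  score_matrix(out, method = paste0(if (is.null(src)) "score" else src,
                                    ".", method))
}

#' Frequency-stratified score diagnostic
#'
#' Splits gene pairs by the homolog frequency of their genes (fraction of
#' reference organisms containing a homolog) and summarizes the score
#' distribution of positive and negative pairs per stratum, before and,
#' optionally, after normalization. Per-gene biased scorers show strata
#' with shifted distributions before normalization and aligned ones after.
#' A pair belongs to a stratum when both genes fall in the same frequency
#' band; mixed pairs are reported in the `"mixed"` stratum.
#'
#' @param matrix a [score_matrix] (pre-normalization).
#' @param profiles the [build_profiles] matrix used to measure frequency.
#' @param labels a [pair_labels] table.
#' @param normalized optional normalized matrix to report alongside.
#' @param n_strata number of frequency bands (default 3, terciles).
#' @return data.frame with columns `stage`, `stratum`, `label`, `n`,
#'   `mean`, `sd`, `median`. Empty strata are omitted (with a message).
#' @export
frequency_strata_report <- function(matrix, profiles, labels,
                                    normalized = NULL, n_strata = 3) {
  freq <- rowMeans(profiles)
  qs <- stats::quantile(freq, probs = seq(0, 1, length.out = n_strata + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  band_names <- if (n_strata == 3) c("infrequent", "middle", "frequent") else
    paste0("band", seq_len(n_strata))
  band <- band_names[cut(freq, qs, labels = FALSE, include.lowest = TRUE)]
  names(band) <- rownames(profiles)
  stages <- list(raw = matrix)
  if (!is.null(normalized)) stages$normalized <- normalized
  rows <- list()
  for (stage in names(stages)) {
    ml <- match_scores_labels(stages[[stage]], labels)
    ba <- band[ml$gene_a]; bb <- band[ml$gene_b]
    stratum <- ifelse(ba == bb, ba, "mixed")
    for (st in c(band_names, "mixed")) for (lb in c("positive", "negative")) {
      sel <- stratum == st & ml$label == (lb == "positive") & !is.na(ml$score)
      if (!any(sel, na.rm = TRUE)) next
      v <- ml$score[which(sel)]
      rows[[length(rows) + 1]] <- data.frame(
        stage = stage, stratum = st, label = lb, n = length(v),
        mean = mean(v), sd = stats::sd(v), median = stats::median(v),
        stringsAsFactors = FALSE)
    }
  }
  empties <- setdiff(band_names, unique(band))
  if (length(empties))
    message("empty frequency stratum omitted: ",
            paste(empties, collapse = ", "))
  do.call(rbind, rows)
}
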