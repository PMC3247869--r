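# Score combination.
#
# Individual genome-context scores are mapped to confidence measures by a
# curve fitted to the cumulative accuracy of a training set, then combined
# with the product rule 1 - prod(1 - s_i) (or the maximum); alternatively a
# bagged ensemble of probability-estimation decision trees combines the raw
# scores. Cross-validation folds are assigned at the level of similar-gene
# group pairs so that near-duplicate gene pairs never straddle train and
# test.

#' Fit a monotone confidence map for one score
#'
#' Computes the cumulative accuracy (precision among pairs scoring at or
#' above each distinct value), smooths it with a cubic smoothing spline
#' (smoothing chosen by generalized cross-validation unless `spar` is
#' given), clamps to \[0, 1\] and enforces monotonicity with an isotonic
#' pass, which guards against spline wiggles. Outside the fitted range the
#' nearest endpoint value is used. Missing scores are excluded from the
#' fit; at prediction time they map to confidence 0.
#'
#' @param scores training scores (higher = more related; NA = missing).
#' @param labels 0/1 training labels.
#' @param spar optional smoothing parameter for [stats::smooth.spline].
#' @param isotonic apply the monotone pass (default TRUE).
#' @return object of class `confidence_map`.
#' @export
fit_confidence_map <- function(scores, labels, spar = NULL,
                               isotonic = TRUE) {
  labels <- as.integer(labels)
  ok <- !is.na(scores)
  ca <- cumulative_accuracy(scores[ok], labels[ok])
  prevalence <- mean(labels[ok] == 1)
  x <- rev(ca$score); y <- rev(ca$ca)          # ascending in score
  if (length(x) < 4) {
    fit_y <- rep(if (length(y)) mean(y) else prevalence, length(x))
    if (!length(x)) { x <- 0; fit_y <- prevalence }
  } else {
    # GCV smoothing can fail on degenerate score spacings (sparse
    # restricted-coverage features); fall back to a fixed smoothing
    # parameter, then to the raw curve (the isotonic pass still smooths
    # non-monotone wiggle)
    sp <- tryCatch(
      if (is.null(spar)) stats::smooth.spline(x, y) else
        stats::smooth.spline(x, y, spar = spar),
      error = function(e) tryCatch(stats::smooth.spline(x, y, spar = 0.8),
                                   error = function(e2) NULL))
    fit_y <- if (is.null(sp)) y else stats::predict(sp, x)$y
  }
  fit_y <- pmin(pmax(fit_y, 0), 1)
  if (isotonic && length(fit_y) > 1)
    fit_y <- stats::isoreg(x, fit_y)$yf
  structure(list(x = x, y = fit_y, prevalence = prevalence),
            class = "confidence_map")
}

#' @export
print.confidence_map <- function(x, ...) {
  cat(sprintf("confidence_map: %d knots, range [%.3f, %.3f]\n",
              length(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Apply a confidence map to scores
#' @param object a [fit_confidence_map] object.
#' @param newdata numeric scores; NA maps to 0 (the missing rule).
#' @param ... unused.
#' @return confidences in \[0, 1\].
#' @export
predict.confidence_map <- function(object, newdata, ...) {
  out <- rep(0, length(newdata))
  ok <- !is.na(newdata)
  if (any(ok)) {
    if (length(object$x) == 1) out[ok] <- object$y
    else out[ok] <- stats::approx(object$x, object$y, xout = newdata[ok],
                                  rule = 2, ties = "ordered")$y
  }
  out
}

#' Product rule for combining confidences
#'
#' `s = 1 - prod_i (1 - s_i)`. A missing method contributes confidence 0
#' (its sentinel is the worst value: infinite distance, p-value 1).
#'
#' @param confidences numeric vector, or matrix with one column per method.
#' @return combined confidence(s) in \[0, 1\].
#' @export
product_combine <- function(confidences) {
  if (is.matrix(confidences)) {
    confidences[is.na(confidences)] <- 0
    return(1 - apply(1 - confidences, 1, prod))
  }
  confidences[is.na(confidences)] <- 0
  1 - prod(1 - confidences)
}

#' Maximum rule for combining confidences
#' @param confidences as in [product_combine]; same missing rule.
#' @return combined confidence(s).
#' @export
max_combine <- function(confidences) {
  if (is.matrix(confidences)) {
    confidences[is.na(confidences)] <- 0
    return(apply(confidences, 1, max))
  }
  confidences[is.na(confidences)] <- 0
  max(confidences)
}

# missing-feature encoding for trees: each feature's NA becomes a constant
# below its observed range (oriented scores: lower = less related)
missing_fill_values <- function(features) {
  vapply(features, function(v) {
    fin <- v[is.finite(v)]
    if (!length(fin)) return(0)
    min(fin) - max(1, diff(range(fin)))
  }, numeric(1))
}

encode_missing <- function(features, fill) {
  for (j in names(fill)) {
    v <- features[[j]]
    v[!is.finite(v)] <- fill[[j]]
    features[[j]] <- v
  }
  features
}

#' Train a confidence combiner (product or max rule)
#'
#' Fits one [fit_confidence_map] per feature column and stores the
#' combination rule.
#'
#' @param features data.frame of per-pair method scores (NA = missing).
#' @param labels 0/1 labels.
#' @param kind `"product"` (default) or `"max"`.
#' @param spar optional smoothing parameter passed to each map.
#' @return object of class `confidence_combiner`.
#' @export
train_confidence_combiner <- function(features, labels,
                                      kind = c("product", "max"),
                                      spar = NULL) {
  kind <- match.arg(kind)
  maps <- lapply(features, fit_confidence_map, labels = labels, spar = spar)
  structure(list(kind = kind, maps = maps, feature_order = names(features)),
            class = "confidence_combiner")
}

#' @export
print.confidence_combiner <- function(x, ...) {
  cat(sprintf("confidence_combiner (%s rule) over: %s\n", x$kind,
              paste(x$feature_order, collapse = ", ")))
  invisible(x)
}

#' @export
predict.confidence_combiner <- function(object, newdata, ...) {
  conf <- vapply(object$feature_order, function(f)
    predict(object$maps[[f]], newdata[[f]]), numeric(nrow(newdata)))
  if (!is.matrix(conf)) conf <- matrix(conf, nrow = 1)
  if (object$kind == "product") product_combine(conf) else
    max_combine(conf)
}

#' Train a bagged decision-tree combiner
#'
#' Trains `n_trees` probability-estimation trees, each on P positives
#' resampled with replacement and `neg_per_pos * P` negatives resampled
#' with replacement from the training pairs. Trees are rpart
#' classification trees pruned at the cost-complexity value minimizing
#' internal cross-validated error, with Laplace-smoothed leaf
#' probabilities. The ensemble prediction is the mean of the per-tree
#' positive-class probabilities. Missing features are encoded as a
#' constant below each feature's observed range; the constants are stored
#' with the model and reused at prediction time.
#'
#' @param features data.frame of per-pair method scores (NA = missing).
#' @param labels 0/1 labels; at least one positive required.
#' @param n_trees ensemble size (default 10).
#' @param neg_per_pos negatives per positive in each resample (default 10).
#' @param seed RNG seed.
#' @param minbucket minimum leaf size (default 8).
#' @return object of class `tree_combiner`.
#' @export
train_bagged_trees <- function(features, labels, n_trees = 10,
                               neg_per_pos = 10, seed = 1, minbucket = 8) {
  labels <- as.integer(labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (!length(pos)) stop("no positive training pairs")
  fill <- missing_fill_values(features)
  features <- encode_missing(features, fill)
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, min(length(neg), neg_per_pos * length(pos)),
                    replace = TRUE))
    df <- features[idx, , drop = FALSE]
    df$.y <- factor(ifelse(labels[idx] == 1, "pos", "neg"),
                    levels = c("neg", "pos"))
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          cp = 0, xval = 10, minbucket = minbucket))
    cpt <- fit$cptable
    best <- cpt[which.min(cpt[, "xerror"]), "CP"]
    fit <- rpart::prune(fit, cp = best)
    # Laplace-smoothed leaf probabilities patched into the frame
    counts <- fit$frame$yval2[, 2:3, drop = FALSE]
    probs <- (counts + 1) / (rowSums(counts) + 2)
    fit$frame$yval2[, 4:5] <- probs
    trees[[b]] <- fit
  }
  structure(list(trees = trees, feature_order = names(features),
                 missing_fill = fill, n_trees = n_trees),
            class = "tree_combiner")
}

#' @export
print.tree_combiner <- function(x, ...) {
  cat(sprintf("tree_combiner: %d bagged trees over: %s\n", x$n_trees,
              paste(x$feature_order, collapse = ", ")))
  invisible(x)
}

#' @export
predict.tree_combiner <- function(object, newdata, ...) {
  newdata <- encode_missing(newdata[object$feature_order],
                            object$missing_fill)
  preds <- vapply(object$trees, function(fit)
    stats::predict(fit, newdata, type = "prob")[, "pos"],
    numeric(nrow(newdata)))
  if (!is.matrix(preds)) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Group genes by sequence similarity
#'
#' Connected components of the similarity graph whose edges are gene pairs
#' with E-value strictly below `e_cut`; singletons are allowed. Used to
#' keep near-duplicate gene pairs inside one cross-validation fold.
#'
#' @param within_hits data.frame `gene_a`, `gene_b`, `e_value` of
#'   within-target similarity hits (self-hits excluded).
#' @param genes full gene universe (adds singletons).
#' @param e_cut similarity threshold (default 1e-2).
#' @return named character vector gene -> group id.
#' @export
group_genes_by_similarity <- function(within_hits, genes, e_cut = 1e-2) {
  edges <- within_hits[within_hits$e_value < e_cut &
                         within_hits$gene_a != within_hits$gene_b, ,
                       drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes))
  comp <- igraph::components(g)$membership
  stats::setNames(paste0("grp", comp[genes]), genes)
}

#' Similarity-grouped cross-validation folds
#'
#' Unordered pairs of similarity groups (including same-group pairs) are
#' split uniformly into k folds; a gene pair inherits the fold of its
#' group pair. Consequence: if G1 ~ G3 and G2 ~ G4, pairs (G1, G2) and
#' (G3, G4) share a fold.
#'
#' @param groups named vector gene -> group (from
#'   [group_genes_by_similarity]).
#' @param k folds (default 10).
#' @param seed RNG seed.
#' @return object of class `grouped_folds`.
#' @export
grouped_cv_folds <- function(groups, k = 10, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  gs <- sort(unique(groups))
  gp <- expand.grid(a = seq_along(gs), b = seq_along(gs))
  gp <- gp[gp$a <= gp$b, , drop = FALSE]
  if (nrow(gp) < k) stop("fewer group pairs than folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = nrow(gp)))
  key <- paste(gs[gp$a], gs[gp$b], sep = "\r")
  structure(list(groups = groups, k = k,
                 fold_of = stats::setNames(fold, key)),
            class = "grouped_folds")
}

#' Fold of each gene pair under grouped folds
#' @param folds a [grouped_cv_folds] object.
#' @param gene_a,gene_b character vectors of pair members.
#' @return integer fold per pair.
#' @export
pair_fold <- function(folds, gene_a, gene_b) {
  ga <- folds$groups[gene_a]; gb <- folds$groups[gene_b]
  key <- ifelse(ga <= gb, paste(ga, gb, sep = "\r"),
                paste(gb, ga, sep = "\r"))
  unname(folds$fold_of[key])
}

#' Per-pair genome-context feature table for a synthetic world
#'
#' Computes the score matrices of the requested score set on the world's
#' inputs and assembles one row per gold-standard pair. The `"orig"` set
#' holds gn-pval, pp-mutual-info, gc and gf; `"orig+new"` adds gn-lnX,
#' gn-lnX after znorm and pp-mutual-info after znorm. Pairs involving
#' genes with no homology information at all are dropped (their scores are
#' outliers that distort combiner training).
#'
#' @param world a [simulate_world] object.
#' @param score_set `"orig"` or `"orig+new"`.
#' @param e_threshold homology threshold (default 1e-4).
#' @param Q,E Rosetta-Stone thresholds (defaults 50, 1e-4).
#' @return data.frame with feature columns, `label` (0/1) and `gene_a`,
#'   `gene_b`.
#' @export
compute_pair_features <- function(world, score_set = c("orig", "orig+new"),
                                  e_threshold = 1e-4, Q = 50, E = 1e-4) {
  score_set <- match.arg(score_set)
  genes <- world$genes
  profiles <- build_profiles(world$hits, genes, world$organisms,
                             e_threshold)
  mats <- list(
    "gn.pval" = score_all_pairs_gn(world$hits, world$annotations, genes,
                                   e_threshold, variant = "pval"),
    "pp.mutual.info" = score_all_pairs_pp(profiles, "mutual-info"),
    "gc" = gene_cluster_scores(world$target_annotation),
    "gf" = score_all_pairs_gf(world$hits, genes, Q = Q, E = E))
  if (score_set == "orig+new") {
    gn_lnx <- score_all_pairs_gn(world$hits, world$annotations, genes,
                                 e_threshold, variant = "lnX")
    mats[["gn.lnX"]] <- gn_lnx
    mats[["gn.lnX.znorm"]] <- normalize_scores(gn_lnx, "znorm")
    mats[["pp.mutual.info.znorm"]] <-
      normalize_scores(mats[["pp.mutual.info"]], "znorm")
  }
  lab <- world$labels
  have_hits <- unique(world$hits$target_gene[world$hits$e_value <
                                               e_threshold])
  keep <- lab$gene_a %in% have_hits & lab$gene_b %in% have_hits
  lab <- lab[keep, , drop = FALSE]
  out <- data.frame(gene_a = lab$gene_a, gene_b = lab$gene_b,
                    label = as.integer(lab$label == "positive"),
                    stringsAsFactors = FALSE)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    g <- rownames(m)
    out[[nm]] <- m[cbind(match(lab$gene_a, g), match(lab$gene_b, g))]
  }
  out
}

feature_cols <- function(features)
  setdiff(names(features), c("gene_a", "gene_b", "label"))

#' Sensitivity at a minimum specificity
#' @param scores,labels as in [roc_curve].
#' @param spec_min specificity floor (default 0.99).
#' @return highest sensitivity attainable with specificity >= spec_min.
#' @export
sensitivity_at_specificity <- function(scores, labels, spec_min = 0.99) {
  r <- roc_curve(scores, labels)
  ok <- r$specificity >= spec_min
  if (!any(ok)) return(0)
  max(r$sensitivity[ok])
}

# train a combiner of the given kind on a feature frame
train_combiner <- function(features, kind, seed = 1) {
  fc <- feature_cols(features)
  x <- features[fc]
  y <- features$label
  switch(kind,
    "product" = train_confidence_combiner(x, y, kind = "product"),
    "max" = train_confidence_combiner(x, y, kind = "max"),
    "trees" = train_bagged_trees(x, y, seed = seed),
    stop("unknown combiner kind: ", kind))
}

predict_combiner <- function(model, features) {
  predict(model, features[feature_cols(features)])
}

#' Combination experiment: grouped CV and train-on-distant protocols
#'
#' Under `"grouped-cv"`, combiners are trained and evaluated by k-fold
#' cross-validation on the test world's pairs, with folds assigned at the
#' similar-gene group-pair level. Under `"train-distant"`, combiners are
#' trained on the pooled pairs of the training worlds (phylogenetically or
#' distributionally distant from the test world) and evaluated on the test
#' world. The report compares each combiner with every single feature at
#' high specificity.
#'
#' @param test_world a [simulate_world] object (evaluation world).
#' @param train_worlds list of worlds for the `"train-distant"` protocol.
#' @param protocol `"grouped-cv"` or `"train-distant"`.
#' @param combiners character subset of `c("product", "max", "trees")`.
#' @param score_set `"orig"` or `"orig+new"`.
#' @param k CV folds (default 10).
#' @param seed RNG seed.
#' @param spec_min specificity floor for the headline comparison.
#' @param features_test,features_train optional precomputed feature frames
#'   (from [compute_pair_features]); computed from the worlds if omitted.
#' @return list with `combined` (data.frame combiner, sensitivity, auroc),
#'   `single` (same per feature), `best_single`, `protocol`, `spec_min`.
#' @export
run_combination_experiment <- function(test_world, train_worlds = NULL,
                                       protocol = c("grouped-cv",
                                                    "train-distant"),
                                       combiners = c("product", "trees"),
                                       score_set = "orig+new",
                                       k = 10, seed = 1, spec_min = 0.99,
                                       features_test = NULL,
                                       features_train = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(features_test))
    features_test <- compute_pair_features(test_world, score_set)
  fc <- feature_cols(features_test)
  y <- features_test$label
  single <- data.frame(
    feature = fc,
    sensitivity = vapply(fc, function(f)
      sensitivity_at_specificity(features_test[[f]], y, spec_min),
      numeric(1)),
    auroc = vapply(fc, function(f) {
      s <- features_test[[f]]
      auroc(s, y)
    }, numeric(1)), row.names = NULL)

  combined <- lapply(combiners, function(kind) {
    if (protocol == "grouped-cv") {
      groups <- stats::setNames(test_world$genes, test_world$genes)
      names(groups) <- test_world$genes   # singleton groups by default
      folds <- grouped_cv_folds(groups, k = k, seed = seed)
      fold_id <- pair_fold(folds, features_test$gene_a,
                           features_test$gene_b)
      pred <- rep(NA_real_, nrow(features_test))
      for (f in seq_len(k)) {
        tr <- features_test[fold_id != f, , drop = FALSE]
        te <- features_test[fold_id == f, , drop = FALSE]
        if (!nrow(te) || !any(tr$label == 1)) next
        model <- train_combiner(tr, kind, seed = seed + f)
        pred[fold_id == f] <- predict_combiner(model, te)
      }
    } else {
      if (is.null(features_train)) {
        if (is.null(train_worlds))
          stop("train-distant protocol needs train_worlds")
        features_train <- do.call(rbind, lapply(
          train_worlds, compute_pair_features, score_set = score_set))
      }
      model <- train_combiner(features_train, kind, seed = seed)
      pred <- predict_combiner(model, features_test)
    }
    data.frame(combiner = kind,
               sensitivity = sensitivity_at_specificity(pred, y, spec_min),
               auroc = auroc(pred, y))
  })
  combined <- do.call(rbind, combined)
  list(combined = combined, single = single,
       best_single = max(single$sensitivity),
       protocol = protocol, spec_min = spec_min)
}

#' Parameter sets of the bundled combination study
#'
#' The matched world carries weak-but-conjunctive signal: labeled modules
#' are both co-present and co-located, co-presence decoy sets mimic the
#' modules' profile correlation without co-location, and co-location decoy
#' blocks are frequent genes (many co-occurring genomes, no profile
#' similarity). The shifted world keeps the same biology but changes the
#' observation scale: fewer reference organisms and sparser presence,
#' which rescales every count-driven feature.
#'
#' @param role `"matched"` (test and CV conditions) or `"shifted"`
#'   (train-distant training conditions).
#' @return a [synthetic_params] list.
#' @export
combination_world_params <- function(role = c("matched", "shifted")) {
  role <- match.arg(role)
  if (role == "matched")
    synthetic_params("small", n_genes = 150, n_modules = 15,
                     module_size = 4, colocation_prob = 1,
                     n_decoy_copresence = 5, n_decoy_colocation = 5,
                     decoy_size = 9, decoy_colocation_rate = 0.85,
                     copresence_boost = 0.5)
  else
    synthetic_params("small", n_organisms = 12, n_genes = 100,
                     n_modules = 10, module_size = 4, colocation_prob = 1,
                     n_decoy_copresence = 1, n_decoy_colocation = 1,
                     decoy_size = 7, decoy_colocation_rate = 0.85,
                     copresence_boost = 0.5, presence_rate = 0.4)
}

#' Run the bundled combination study
#'
#' Builds matched test worlds and three shifted training worlds, computes
#' the extended feature set, and evaluates the product and bagged-tree
#' combiners under both protocols at the high-specificity operating
#' point. Sensitivities are averaged over the replicate test worlds to
#' damp sampling noise in the small gold standards.
#'
#' @param seed RNG seed; all world seeds derive from it.
#' @param spec_min specificity floor (default 0.99).
#' @param n_test_worlds replicate matched test worlds (default 3).
#' @return list with `summary` (data.frame of mean sensitivities per
#'   protocol for the two combiners and the best single score) and
#'   `replicates` (per-world reports).
#' @export
combination_study <- function(seed = 1, spec_min = 0.99,
                              n_test_worlds = 3) {
  train_worlds <- lapply(seed + 200L + (1:3), function(s)
    simulate_world(combination_world_params("shifted"), seed = s))
  features_train <- do.call(rbind, lapply(
    train_worlds, compute_pair_features, score_set = "orig+new"))
  reps <- lapply(seq_len(n_test_worlds), function(r) {
    test_world <- simulate_world(combination_world_params("matched"),
                                 seed = seed + 100L + 10L * (r - 1L))
    features_test <- compute_pair_features(test_world, "orig+new")
    grouped <- run_combination_experiment(
      test_world, protocol = "grouped-cv",
      combiners = c("product", "trees"),
      features_test = features_test, seed = seed, spec_min = spec_min)
    distant <- run_combination_experiment(
      test_world, protocol = "train-distant",
      combiners = c("product", "trees"), features_test = features_test,
      features_train = features_train, seed = seed, spec_min = spec_min)
    list(grouped = grouped, distant = distant)
  })
  pull <- function(proto, what) vapply(reps, function(r) {
    rep <- r[[proto]]
    if (what == "best_single") rep$best_single else
      rep$combined$sensitivity[rep$combined$combiner == what]
  }, numeric(1))
  summary <- data.frame(
    protocol = rep(c("grouped-cv", "train-distant"), each = 3),
    system = rep(c("product", "trees", "best-single"), 2),
    sensitivity = c(mean(pull("grouped", "product")),
                    mean(pull("grouped", "trees")),
                    mean(pull("grouped", "best_single")),
                    mean(pull("distant", "product")),
                    mean(pull("distant", "trees")),
                    mean(pull("distant", "best_single"))))
  list(summary = summary, replicates = reps)
}
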