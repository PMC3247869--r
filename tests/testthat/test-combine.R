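# score combination

test_that("product and max rules follow their algebra", {
  expect_equal(product_combine(c(0.5, 0.5)), 0.75)
  expect_equal(product_combine(c(0, 0, 0)), 0)
  expect_equal(product_combine(c(0.3, 1, 0.2)), 1)
  expect_equal(max_combine(c(0.2, 0.9)), 0.9)
  expect_equal(max_combine(0.4), 0.4)
  # missing rule: NA contributes 0
  expect_equal(product_combine(c(NA, 0.5)), 0.5)
  expect_equal(max_combine(c(NA, 0.5)), 0.5)
  # product >= max >= each confidence, over random cases
  set.seed(2)
  for (i in 1:50) {
    s <- runif(sample(2:6, 1))
    expect_gte(product_combine(s), max_combine(s) - 1e-12)
    expect_gte(max_combine(s), max(s) - 1e-12)
  }
  # matrix form
  m <- rbind(c(0.5, 0.5), c(NA, 0.2))
  expect_equal(product_combine(m), c(0.75, 0.2))
  expect_equal(max_combine(m), c(0.5, 0.2))
})

test_that("confidence maps are monotone, clamped and shaped by the data", {
  set.seed(4)
  # separating score: high confidence above the split, prevalence below
  s <- c(rnorm(50, 5), rnorm(450, 0))
  y <- c(rep(1, 50), rep(0, 450))
  cm <- fit_confidence_map(s, y)
  expect_true(all(diff(cm$y) >= -1e-12))
  expect_true(all(cm$y >= 0 & cm$y <= 1))
  expect_gt(predict(cm, 6), 0.8)
  expect_lt(predict(cm, -2), 0.3)
  # endpoint extension beyond the fitted range
  expect_equal(predict(cm, 100), max(cm$y))
  expect_equal(predict(cm, -100), min(cm$y))
  # label-free score: map stays near the prevalence
  s2 <- rnorm(800); y2 <- rbinom(800, 1, 0.3)
  cm2 <- fit_confidence_map(s2, y2)
  expect_lt(max(abs(predict(cm2, seq(-1.5, 1.5, by = 0.5)) - 0.3)), 0.12)
  # single distinct score: constant map at prevalence
  cm3 <- fit_confidence_map(rep(1, 10), c(1, rep(0, 9)))
  expect_equal(predict(cm3, c(0, 1, 2)), rep(0.1, 3))
  # NA maps to confidence 0
  expect_equal(predict(cm, NA), 0)
})

test_that("bagged trees are deterministic, bounded and Laplace-smoothed", {
  set.seed(9)
  n <- 400
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- as.integer(x$a > 0.5 & x$b > 0.5)
  y[sample(n, 20)] <- 1 - y[sample(n, 20)]  # label noise
  m1 <- train_bagged_trees(x, y, seed = 3)
  m2 <- train_bagged_trees(x, y, seed = 3)
  p1 <- predict(m1, x); p2 <- predict(m2, x)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # Laplace smoothing keeps leaf probabilities off 0 and 1
  expect_true(all(p1 > 0 & p1 < 1))
  # conjunctive signal is learned
  expect_gt(mean(p1[x$a > 0.5 & x$b > 0.5]), mean(p1[x$a <= 0.5]))
  # feature-scale invariance when applied consistently
  x10 <- data.frame(a = x$a * 10, b = x$b * 10)
  m10 <- train_bagged_trees(x10, y, seed = 3)
  expect_equal(predict(m10, x10), p1, tolerance = 1e-12)
  expect_error(train_bagged_trees(x, rep(0, n)), "no positive")
})

test_that("similarity groups are connected components", {
  hits <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                     e_value = c(1e-4, 1e-3))
  g <- group_genes_by_similarity(hits, c("A", "B", "C", "D"))
  expect_equal(g[["A"]], g[["B"]])
  expect_equal(g[["B"]], g[["C"]])     # transitivity via components
  expect_false(g[["D"]] == g[["A"]])
  # boundary: e_cut is strict
  hits2 <- data.frame(gene_a = "A", gene_b = "B", e_value = 1e-2)
  g2 <- group_genes_by_similarity(hits2, c("A", "B"))
  expect_false(g2[["A"]] == g2[["B"]])
})

test_that("grouped folds keep similar pairs together and partition all", {
  groups <- c(G1 = "grpA", G3 = "grpA", G2 = "grpB", G4 = "grpB",
              G5 = "grpC")
  folds <- grouped_cv_folds(groups, k = 3, seed = 2)
  # (G1,G2) and (G3,G4) share a group pair, hence a fold
  expect_equal(pair_fold(folds, "G1", "G2"), pair_fold(folds, "G3", "G4"))
  expect_equal(pair_fold(folds, "G2", "G1"), pair_fold(folds, "G1", "G2"))
  # every pair gets exactly one fold
  prs <- enumerate_pairs(names(groups))
  f <- pair_fold(folds, prs$gene_a, prs$gene_b)
  expect_true(all(f %in% 1:3))
  # reproducible
  folds2 <- grouped_cv_folds(groups, k = 3, seed = 2)
  expect_identical(folds$fold_of, folds2$fold_of)
  expect_error(grouped_cv_folds(c(a = "g1"), k = 10), "fewer")
})

test_that("no test pair is similar to a training pair under grouped CV", {
  groups <- c(G1 = "grpA", G3 = "grpA", G2 = "grpB", G4 = "grpB",
              G5 = "grpC", G6 = "grpD")
  folds <- grouped_cv_folds(groups, k = 4, seed = 5)
  prs <- enumerate_pairs(names(groups))
  f <- pair_fold(folds, prs$gene_a, prs$gene_b)
  key <- paste(groups[prs$gene_a], groups[prs$gene_b])
  canon <- ifelse(groups[prs$gene_a] <= groups[prs$gene_b],
                  paste(groups[prs$gene_a], groups[prs$gene_b]),
                  paste(groups[prs$gene_b], groups[prs$gene_a]))
  # a group pair never straddles folds
  expect_true(all(tapply(f, canon, function(x) length(unique(x))) == 1))
})

test_that("pair features carry the orientation contract and drop no-homology genes", {
  w <- cached_world()
  ft <- compute_pair_features(w, "orig")
  expect_setequal(feature_cols(ft), c("gn.pval", "pp.mutual.info",
                                      "gc", "gf"))
  expect_true(all(ft$label %in% 0:1))
  # restricted features are mostly missing, full-coverage mostly present
  expect_lt(mean(!is.na(ft$gc)), 0.1)
  expect_gt(mean(!is.na(ft$pp.mutual.info)), 0.95)
})

test_that("missing-feature encoding sits below the observed range", {
  x <- data.frame(a = c(1, 2, NA, 4), b = c(NA, -5, -4, -3))
  fill <- genecontext:::missing_fill_values(x)
  expect_lt(fill[["a"]], 1)
  expect_lt(fill[["b"]], -5)
  enc <- genecontext:::encode_missing(x, fill)
  expect_false(anyNA(enc))
})
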