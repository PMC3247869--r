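# organism clustering, pruning, representatives, leaf ordering

toy_profiles <- function(bits, organisms) {
  m <- matrix(bits, ncol = length(organisms))
  dimnames(m) <- list(sprintf("g%02d", seq_len(nrow(m))), organisms)
  structure(m, class = c("profile_matrix", "matrix", "array"))
}

test_that("organism Jaccard distance matches hand counts and vegan", {
  pr <- toy_profiles(c(1, 1, 0,   1, 0, 1,   1, 1, 0,   0, 0, 0),
                     c("a", "b", "c", "d"))
  d <- organism_distance(pr)
  expect_equal(d["a", "b"], 2 / 3)        # columns (1,1,0) vs (1,0,1)
  expect_equal(d["a", "c"], 0)            # identical columns
  expect_equal(d["a", "d"], 1)            # disjoint (empty column)
  expect_equal(d["d", "d"], 0)
  skip_if_not_installed("vegan")
  set.seed(3)
  pr2 <- toy_profiles(rbinom(10 * 6, 1, 0.5), sprintf("o%d", 1:6))
  d2 <- organism_distance(pr2)
  dv <- as.matrix(vegan::vegdist(t(unclass(pr2)), method = "jaccard",
                                 binary = TRUE))
  # vegan leaves NaN for empty-vs-empty; compare defined entries
  ok <- !is.nan(dv)
  expect_equal(unname(d2[ok]), unname(dv[ok]), tolerance = 1e-12)
})

test_that("tree building is deterministic with index tie-breaks", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  dimnames(d) <- list(c("a", "b", "c"), c("a", "b", "c"))
  tr <- build_tree(d)
  # equidistant organisms: first merge joins the lowest-index pair
  expect_equal(sort(tr$members[[1]]), c(1L, 2L))
  # duplicate organisms merge first at height 0
  d2 <- matrix(c(0, 0, .9, 0, 0, .9, .9, .9, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr2 <- build_tree(d2)
  expect_equal(tr2$hclust$height[1], 0)
  expect_equal(sort(tr2$members[[1]]), c(1L, 2L))
})

test_that("distortion cut spans singletons to the full set monotonically", {
  w <- cached_world()
  pr <- build_profiles(w$hits, w$genes, w$organisms)
  d <- organism_distance(pr)
  tr <- build_tree(d)
  cl0 <- cut_by_distortion(tr, 0)
  expect_equal(sort(unlist(cl0)), sort(w$organisms))
  expect_equal(lengths(cl0), rep(1L, length(w$organisms)))
  cl_all <- cut_by_distortion(tr, max(d) + 1)
  expect_equal(length(cl_all), 1L)
  sizes <- vapply(seq(0, 1, by = 0.1), function(t)
    length(cut_by_distortion(tr, t)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # every cut is a partition
  for (t in c(0.2, 0.5, 0.8))
    expect_equal(sort(unlist(cut_by_distortion(tr, t))), sort(w$organisms))
})

test_that("representatives minimize average within-cluster distance", {
  d <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(pick_representatives(list(c("a", "b", "c")), d), "b")
  expect_equal(pick_representatives(list("c"), d), "c")
  # tie: lower index wins
  d2 <- matrix(1, 3, 3); diag(d2) <- 0
  dimnames(d2) <- dimnames(d)
  expect_equal(pick_representatives(list(c("b", "c")), d2), "b")
})

test_that("random subsets are reproducible, distinct and sized", {
  orgs <- sprintf("o%02d", 1:12)
  s1 <- random_subsets(orgs, sizes = c(3, 12), n_reps = 3, seed = 9)
  s2 <- random_subsets(orgs, sizes = c(3, 12), n_reps = 3, seed = 9)
  expect_identical(s1, s2)
  expect_equal(length(s1[["3"]]), 3L)
  for (ss in s1[["3"]]) expect_equal(anyDuplicated(ss), 0L)
  expect_setequal(s1[["12"]][[1]], orgs)
  expect_error(random_subsets(orgs, 13), "exceeds")
})

test_that("swiveling places outliers at the ends and never hurts", {
  # 3-leaf chain: b central, c the outlier
  d <- matrix(c(0, .1, .9,
                .1, 0, .8,
                .9, .8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_tree(d)
  ord <- swivel_leaf_order(tr, d)
  expect_true(ord[1] == "c" || ord[3] == "c")
  w <- cached_world()
  pr <- build_profiles(w$hits, w$genes, w$organisms)
  dd <- organism_distance(pr)
  trw <- build_tree(dd)
  unswiveled <- leaf_order_objective(
    trw$labels[trw$hclust$order], dd)
  exact <- leaf_order_objective(swivel_leaf_order(trw, dd, method = "exact"),
                                dd)
  greedy <- leaf_order_objective(
    swivel_leaf_order(trw, dd, method = "greedy"), dd)
  expect_lte(exact, greedy + 1e-12)
  expect_lte(greedy, unswiveled + 1e-12)
})

test_that("exact DP beats or ties greedy on random instances", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    p <- matrix(rbinom(40 * n, 1, 0.5), 40, n,
                dimnames = list(sprintf("g%02d", 1:40),
                                sprintf("o%02d", 1:n)))
    d <- organism_distance(structure(p, class = c("profile_matrix",
                                                  "matrix", "array")))
    tr <- build_tree(d)
    oe <- leaf_order_objective(swivel_leaf_order(tr, d, method = "exact"), d)
    og <- leaf_order_objective(swivel_leaf_order(tr, d, method = "greedy"),
                               d)
    expect_lte(oe, og + 1e-12)
    # the exact order visits every organism exactly once
    expect_setequal(swivel_leaf_order(tr, d, method = "exact"),
                    colnames(p))
  }
})

test_that("reference selection returns one representative per cluster", {
  w <- cached_world()
  pr <- build_profiles(w$hits, w$genes, w$organisms)
  refs0 <- select_reference_organisms(pr, 0)
  expect_setequal(refs0, w$organisms)
  refs <- select_reference_organisms(pr, 0.5)
  expect_lt(length(refs), length(w$organisms))
  expect_true(all(refs %in% w$organisms))
})
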