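# phylogenetic-profile metrics

test_that("homology call uses strict E < threshold", {
  hits <- tiny_hits(c("g1", "g2"), "orgA", c("r1", "r2"),
                    e_value = c(1e-5, 1e-4))
  pr <- build_profiles(hits, c("g1", "g2", "g3"), c("orgA", "orgB"),
                       e_threshold = 1e-4)
  expect_equal(pr["g1", "orgA"], 1L)   # below threshold
  expect_equal(pr["g2", "orgA"], 0L)   # boundary excluded
  expect_equal(pr["g3", "orgA"], 0L)   # no hit
  expect_error(build_profiles(hits, "g1", character(0)), "empty")
})

test_that("pair_counts builds the exact 2x2 table", {
  ct <- pair_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unname(ct$n12["1", "1"]), 1)
  expect_equal(unname(ct$n12["0", "0"]), 1)
  expect_equal(sum(ct$n12), ct$M)
  ct2 <- pair_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unname(ct2$n12["1", "0"]), 0)
  expect_equal(unname(ct2$n12["0", "1"]), 0)
  expect_equal(unname(pair_counts(c(0, 0), c(0, 0))$n12["0", "0"]), 2)
  expect_error(pair_counts(c(1, 0), c(1, 0, 1)), "length")
})

test_that("simple metrics match hand values and degenerate rules", {
  p1 <- c(1, 1, 0, 0); p2 <- c(1, 0, 1, 0)
  expect_equal(pp_jaccard(pair_counts(p1, p2)), 1 / 3)
  expect_equal(pp_jaccard(pair_counts(p1, p1)), 1)
  expect_equal(pp_jaccard(pair_counts(c(0, 0), c(0, 0))), 0)
  expect_equal(pp_pearson(p1, p1), 1)
  expect_equal(pp_pearson(c(1, 0), c(0, 1)), -1)
  expect_equal(pp_pearson(c(1, 1), c(1, 0)), 0)    # constant profile
  expect_equal(pp_mutual_info(pair_counts(p1, p1)), log(2))
  expect_equal(pp_mutual_info(pair_counts(p1, p2)), 0)
  expect_equal(pp_mutual_info(pair_counts(c(1, 1), p2[1:2])), 0)
})

test_that("hypergeometric p-value matches enumeration", {
  # M=4, both margins 2, full overlap: 1 of C(4,2)=6 placements
  ct <- pair_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(pp_hypergeom_pval(ct), 1 / 6)
  expect_equal(pp_hypergeom_pval(pair_counts(c(1, 0, 0), c(0, 1, 0))), 1)
  expect_equal(pp_hypergeom_pval(pair_counts(c(1, 0, 0), c(1, 0, 0))),
               1 / 3)
  # tail is non-increasing in overlap at fixed margins
  tails <- vapply(0:3, function(ov) {
    p1 <- c(rep(1, 3), rep(0, 5))
    p2 <- c(rep(1, ov), rep(0, 3 - ov), rep(1, 3 - ov), rep(0, 2 + ov))
    pp_hypergeom_pval(pair_counts(p1, p2))
  }, numeric(1))
  expect_true(all(diff(tails) <= 1e-12))
})

test_that("organism weights are column fractions", {
  pr <- build_profiles(tiny_hits(c("g1", "g2", "g3"), "orgA",
                                 c("r1", "r2", "r3")),
                       sprintf("g%d", 1:4), c("orgA", "orgB"))
  w <- organism_weights(pr)
  expect_equal(unname(w["orgA"]), 0.75)
  expect_equal(unname(w["orgB"]), 0)
})

test_that("weighted p-value equals the hypergeometric under equal weights", {
  for (M in c(4, 6, 8)) {
    for (n1 in 1:(M - 1)) for (n2 in 1:(M - 1)) {
      ov <- max(0, n1 + n2 - M):min(n1, n2)
      for (o in ov) {
        p1 <- c(rep(1, n1), rep(0, M - n1))
        p2 <- c(rep(1, o), rep(0, n1 - o), rep(1, n2 - o),
                rep(0, M - n1 - n2 + o))
        expect_equal(pp_weighted_pval(p1, p2, rep(0.5, M)),
                     pp_hypergeom_pval(pair_counts(p1, p2)),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("weighted p-value matches exhaustive enumeration", {
  w <- c(0.9, 0.5, 0.1)
  p1 <- c(1, 0, 0); p2 <- c(1, 0, 0)
  expect_equal(pp_weighted_pval(p1, p2, w),
               enum_weighted_pval(w, 1, 1, 1), tolerance = 1e-9)
  w4 <- c(0.8, 0.6, 0.4, 0.2)
  p1 <- c(1, 1, 0, 0); p2 <- c(1, 0, 1, 0)
  expect_equal(pp_weighted_pval(p1, p2, w4),
               enum_weighted_pval(w4, 2, 2, 1), tolerance = 1e-9)
  # zero overlap is certain
  expect_equal(pp_weighted_pval(c(1, 0, 0, 0), c(0, 1, 0, 0), w4), 1)
})

test_that("run counting and the runs null are exact", {
  expect_equal(count_runs(c(1, 1, 0, 1)), 2L)
  expect_equal(count_runs(rep(0, 5)), 0L)
  expect_equal(count_runs(c(1, 0, 1, 0, 1)), 3L)
  expect_equal(runs_pvalue(4, 3, 2), 0.5)
  expect_equal(runs_pvalue(5, 2, 2), 0.6)
  expect_equal(runs_pvalue(7, 0, 1), 1)
  # arrangement counts sum to C(M, k)
  for (M in 2:12) for (k in 1:M) {
    r <- seq_len(max(1, min(k, M - k + 1)))
    expect_equal(sum(choose(k - 1, r - 1) * choose(M - k + 1, r)),
                 choose(M, k))
  }
  # tail agrees with enumeration
  for (M in c(5, 7)) for (k in 1:M) for (r in 1:(min(k, M - k + 1)))
    expect_equal(runs_pvalue(M, k, r), enum_runs_tail(M, k, r))
})

test_that("wpval-with-runs composes its two parts", {
  w <- rep(0.5, 4)
  p1 <- c(1, 1, 0, 0); p2 <- c(1, 1, 0, 0)
  # overlap profile (1,1,0,0): k=2, 1 run; identity order
  wp <- pp_weighted_pval(p1, p2, w)
  rp <- runs_pvalue(4, 2, 1)
  expect_equal(pp_wpval_with_runs(p1, p2, w, 1:4), wp / rp)
  # reordering that splits the run changes only the runs part
  ord <- c(1, 3, 2, 4)  # product profile becomes 1,0,1,0 -> 2 runs
  expect_equal(pp_wpval_with_runs(p1, p2, w, ord),
               wp / runs_pvalue(4, 2, 2))
  # empty product profile: both parts are 1
  expect_equal(pp_wpval_with_runs(c(1, 0, 0, 0), c(0, 1, 0, 0), w, 1:4), 1)
})

test_that("all-pairs pp matrices are symmetric, oriented and complete", {
  w <- cached_world()
  pr <- build_profiles(w$hits, w$genes[1:12], w$organisms)
  wt <- organism_weights(build_profiles(w$hits, w$genes, w$organisms))
  for (metric in c("jaccard", "pearson", "mutual-info", "pval", "wpval")) {
    m <- score_all_pairs_pp(pr, metric,
                            weights = if (startsWith(metric, "wpval")) wt)
    expect_s3_class(m, "score_matrix")
    expect_true(all(!is.na(m[upper.tri(m)])))
    expect_equal(unclass(m), t(unclass(m)))
  }
  # p-value metrics are stored negated (in [-1, 0))
  mp <- score_all_pairs_pp(pr, "pval")
  expect_true(all(mp[upper.tri(mp)] >= -1 & mp[upper.tri(mp)] < 0))
  expect_error(score_all_pairs_pp(pr, "wpval"), "weights")
})

test_that("gene permutation permutes the score matrix consistently", {
  w <- cached_world()
  pr <- build_profiles(w$hits, w$genes[1:8], w$organisms)
  m1 <- score_all_pairs_pp(pr, "jaccard")
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  m2 <- score_all_pairs_pp(pr[perm, ], "jaccard")
  expect_equal(unclass(m2), unclass(m1)[perm, perm], ignore_attr = TRUE)
})
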