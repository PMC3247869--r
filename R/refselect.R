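# Reference-organism selection.
#
# Closely related reference genomes violate the independence assumptions of
# the profile and neighbor scores. Organisms are clustered hierarchically
# on the Jaccard distance between organism profiles; pruning the tree at a
# maximum within-cluster distortion and keeping one representative per
# cluster yields reference lists free of near-duplicates. The same tree,
# swiveled to minimize the distance between neighboring leaves, provides
# the organism ordering used by the runs-corrected profile score.

#' Jaccard distance between organism profiles
#'
#' `d(a, b) = 1 - |genes in both| / |genes in either|`, computed on the
#' columns of the profile matrix; 1 when the union is empty. Jaccard is a
#' true metric (it satisfies the triangle inequality), which makes it safe
#' for hierarchical clustering.
#'
#' @param profiles a [build_profiles] matrix (genes x organisms).
#' @return symmetric distance matrix with organism dimnames.
#' @export
organism_distance <- function(profiles) {
  if (ncol(profiles) < 2) stop("need at least 2 organisms")
  b <- unclass(profiles)
  both <- crossprod(b)                  # t(b) %*% b
  ones <- colSums(b)
  either <- outer(ones, ones, "+") - both
  d <- ifelse(either == 0, 1, 1 - both / either)
  diag(d) <- 0
  dimnames(d) <- list(colnames(profiles), colnames(profiles))
  d
}

#' Hierarchical clustering tree over organisms
#'
#' Agglomerative clustering of the organism-distance matrix. The root is a
#' single cluster of all organisms; leaves are individual organisms. The
#' returned object also carries the per-internal-node within-cluster
#' distortion, defined as the cluster diameter (maximum pairwise distance;
#' mean pairwise distance available via `distortion = "mean"`).
#'
#' @param distances symmetric distance matrix from [organism_distance].
#' @param linkage `"average"` (default) or `"complete"`.
#' @param distortion `"max"` (diameter, default) or `"mean"`.
#' @return object of class `organism_tree`: list with the `hclust` fit,
#'   `labels`, `distances`, per-node `members` and `distortion`.
#' @export
build_tree <- function(distances, linkage = c("average", "complete"),
                       distortion = c("max", "mean")) {
  linkage <- match.arg(linkage)
  distortion <- match.arg(distortion)
  labels <- rownames(distances)
  hc <- stats::hclust(stats::as.dist(distances), method = linkage)
  n <- length(labels)
  members <- vector("list", n - 1)
  dist_node <- numeric(n - 1)
  for (v in seq_len(n - 1)) {
    kids <- hc$merge[v, ]
    mem <- unlist(lapply(kids, function(k)
      if (k < 0) -k else members[[k]]))
    members[[v]] <- mem
    sub <- distances[mem, mem, drop = FALSE]
    dist_node[v] <- if (distortion == "max") max(sub) else
      mean(sub[upper.tri(sub)])
  }
  structure(list(hclust = hc, labels = labels, distances = distances,
                 members = members, distortion = dist_node),
            class = "organism_tree")
}

#' @export
print.organism_tree <- function(x, ...) {
  cat(sprintf("organism_tree: %d organisms, root distortion %.3f\n",
              length(x$labels), x$distortion[length(x$distortion)]))
  invisible(x)
}

#' Cut the organism tree at a maximum within-cluster distortion
#'
#' Returns the minimal set of subtrees whose distortion does not exceed
#' `max_distortion`, walking down from the root. A threshold of 0 yields
#' every organism as its own cluster (assuming no duplicate organisms); a
#' threshold at or above the tree diameter yields one cluster. The number
#' of clusters is non-increasing in the threshold.
#'
#' @param tree an [build_tree] object.
#' @param max_distortion threshold >= 0.
#' @return list of character vectors of organism ids.
#' @export
cut_by_distortion <- function(tree, max_distortion) {
  if (max_distortion < 0) stop("max_distortion must be >= 0")
  n <- length(tree$labels)
  clusters <- list()
  walk <- function(node) {
    if (node < 0) {
      clusters[[length(clusters) + 1]] <<- tree$labels[-node]
    } else if (tree$distortion[node] <= max_distortion) {
      clusters[[length(clusters) + 1]] <<- tree$labels[tree$members[[node]]]
    } else {
      walk(tree$hclust$merge[node, 1])
      walk(tree$hclust$merge[node, 2])
    }
  }
  if (n == 1) return(list(tree$labels))
  walk(n - 1L)
  clusters
}

#' Pick a representative organism per cluster
#'
#' The representative has the smallest average distance to all other
#' members of its cluster; a singleton represents itself; ties go to the
#' organism with the smallest index in the distance matrix.
#'
#' @param clusters list of organism-id vectors (from [cut_by_distortion]).
#' @param distances the organism distance matrix.
#' @return character vector with one organism per cluster.
#' @export
pick_representatives <- function(clusters, distances) {
  labels <- rownames(distances)
  vapply(clusters, function(cl) {
    if (length(cl) == 1) return(cl)
    idx <- match(cl, labels)
    idx <- idx[order(idx)]              # index order fixes the tie rule
    avg <- rowMeans(distances[idx, idx, drop = FALSE]) *
      length(idx) / (length(idx) - 1)   # exclude self (distance 0)
    labels[idx[which.min(avg)]]
  }, character(1))
}

#' Reference-list selection by clustering
#'
#' Convenience wrapper: cluster, cut at the distortion threshold and pick
#' representatives.
#'
#' @param profiles a [build_profiles] matrix.
#' @param max_distortion within-cluster distortion threshold.
#' @param linkage passed to [build_tree].
#' @return character vector of representative organism ids.
#' @export
select_reference_organisms <- function(profiles, max_distortion,
                                       linkage = "average") {
  d <- organism_distance(profiles)
  tree <- build_tree(d, linkage = linkage)
  pick_representatives(cut_by_distortion(tree, max_distortion), d)
}

#' Random organism subsets (baseline lists)
#'
#' Reproducible uniform sampling without replacement, repeated `n_reps`
#' times per size so that performance can be averaged over replicate lists.
#'
#' @param organisms character vector to sample from.
#' @param sizes integer vector of subset sizes.
#' @param n_reps replicates per size (default 3).
#' @param seed RNG seed.
#' @return nested list: `out[[size]][[rep]]` is a character vector.
#' @export
random_subsets <- function(organisms, sizes, n_reps = 3, seed = 1) {
  if (any(sizes > length(organisms)))
    stop("subset size exceeds the number of organisms")
  set.seed(seed)
  out <- lapply(sizes, function(sz)
    lapply(seq_len(n_reps), function(r) sample(organisms, sz)))
  names(out) <- as.character(sizes)
  out
}

#' Swiveled leaf order of the organism tree
#'
#' Rotates (swivels) the left and right branches under each node of the
#' tree so that the sum of distances between neighboring leaves is
#' minimized, and reads off the leaves in order. Exact dynamic-programming
#' optimal leaf ordering is used up to `exact_limit` leaves (it searches
#' all 2^(internal nodes) swivel choices implicitly); beyond that a greedy
#' bottom-up swivel is used. The objective value of the returned order
#' never exceeds the unswiveled order's objective.
#'
#' @param tree an [build_tree] object.
#' @param distances the organism distance matrix.
#' @param exact_limit max leaves for the exact DP (default 25).
#' @param method force `"exact"` or `"greedy"`; default picks by size.
#' @return character vector: ordered organism ids.
#' @export
swivel_leaf_order <- function(tree, distances, exact_limit = 25,
                              method = NULL) {
  n <- length(tree$labels)
  if (n == 1) return(tree$labels)
  if (is.null(method))
    method <- if (n <= exact_limit) "exact" else "greedy"
  ord <- if (method == "exact") olo_exact(tree, distances) else
    olo_greedy(tree, distances)
  tree$labels[ord]
}

#' Adjacent-leaf distance objective of an ordering
#' @param order character or integer ordering of organisms.
#' @param distances organism distance matrix.
#' @return sum of distances between neighboring leaves.
#' @export
leaf_order_objective <- function(order, distances) {
  if (is.character(order)) order <- match(order, rownames(distances))
  sum(distances[cbind(order[-length(order)], order[-1])])
}

# exact optimal leaf ordering (Bar-Joseph style DP over subtree endpoints).
# cost[[v]] is a full symmetric |leaves(v)| x |leaves(v)| matrix: entry
# (i, j) is the minimum within-subtree objective of an ordering of the
# leaves of v that starts at leaf i and ends at leaf j (Inf where i, j lie
# on the same side of v's split). Leaf indices are global (1..n).
olo_exact <- function(tree, distances) {
  hc <- tree$hclust
  n <- length(tree$labels)
  cost <- vector("list", n - 1)
  node_cost <- function(k) {
    if (k < 0)
      return(matrix(0, 1, 1, dimnames = list(as.character(-k),
                                             as.character(-k))))
    cost[[k]]
  }
  node_leaves <- function(k) if (k < 0) -k else tree$members[[k]]
  for (v in seq_len(n - 1)) {
    k1 <- hc$merge[v, 1]; k2 <- hc$merge[v, 2]
    c1 <- node_cost(k1); c2 <- node_cost(k2)
    A <- node_leaves(k1); B <- node_leaves(k2)
    all_lv <- c(A, B)
    m <- matrix(Inf, length(all_lv), length(all_lv),
                dimnames = list(as.character(all_lv), as.character(all_lv)))
    dAB <- distances[A, B, drop = FALSE]
    for (ii in seq_along(A)) {
      # b[h] = min_k cost1(i, k) + d(k, h)
      b <- apply(c1[ii, , drop = FALSE][1, ] + dAB, 2, min)
      # m[i, j] = min_h b[h] + cost2(h, j)
      m[ii, length(A) + seq_along(B)] <-
        apply(b + c2, 2, min)
    }
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    cost[[v]] <- m
  }
  # layout(k, i, j): leaves of subtree k ordered from leaf i to leaf j
  layout <- function(k, i, j) {
    if (k < 0) return(-k)
    k1 <- hc$merge[k, 1]; k2 <- hc$merge[k, 2]
    A <- node_leaves(k1); B <- node_leaves(k2)
    if (!(i %in% A)) { tmp <- k1; k1 <- k2; k2 <- tmp
                       tmp <- A; A <- B; B <- tmp }
    c1 <- node_cost(k1); c2 <- node_cost(k2)
    ci <- as.character(i); cj <- as.character(j)
    best <- list(val = Inf, kk = A[1], hh = B[1])
    for (h in B) {
      vk <- c1[ci, as.character(A)] + distances[A, h]
      kk <- which.min(vk)
      tot <- vk[kk] + c2[as.character(h), cj]
      if (tot < best$val - 1e-12) best <- list(val = tot, kk = A[kk], hh = h)
    }
    c(layout(k1, i, best$kk), layout(k2, best$hh, j))
  }
  root <- n - 1L
  m <- cost[[root]]
  ij <- which(m == min(m), arr.ind = TRUE)[1, ]
  lv <- as.integer(rownames(m))
  layout(root, lv[ij[1]], lv[ij[2]])
}

# greedy bottom-up swivel: at each node try the 4 child orientations
olo_greedy <- function(tree, distances) {
  hc <- tree$hclust
  n <- length(tree$labels)
  orders <- vector("list", n - 1)
  node_order <- function(k) if (k < 0) -k else orders[[k]]
  for (v in seq_len(n - 1)) {
    a <- node_order(hc$merge[v, 1])
    b <- node_order(hc$merge[v, 2])
    cands <- list(c(a, b), c(rev(a), b), c(a, rev(b)), c(rev(a), rev(b)))
    junction <- vapply(cands, function(o)
      distances[o[length(a)], o[length(a) + 1L]], numeric(1))
    orders[[v]] <- cands[[which.min(junction)]]
  }
  orders[[n - 1L]]
}
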