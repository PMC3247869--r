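# shared fixtures: worlds are cached per (preset, seed, overrides) so the
# suite pays for each simulation once

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(preset = "small", seed = 1, ...) {
  key <- paste(preset, seed, deparse(list(...)), collapse = "|")
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- simulate_world(synthetic_params(preset, ...),
                                          seed = seed)
  .world_cache[[key]]
}

# minimal single-replicon annotation from parallel vectors
tiny_annotation <- function(starts, ends, strands,
                            ids = sprintf("g%02d", seq_along(starts)),
                            organism = "orgA", circular = TRUE,
                            length_bases = max(ends) + 100L) {
  genome_annotation(
    data.frame(gene_id = ids, organism = organism, replicon_id = "chr",
               start = starts, end = ends, strand = strands,
               stringsAsFactors = FALSE),
    data.frame(replicon_id = "chr", organism = organism,
               length_bases = length_bases, circular = circular,
               stringsAsFactors = FALSE))
}

# hits table from parallel vectors
tiny_hits <- function(target_gene, organism, ref_gene,
                      e_value = 1e-10, coverage_pct = 90) {
  homology_hits(data.frame(target_gene = target_gene, organism = organism,
                           ref_gene = ref_gene, e_value = e_value,
                           coverage_pct = coverage_pct,
                           stringsAsFactors = FALSE))
}

# exhaustive weighted co-occurrence tail: enumerate all 2^M x 2^M profile
# pairs, condition on the margins, sum the tail mass
enum_weighted_pval <- function(w, n1, n2, overlap) {
  M <- length(w)
  combos <- expand.grid(rep(list(0:1), M))
  pvec <- apply(combos, 1, function(x) prod(ifelse(x == 1, w, 1 - w)))
  sums <- rowSums(combos)
  tot <- 0; tail <- 0
  for (i in which(sums == n1)) for (j in which(sums == n2)) {
    pr <- pvec[i] * pvec[j]
    ov <- sum(combos[i, ] & combos[j, ])
    tot <- tot + pr
    if (ov >= overlap) tail <- tail + pr
  }
  tail / tot
}

# exact run-count distribution by enumeration of all k-subsets of M slots
enum_runs_tail <- function(M, k, r_obs) {
  if (k == 0) return(1)
  sets <- utils::combn(M, k)
  runs <- apply(sets, 2, function(s) {
    x <- integer(M); x[s] <- 1L
    sum(x == 1L & c(0L, x[-M]) == 0L)
  })
  mean(runs >= r_obs)
}

# exhaustive fusion tail: overlap of a random n2-subset with a fixed
# n1-subset out of K candidates
enum_fusion_tail <- function(K, n1, n2, f) {
  if (n2 == 0) return(as.numeric(f <= 0))
  sets <- utils::combn(K, n2)
  mean(apply(sets, 2, function(s) sum(s <= n1)) >= f)
}
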