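# Synthetic pangenome generator.
#
# Generates complete inputs (homology table, genome annotations, gold
# standard) with the statistical structure the scorers assume: homolog
# presence/absence correlated along a random phylogeny, functional modules
# whose genes co-occur and may be co-located on the same strand with small
# intergenic gaps, occasional fused genes, and per-gene frequency bias to
# exercise normalization. Module pairs are exactly the positive labels.

#' Parameters for [simulate_world]
#'
#' Presets: `"small"` (default conditions: modules with co-presence,
#' co-location and fusions), `"null"` (modules exist as labels but carry no
#' signal: zero boost, no co-location, no fusion — scorers should be at
#' chance), `"biased"` (adds strong per-gene frequency spread), and
#' `"fusion-rich"` (high fusion rate).
#'
#' @param preset preset name.
#' @param ... overrides for individual parameters.
#' @return named list of parameters.
#' @export
synthetic_params <- function(preset = c("small", "null", "biased",
                                        "fusion-rich"), ...) {
  preset <- match.arg(preset)
  p <- list(
    n_organisms = 30,        # reference genomes
    n_genes = 60,            # target genes
    n_modules = 8,           # functional modules (disjoint)
    module_size = 3,         # genes per module
    presence_rate = 0.5,     # base homolog presence probability
    copresence_boost = 0.8,  # prob. a module gene copies the module profile
    colocation_prob = 0.5,   # fraction of modules that are co-located
    module_gap = 20L,        # intra-module intergenic gap (bases)
    intergenic_mean = 150,   # mean intergenic gap elsewhere (bases)
    gene_len_range = c(600L, 1200L),
    fusion_rate = 0.15,      # per-organism fusion prob. for fusion pairs
    freq_bias = 0,           # spread of per-gene presence rates (0..0.45)
    noise_rate = 0.02,       # random presence bit flips
    known_function_frac = 1, # fraction of genes in the gold standard
    n_decoy_copresence = 0,  # unlabeled co-evolving gene sets (habitat-
                             # shared distribution without shared function)
    n_decoy_colocation = 0,  # unlabeled co-located blocks (neighbors
                             # without a functional link)
    decoy_size = NULL,       # genes per decoy set (default: module_size)
    decoy_colocation_rate = NULL,  # presence rate of co-location decoy
                             # genes; a high value gives them as many
                             # co-occurring genomes as boosted modules
                             # without profile similarity (default: the
                             # base presence rate)
    evolution_rate_range = c(0.5, 2))
  p <- switch(preset,
    "small" = p,
    "null" = utils::modifyList(p, list(copresence_boost = 0,
                                       colocation_prob = 0,
                                       fusion_rate = 0)),
    "biased" = utils::modifyList(p, list(freq_bias = 0.35)),
    "fusion-rich" = utils::modifyList(p, list(fusion_rate = 0.6)))
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown)) stop("unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    p <- utils::modifyList(p, over)
  }
  if (is.null(p$decoy_size)) p$decoy_size <- p$module_size
  if (p$module_size * p$n_modules + p$decoy_size *
        (p$n_decoy_copresence + p$n_decoy_colocation) > p$n_genes)
    stop("modules plus decoy sets exceed n_genes")
  p
}

# two-state presence/absence evolution down an ape tree: equilibrium pi,
# rate r; returns named 0/1 vector over tips
evolve_presence <- function(tree, pi, rate) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  state <- integer(n_node)
  root <- n_tip + 1L
  state[root] <- as.integer(stats::runif(1) < pi)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    p1 <- pi + (state[parent] - pi) * exp(-rate * tr$edge.length[e])
    state[child] <- as.integer(stats::runif(1) < p1)
  }
  stats::setNames(state[seq_len(n_tip)], tree$tip.label)
}

#' Simulate a synthetic pangenome world
#'
#' Presence/absence of each gene's homolog evolves by a two-state
#' gain/loss process down a random phylogeny; genes of a module share the
#' module's evolved profile with probability `copresence_boost` per
#' organism. Genomes are single circular replicons; co-located modules are
#' placed as contiguous same-strand blocks with small intergenic gaps.
#' Present homologs get E-values drawn log-uniformly in \[1e-30, 1e-6\]
#' (below the 1e-4 homology threshold); absent genes emit no row. Fused
#' genes appear as a single reference gene hit by both partners with
#' coverage above the Rosetta threshold. The gold standard holds all pairs
#' among the known-function gene subset, positive iff the two genes share
#' a module.
#'
#' @param params from [synthetic_params].
#' @param seed RNG seed; the same seed reproduces the world (and its
#'   emitted files) exactly.
#' @return object of class `synthetic_world`: list with `params`, `seed`,
#'   `tree`, `organisms`, `genes`, `modules`, `colocated`, `fusion_pairs`,
#'   `presence` (truth matrix), `hits`, `annotations` (per organism),
#'   `target_annotation`, `labels`, `known_function_genes`.
#' @export
simulate_world <- function(params = synthetic_params(), seed = 1) {
  set.seed(seed)
  np <- params
  organisms <- sprintf("org%03d", seq_len(np$n_organisms))
  genes <- sprintf("g%04d", seq_len(np$n_genes))
  tree <- ape::rtree(np$n_organisms, tip.label = organisms)
  tree$edge.length <- tree$edge.length / mean(ape::node.depth.edgelength(
    tree)[seq_len(np$n_organisms)])

  modules <- split(genes[seq_len(np$n_modules * np$module_size)],
                   rep(seq_len(np$n_modules), each = np$module_size))
  names(modules) <- sprintf("mod%02d", seq_along(modules))
  colocated <- stats::runif(length(modules)) < np$colocation_prob
  module_of <- stats::setNames(rep(NA_character_, length(genes)), genes)
  for (m in names(modules)) module_of[modules[[m]]] <- m

  # decoy structure: correlated presence or co-location without a label
  n_used <- np$n_modules * np$module_size
  take_sets <- function(k) {
    if (k == 0) return(list())
    out <- split(genes[n_used + seq_len(k * np$decoy_size)],
                 rep(seq_len(k), each = np$decoy_size))
    n_used <<- n_used + k * np$decoy_size
    out
  }
  decoy_cop <- take_sets(np$n_decoy_copresence)
  if (length(decoy_cop))
    names(decoy_cop) <- sprintf("dcop%02d", seq_along(decoy_cop))
  decoy_col <- take_sets(np$n_decoy_colocation)
  if (length(decoy_col))
    names(decoy_col) <- sprintf("dcol%02d", seq_along(decoy_col))

  # per-gene equilibrium presence rate (frequency bias knob) and rate
  pi_g <- pmin(pmax(np$presence_rate +
                      stats::runif(length(genes), -np$freq_bias,
                                   np$freq_bias), 0.03), 0.97)
  names(pi_g) <- genes
  if (!is.null(np$decoy_colocation_rate))
    pi_g[unlist(decoy_col)] <- np$decoy_colocation_rate
  rate_g <- stats::runif(length(genes), np$evolution_rate_range[1],
                         np$evolution_rate_range[2])

  # co-presence groups (labeled modules + co-presence decoys) share an
  # evolved master profile
  cop_groups <- c(modules, decoy_cop)
  cop_of <- stats::setNames(rep(NA_character_, length(genes)), genes)
  for (m in names(cop_groups)) cop_of[cop_groups[[m]]] <- m
  master <- lapply(names(cop_groups), function(m)
    evolve_presence(tree, np$presence_rate, stats::runif(
      1, np$evolution_rate_range[1], np$evolution_rate_range[2])))
  names(master) <- names(cop_groups)
  presence <- matrix(0L, length(genes), length(organisms),
                     dimnames = list(genes, organisms))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    own <- evolve_presence(tree, pi_g[g], rate_g[gi])
    m <- cop_of[g]
    if (!is.na(m) && np$copresence_boost > 0) {
      copy <- stats::runif(length(organisms)) < np$copresence_boost
      own[copy] <- master[[m]][names(own)[copy]]
    }
    presence[gi, names(own)] <- own
  }
  flip <- matrix(stats::runif(length(presence)) < np$noise_rate,
                 nrow(presence))
  presence[flip] <- 1L - presence[flip]

  # fusion partners: first two genes of each module
  fusion_pairs <- if (np$fusion_rate > 0 && length(modules))
    do.call(rbind, lapply(modules, function(g)
      data.frame(g1 = g[1], g2 = g[2], stringsAsFactors = FALSE)))
  else data.frame(g1 = character(0), g2 = character(0))

  # co-located blocks: labeled co-located modules + co-location decoys
  blocks <- c(modules[colocated], decoy_col)

  # genome layout helper: returns annotation + instance map gene->ref gene
  layout_genome <- function(org, present_genes, fused_pairs_here) {
    fused_first <- fused_pairs_here$g1
    fused_second <- fused_pairs_here$g2
    placeable <- setdiff(present_genes, fused_second)
    # blocks become contiguous same-strand runs with small gaps
    items <- list()
    used <- character(0)
    for (bl in blocks) {
      mem <- intersect(bl, placeable)
      if (length(mem) >= 2) {
        items[[length(items) + 1]] <- mem
        used <- c(used, mem)
      }
    }
    singles <- setdiff(placeable, used)
    items <- c(items, as.list(singles))
    items <- items[sample.int(length(items))]
    rows <- list()
    pos <- 1L
    for (it in items) {
      block_strand <- if (stats::runif(1) < 0.5) "+" else "-"
      for (k in seq_along(it)) {
        g <- it[[k]]
        len <- sample(np$gene_len_range[1]:np$gene_len_range[2], 1)
        if (g %in% fused_first &&
            fused_pairs_here$g2[match(g, fused_first)] %in% present_genes)
          len <- len * 2L  # fused ORF spans both partners
        strand <- if (length(it) > 1) block_strand else
          if (stats::runif(1) < 0.5) "+" else "-"
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = paste0(org, "_", g), source_gene = g,
          start = pos, end = pos + len - 1L, strand = strand,
          stringsAsFactors = FALSE)
        gap <- if (k < length(it)) np$module_gap else
          1L + stats::rgeom(1, 1 / np$intergenic_mean)
        pos <- pos + len - 1L + gap + 1L
      }
    }
    ann <- do.call(rbind, rows)
    ann$organism <- org
    ann$replicon_id <- paste0(org, "_chr")
    replicons <- data.frame(replicon_id = paste0(org, "_chr"),
                            organism = org,
                            length_bases = pos + 200L, circular = TRUE,
                            stringsAsFactors = FALSE)
    list(annotation = genome_annotation(
           ann[, c("gene_id", "organism", "replicon_id", "start", "end",
                   "strand")], replicons),
         instance = stats::setNames(ann$gene_id, ann$source_gene))
  }

  annotations <- list()
  hit_rows <- list()
  for (org in organisms) {
    present <- genes[presence[, org] == 1L]
    if (length(present) < 2) present <- genes[seq_len(2)]  # avoid empties
    fp <- fusion_pairs[fusion_pairs$g1 %in% present &
                         fusion_pairs$g2 %in% present, , drop = FALSE]
    if (nrow(fp))
      fp <- fp[stats::runif(nrow(fp)) < np$fusion_rate, , drop = FALSE]
    lay <- layout_genome(org, present, fp)
    annotations[[org]] <- lay$annotation
    inst <- lay$instance
    for (g in present) {
      if (g %in% fp$g2) {
        ref <- inst[[fp$g1[match(g, fp$g2)]]]  # hit on the fused gene
        cov <- stats::runif(1, 55, 90)
      } else if (g %in% fp$g1) {
        ref <- inst[[g]]
        cov <- stats::runif(1, 55, 90)
      } else {
        ref <- inst[[g]]
        cov <- stats::runif(1, 80, 100)
      }
      hit_rows[[length(hit_rows) + 1]] <- data.frame(
        target_gene = g, organism = org, ref_gene = ref,
        e_value = 10^stats::runif(1, -30, -6), coverage_pct = round(cov, 1),
        stringsAsFactors = FALSE)
    }
  }
  hits <- homology_hits(do.call(rbind, hit_rows))

  target <- layout_genome("target", genes,
                          fusion_pairs[0, , drop = FALSE])$annotation
  # target gene ids should be the plain gene names
  target$genes$gene_id <- sub("^target_", "", target$genes$gene_id)

  kf <- sort(sample(genes, max(2, round(np$known_function_frac *
                                          length(genes)))))
  pairs <- enumerate_pairs(kf)
  same_mod <- !is.na(module_of[pairs$gene_a]) &
    !is.na(module_of[pairs$gene_b]) &
    module_of[pairs$gene_a] == module_of[pairs$gene_b]
  same_mod[is.na(same_mod)] <- FALSE
  labels <- pair_labels(data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    label = ifelse(same_mod, "positive", "negative"),
    stringsAsFactors = FALSE))

  structure(list(params = np, seed = seed, tree = tree,
                 organisms = organisms, genes = genes, modules = modules,
                 colocated = colocated, decoy_copresence = decoy_cop,
                 decoy_colocation = decoy_col,
                 fusion_pairs = fusion_pairs,
                 presence = presence, hits = hits,
                 annotations = annotations, target_annotation = target,
                 labels = labels, known_function_genes = kf),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic_world: %d genes x %d organisms, ",
                     "%d modules, %d positive pairs (seed %d)\n"),
              length(x$genes), length(x$organisms), length(x$modules),
              sum(x$labels$label == "positive"), x$seed))
  invisible(x)
}

#' Write a synthetic world's input files to a directory
#'
#' Emits `homology.tsv`, `annotations/<organism>.tsv` (internal TSV
#' dialect), `target_annotation.tsv`, `labels.tsv` and `organisms.txt`,
#' all of which round-trip through the package readers.
#'
#' @param world a [simulate_world] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_world <- function(world, dir) {
  dir.create(file.path(dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  write_homology_table(world$hits, file.path(dir, "homology.tsv"))
  for (org in names(world$annotations))
    write_annotation(world$annotations[[org]],
                     file.path(dir, "annotations", paste0(org, ".tsv")))
  write_annotation(world$target_annotation,
                   file.path(dir, "target_annotation.tsv"))
  write_pair_labels(world$labels, file.path(dir, "labels.tsv"))
  write_organism_list(world$organisms, file.path(dir, "organisms.txt"))
  invisible(dir)
}

#' Score matrix with planted per-gene additive bias
#'
#' Builds `score(i, j) = b_i + b_j + signal * 1[positive] + noise` with
#' `b ~ N(0, bias_spread^2)`: the bias model that row normalization is
#' designed to remove. Positive pairs are drawn at random.
#'
#' @param n_genes number of genes.
#' @param bias_spread SD of the per-gene bias (default 1).
#' @param signal additive effect on positive pairs (default 1.5).
#' @param noise_sd SD of pair noise (default 0.5).
#' @param positive_frac fraction of pairs planted positive (default 0.01).
#' @param seed RNG seed.
#' @return list with `matrix` (a [score_matrix]) and `labels`
#'   (a [pair_labels]).
#' @export
planted_bias_matrix <- function(n_genes = 200, bias_spread = 1,
                                signal = 1.5, noise_sd = 0.5,
                                positive_frac = 0.01, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  b <- stats::rnorm(n_genes, 0, bias_spread)
  n_pairs <- n_genes * (n_genes - 1) / 2
  pos <- sample.int(n_pairs, max(1, round(positive_frac * n_pairs)))
  m <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  val <- b[ut[, 1]] + b[ut[, 2]] + stats::rnorm(n_pairs, 0, noise_sd)
  val[pos] <- val[pos] + signal
  m[ut] <- val
  m <- m + t(m)
  labels <- pair_labels(data.frame(
    gene_a = genes[ut[, 1]], gene_b = genes[ut[, 2]],
    label = ifelse(seq_len(n_pairs) %in% pos, "positive", "negative"),
    stringsAsFactors = FALSE))
  list(matrix = score_matrix(m, method = "planted-bias"), labels = labels)
}
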