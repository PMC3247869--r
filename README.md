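# genecontext

Genome context methods infer whether two genes of a bacterial genome are
functionally related — same pathway, same complex — from the behavior of
their **homologs** across a list of reference genomes, without any direct
sequence similarity between the two genes themselves. `genecontext`
implements the four classic method families end to end, plus the
machinery needed to use them well:

* **Phylogenetic profiles** — similarity of presence/absence vectors
  across organisms: Jaccard, Pearson, mutual information, hypergeometric
  p-value, weighted hypergeometric p-value (`pp-wpval`, computed by a
  conditional dynamic program over per-organism inclusion rates), and the
  runs-corrected variant `pp-wpval-with-runs` that discounts
  co-occurrence concentrated in a single clade.
* **Gene neighbor** — relative rank distance between the homologs in each
  genome containing both. With relative distances `p_i = 2 d_i / (N_i - 1)`
  uniform under independence, the product `x = prod p_i` gives
  `gn-lnX = -log x`, its normalized form, and the Gamma-tail p-value
  `gn-pval = x * sum_{k<M} (-log x)^k / k!`.
* **Gene cluster** — intergenic base distance of rank-adjacent,
  same-strand gene pairs, normalized by the genome's genes-per-intergenic-
  base factor `m` (restricted coverage).
* **Gene fusion** — Rosetta-Stone detection (coverage ≥ Q% of both
  queries, E-value ≤ E) with an upper-tail hypergeometric p-value that
  penalizes promiscuous matchers (restricted coverage).

On top of the scorers: row **znorm/rnorm normalization** of the pairwise
score matrix with composed variants and a frequency-stratified
diagnostic; **reference-organism selection** by Jaccard clustering of
organism profiles with distortion pruning, representatives, and exact
optimal leaf ordering (swiveling); **evaluation** (ROC, sensitivity and
precision in the top p%, cumulative accuracy, fold improvement);
**combination** by a spline-calibrated confidence-product rule and by
bagged probability-estimation trees, with similarity-grouped
cross-validation; and a **synthetic pangenome generator** that emits the
complete input data model (homology table, annotations, gold standard)
for fully self-contained testing.

All score matrices share one orientation contract — higher = more
related — with `NA` as the missing-value sentinel.

## Worked example

```r
library(genecontext)

w  <- simulate_world(synthetic_params("small"), seed = 42)
w
#> synthetic_world: 60 genes x 30 organisms, 8 modules, 24 positive pairs (seed 42)

pr <- build_profiles(w$hits, w$genes, w$organisms, e_threshold = 1e-4)
mi <- score_all_pairs_pp(pr, "mutual-info")
gn <- score_all_pairs_gn(w$hits, w$annotations, w$genes, variant = "pval")

evaluate_scores(mi, w$labels, top_pct = c(1, 5))$auroc
#> [1] 0.9683801
evaluate_scores(gn, w$labels, top_pct = c(1, 5))$top$sensitivity[1]
#> [1] 0.4583333

# normalization removes per-gene bias from the raw lnX score
ln <- score_all_pairs_gn(w$hits, w$annotations, w$genes, variant = "lnX")
evaluate_scores(ln, w$labels)$auroc
#> [1] 0.8929696
nm <- normalize_scores(ln, "znorm")
evaluate_scores(nm, w$labels)$auroc
#> [1] 0.9057608

# prune near-duplicate reference organisms
length(select_reference_organisms(pr, max_distortion = 0.5))
#> [1] 17
```

The mutual-information profile score separates module pairs from the
rest almost perfectly on this world (AUROC 0.97); the raw gene-neighbor
p-value finds 46% of the functionally related pairs within the top 1% of
all pairs; z-normalizing `gn-lnX` lifts its AUROC from 0.89 to 0.91 by
removing the per-gene frequency bias; and a within-cluster distortion of
0.5 prunes the 30 reference organisms to 17 representatives.

A thin command-line front end over the same functions lives at
`inst/cli/genomecontext.R` (subcommands `simulate`, `score`, `normalize`,
`select-organisms`, `evaluate`).

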