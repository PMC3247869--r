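---
title: "Genome context methods: models, scores, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome context methods: models, scores, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecontext)
```

Genome context methods infer functional relatedness between two genes of a
target genome without any direct sequence similarity between them. The
evidence is the behavior of their *homologs* across a list of reference
genomes: whether the homologs co-occur (phylogenetic profiles), whether
they sit near each other (gene neighbor), whether the genes are adjacent
and co-directional in the target genome itself (gene cluster), and whether
the two genes appear fused into a single gene elsewhere (gene fusion,
"Rosetta Stone"). This vignette describes the models behind each score,
the package's normalization and combination machinery, the synthetic
pangenome generator used for testing, and the design choices made where
the methodology left genuine freedom.

Throughout, every published score matrix obeys one orientation contract:
**higher always means more related**. Scores whose natural scale runs the
other way (p-values, base-pair distances) are negated at the matrix
boundary, and `NA` is the missing-value sentinel — a restricted-coverage
method's unscored pairs, or a pair whose homologs never co-occur.

## Phylogenetic profiles

The profile of gene $G$ is the binary vector $p(i) \in \{0,1\}$ over
reference organisms $i = 1,\dots,M$, with $p(i)=1$ iff some homology hit
for $(G, i)$ has E-value **strictly below** the homology threshold
(default $10^{-4}$; the strict inequality is a deliberate reading of
"smaller than", so boundary hits are excluded). Six pair similarities are
implemented. With $n_{12}(x,y)$ the 2×2 contingency counts of two
profiles:

* `jaccard` $= n_{12}(1,1) / (M - n_{12}(0,0))$, defined as 0 when both
  profiles are empty;
* `pearson`, the ordinary correlation of the two binary vectors, defined
  as 0 when either profile is constant;
* `mutual-info`, the plug-in mutual information of the empirical joint,
  in nats (natural log — only a scale factor relative to bits);
* `pval`, the upper-tail hypergeometric probability of at least the
  observed co-occurrence count given the margins;
* `wpval`, the same tail under per-organism inclusion probabilities
  $w_i$ (the fraction of all target genes found in genome $i$) instead of
  exchangeable placement. There is no closed form; the package runs a
  dynamic program over organisms that accumulates the joint law of
  (ones in $p_1$, ones in $p_2$, co-occurrences) under independent
  Bernoulli($w_i$) draws and conditions on the observed margins. With all
  weights equal this reduces *exactly* to the hypergeometric tail, which
  is the oracle the tests exploit. Weights are clamped to
  $[10^{-6}, 1-10^{-6}]$ because weights at 0 or 1 collapse the
  conditional law;
* `wpval-with-runs`, the ratio of `wpval` to a runs p-value computed on
  the product profile after reordering the organisms by the swiveled
  cluster tree (below). Co-occurrence concentrated in one clade (a single
  run of 1s) is weak evidence — it may reflect shared ancestry rather
  than shared function — while co-occurrence scattered across the tree
  (many runs) is strong evidence. The null places the $k$ ones of the
  product profile uniformly among the $M$ positions of a **linear**
  arrangement (the ordering has free ends, so a circular null was not
  adopted), and the number of arrangements with exactly $r$ runs is
  $\binom{k-1}{r-1}\binom{M-k+1}{r}$; the score uses the upper tail
  $P(R \ge r_{\mathrm{obs}})$, validated against exhaustive enumeration
  for all $M \le 12$.

## Gene neighbor

For genes $G_1, G_2$ and a genome $i$ with $N_i$ genes containing
homologs of both, the distance $d_i$ is the number of genes between the
closest homolog pair plus one (adjacent genes have $d=1$; a shared
homolog is defined as $d=1$ rather than 0, so one genome can never zero
out the whole product). On a circular replicon the shorter arc is used.
Under independence on a circular chromosome the relative distance
$p_i = 2d_i/(N_i - 1)$ is uniform on $(0,1]$ (clipped at 1). Across the
$\tilde M$ genomes containing both homologs,

$$x = \prod_i p_i, \qquad \texttt{gn-lnX} = -\log x, \qquad
\texttt{gn-pval} = P(X \le x) = x \sum_{k=0}^{\tilde M - 1}
\frac{(-\log x)^k}{k!},$$

the Gamma$(\tilde M, 1)$ tail of $-\log X$. The package evaluates it as
`pgamma(-log(x), shape, lower.tail = FALSE)`, identical to the truncated
series but stable in log space for large $\tilde M$; the series is kept
as a test oracle. `gn-norm-lnX` divides `lnX` by $\tilde M$ as a simple
bias compensation.

Conventions where the method description is silent: with several homologs
per genome the *minimum* distance is used (the most sensitive
convention); an organism whose two homolog sets live on different
replicons contributes no evidence, because the uniform null assumes a
single chromosome; linear replicons can use the $p = d/(N-1)$ null behind
the `null = "linear"` flag.

## Gene cluster and gene fusion (restricted coverage)

`gc` scores only pairs adjacent in gene rank on the same replicon and
coded on the same strand — operon-style neighbors. The raw score is the
intergenic distance in bases times $m$ = (gene count) / (total
intergenic bases of the genome), which makes the score
genome-independent: rescaling all coordinates uniformly leaves it
unchanged, a property tested exactly. Circular replicons include the
wrap-around adjacency; overlapping genes contribute gap 0. All other
pairs are missing ("infinitely distant"). For an $N$-gene single
replicon at most $N$ pairs are scored.

`gf` declares a reference gene a Rosetta Stone for $(G_1, G_2)$ when at
least $Q\%$ of *each* query is covered by its match (default $Q=50$,
inclusive) and both E-values are at most $E$ (default $10^{-4}$,
inclusive — "at most"). The score is the upper-tail hypergeometric
probability of the observed number of shared matches: out of $K$
candidate reference genes, $G_1$ matches $n_1$, $G_2$ matches $n_2$, and
$f$ are shared. The exact margins of the original database
implementation are not published; this package defines $K$ as the number
of distinct reference genes matched by any target gene at $(Q, E)$, a
reconstruction isolated behind `gene_fusion_pval()` and validated against
subset enumeration for all $K \le 12$. Pairs with no Rosetta Stone are
missing (semantically p-value 1).

## Normalization

Row normalization removes per-gene score bias (for example, frequent
genes inflate `lnX` for *all* their pairs simply by multiplying more
factors). `znorm` centers and scales each row to mean 0, SD 1 over its
non-missing entries; the population (divide-by-$n$) SD is used — the
choice is only a per-row constant. `rnorm` is quantile normalization:
each row is mapped onto the across-rows mean of the sorted rows, ties
receiving the mean of their tied target positions (median and uniform
targets exist behind a flag but gave no consistent gain and are
non-default). Because a row-normalized matrix is no longer symmetric, it
is averaged with its transpose; the *composed* variants re-normalize the
transposed matrix first, compensating for the second gene's bias after
the first gene's has been removed. Composition is what removes an exactly
additive bias $b_i + b_j$ — the package's planted-bias generator
(`planted_bias_matrix()`) plants exactly that structure plus a positive
effect, and the tests check that composed znorm decorrelates the output
from the bias ($|r| < 0.05$ at $n = 200$) and that plain znorm already
strictly improves top-1% sensitivity.

Normalization always runs on the full gene-by-gene matrix, never on an
evaluation subset, and refuses restricted-coverage matrices: with almost
every entry missing, row statistics are meaningless. Missing entries
(including the diagonal) are excluded from all row statistics — the
treatment of genes with no homology information at all is deliberately
"exclude, don't impute".

`frequency_strata_report()` is the standard diagnostic: split pairs by
the homolog frequency of their genes (terciles by default) and compare
score distributions of positive and negative pairs per stratum before
and after normalization; biased scorers show strata misalignment before
and alignment after.

## Reference-organism selection

Closely related reference genomes violate every independence assumption
above. Organism profiles (columns of the profile matrix) are compared
with the Jaccard distance — a true metric — and clustered
agglomeratively (average linkage by default; linkage was a free choice,
with `complete` behind a flag). The tree is pruned at a maximum
within-cluster *distortion*, defined here as the cluster diameter
(maximum pairwise distance; mean-pairwise available behind a flag):
threshold 0 yields all singletons, a threshold at the diameter yields one
cluster, and cluster counts are monotone in the threshold. Each cluster
is represented by the member with the smallest average distance to the
rest, ties to the lowest index. `random_subsets()` provides the matched
random baseline (three replicate lists per size, by convention).

The same tree, *swiveled* — children of each node rotated to minimize
the summed distance between neighboring leaves — provides the organism
ordering for the runs statistic. Up to 25 leaves the package runs the
exact dynamic program over subtree endpoint pairs (optimal over all
$2^{\text{internal nodes}}$ rotations); above that a greedy bottom-up
swivel is used. The tests verify exact $\le$ greedy $\le$ unswiveled on
random instances.

## Evaluation

Gold standards are unordered labeled pairs; $e$ genes yield $e(e-1)/2$
pairs. Sensitivity ($tp/p$) and specificity ($tn/n$) are computed at any
threshold; ROC curves place one point per distinct score so tied scores
move together; `sensitivity_at_top()` selects the top $p\%$ of pairs
(ties at the cut resolved by stable pair-id order, documented because
sensitivities at small $p$ are tie-sensitive). Missing scores always
rank after every scored pair. "Cumulative accuracy" is read as precision
among pairs at or above a threshold — the reading used by confidence
calibration — with the literal recall reading available behind
`reading = "recall"`; the default must not be changed silently since the
two readings differ exactly where the curve is used.

## Combination

The *confidence-product* combiner maps each method's score to a
confidence via a curve fitted to training-set cumulative accuracy — a
cubic smoothing spline (`smooth.spline`, GCV smoothing by default),
clamped to $[0,1]$, then made monotone by an isotonic pass. The isotonic
pass is an addition over the classical recipe: it guards against spline
wiggles at sparse score regions and can be disabled. Outside the fitted
range the nearest endpoint value applies; a missing method contributes
confidence 0 (its sentinel is the worst value). Confidences combine as
$s = 1 - \prod_i (1 - s_i)$, with the maximum rule as the alternative.

The *tree* combiner bags 10 probability-estimation trees, each trained
on $P$ positives and $10P$ negatives resampled with replacement. Trees
are `rpart` classification trees pruned at the cost-complexity value
minimizing internal cross-validated error, with Laplace-smoothed leaf
probabilities patched into the fitted frame; the ensemble predicts the
mean positive-class probability. This is a deliberate stand-in for the
historical minimum-message-length tree software: a pruned
probability-estimation tree with smoothed leaves reproduces the
functional contract (probabilistic outputs, complexity control) with a
standard, testable criterion. Missing features are encoded as a constant
below each feature's observed range and serialized with the model. Gene
pairs involving genes with no homology information are dropped before
training; their outlier scores otherwise distort both combiners.

Cross-validation folds are assigned at the level of *similar-gene group
pairs*: genes are grouped into connected components of the similarity
graph (E-value below $10^{-2}$), unordered group pairs are split into
folds, and a gene pair inherits its group pair's fold — so if
$G_1 \sim G_3$ and $G_2 \sim G_4$, pairs $(G_1,G_2)$ and $(G_3,G_4)$ can
never straddle train and test.

### The bundled combination study

`combination_study()` packages the robustness experiment. The *matched*
worlds carry weak-but-conjunctive signal: labeled modules are both
co-present and co-located (`copresence_boost = 0.5`,
`colocation_prob = 1`), flanked by two decoy families each matched to a
single method — co-presence decoys share the modules' profile
correlation but are scattered around the genome, and co-location decoys
are blocks of *frequent* genes, giving them as many co-occurring genomes
as boosted modules but no profile similarity. A single monotone score
cannot separate positives from its matched decoys; the conjunction can.
The *shifted* training worlds keep the same biology but change the
observation scale (12 reference organisms instead of 30, presence rate
0.4) and are nearly decoy-free, so a combiner trained there never needs
the conjunctive exclusion that the test world demands. Sensitivities at
specificity $\ge 0.99$ are averaged over three replicate test worlds to
damp gold-standard sampling noise. Under matched grouped CV the bagged
trees beat the product rule; under the shifted protocol the trees
typically fall below the best single score while the product rule stays
at or above it — the qualitative conclusion that complex combiners are
the more training-data-sensitive ones. Being a stochastic qualitative
finding, it is seed-dependent at the margins: over most seeds the
pattern holds; occasionally the trees happen to select shift-robust
splits and survive.

## The synthetic pangenome generator

`simulate_world()` emits the complete input data model — homology table,
per-genome annotations, target annotation, gold standard, organism
list — with the statistical structure every scorer assumes:

* presence/absence evolves down a random phylogeny (`ape::rtree`,
  depth-normalized branch lengths) by a two-state gain/loss process with
  per-gene equilibrium rates; module genes copy their module's evolved
  master profile with probability `copresence_boost`;
* genomes are single circular replicons; co-located modules are placed
  as contiguous same-strand blocks with small intergenic gaps (20 bases
  inside blocks, geometric with mean 150 elsewhere; gene lengths uniform
  600–1200 bases) — values chosen once as typical bacterial scales;
* present homologs get E-values log-uniform in $[10^{-30}, 10^{-6}]$,
  safely below the $10^{-4}$ call; absent genes emit *no* row, matching
  sparse real homology tables; coverage is 80–100% for ordinary hits;
* a module's first two genes are fusion partners: in an organism where
  both are present, with probability `fusion_rate` both hit the same
  (double-length) reference gene with coverages 55–90%, above the
  Rosetta threshold;
* positive labels are exactly the within-module pairs over the
  known-function gene subset.

The `null` preset keeps the modules as labels but removes all signal
(zero boost, no co-location, no fusion), which calibrates every scorer
at chance and gives the positional null for `gn-pval`. One lattice
caveat discovered during calibration: the Gamma-tail null assumes
*continuous* relative distances, while a synthetic genome of $N$ genes
offers a grid of spacing $2/(N-1)$, biasing $E[-\log p]$ below 1 by
roughly $\log N / N$ per genome. At real genome scales this is
negligible; for the calibration check the package uses 300-gene genomes,
where the KS distance to uniform is ≈ 0.04 over ~43,000 pairs. This is a
generator artifact, not a scorer defect — the scorer implements the
stated null exactly.

What the generator does **not** emulate: real E-value distributions,
horizontal transfer, paralog families within the target genome
(similarity groups degenerate to singletons unless provided), multiple
replicons, and genome rearrangement rates that vary along the tree.
Passing tests therefore demonstrate correctness of the computations and
the qualitative behavior of the pipeline under its own model
assumptions, not performance on real pangenomes.

## Problem sizes and numerics

The test suite and the acceptance script run worlds of 30–150 genes and
12–30 organisms (300 genes for the null calibration), sizes chosen so
the full suite completes in a couple of minutes while keeping every
statistical check adequately powered. Exhaustive oracles cover
$M \le 10$ (weighted p-value), $M \le 12$ (runs), $K \le 12$ (fusion).
Tails are floored at the smallest positive double rather than 0;
degenerate inputs (constant profiles, empty product profiles, constant
rows, single distinct scores) all take documented finite values rather
than NaN.
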