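---
title: "Phylogeny-aware pan-genome association: models and design choices"
author: "pairGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-aware pan-genome association: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairGWAS)
```

## The problem

Bacterial isolates are related by descent, so a naive association between a
gene's presence/absence and a phenotype across a strain collection is
confounded by population structure: clonally related isolates are not
independent observations, and any gene that happens to track the clonal
background correlates with every phenotype that does too. pairGWAS scores
orthogroup presence/absence against many phenotypes with Fisher's exact
test, then guards each candidate with a statistic that only counts
phylogenetically independent evidence, plus a label-switching permutation
test.

## Contrasting pairs

Given a rooted binary tree over the isolates and a joint labeling of each
leaf by gene state (present/absent) and trait state (positive/negative), a
*contrasting pair* is two leaves that differ in both coordinates. A set of
contrasting pairs is admissible when the tree paths connecting the two
leaves of each pair are mutually edge-disjoint; each admissible pair is then
evidence from an independent part of the phylogeny. The package computes

* `maxPairs` — the maximum size of an admissible set,
* `bestSupporting` / `worstSupporting` — among all maximum-size sets, the
  most and fewest *supporting* pairs (pairs where gene and trait co-vary:
  present/positive against absent/negative),
* `pBest`, `pWorst` — upper tails `P[X >= best]` and `P[X >= worst]` for
  `X ~ Binomial(maxPairs, 1/2)`: if gene and trait were unrelated, each
  independent contrast would support the association with probability 1/2.

Both tails are reported and the interpretation is left to the reader;
`pBest <= pWorst` always holds. The computation is a single postorder
dynamic program per labeling. Each node stores, for each "leftover" state
(an unmatched leaf whose path continues upward, or none), the maximum pair
count in its subtree and the conditional max/min supporting counts. In a
rooted binary tree two leaf-to-leaf paths that share a node necessarily
share an edge, so at most one leftover path crosses any node and this state
space is exact; the implementation (C++) is iterative and therefore
independent of tree depth — a fully unbalanced tree over 13,000 isolates
traverses without recursion limits. An independent exhaustive
branch-and-bound oracle over explicit path edge-sets validates the program
on every tree shape with up to 7 leaves and every one of the 4^7 leaf
labelings in the test suite.

## Label-switching permutation test

The permutation test holds the tree and the gene labels fixed, permutes the
trait labels uniformly over the leaves, and recomputes `bestSupporting`.
The reported empirical p-value is `(1 + #{null >= observed}) / (1 + n)`;
ties count against significance and the value is bounded below by
`1/(n+1)`. The statistic is the optimistic bound (`bestSupporting`), so the
test acts as a post hoc guard on the best-case reading of a candidate. If
the observed labeling admits no contrasting pair at all, the test returns 1
without permuting.

The null distribution depends only on the tree, the gene's presence
pattern, and the number of trait-positive leaves — not on which leaves are
positive. Nulls are therefore cached under a canonical key of the gene
pattern (invariant under child-order swaps, computed bottom-up with two
independent exact modular hashes so the key stays linear-time even on very
unbalanced trees) plus the positive count and the permutation count. Two
orthogroups with identical presence patterns, or the same orthogroup
against many traits with equal positive counts, share one computation. The
permutation RNG is a self-contained splitmix64 stream seeded by a stable
hash of (master seed, pattern key, positive count, n), so p-values are
independent of trait processing order, worker count, and cache state.
Leaves whose trait is missing (or abstained during binarization) are pruned
before the analysis, and trait labels are permuted among the remaining
leaves only.

## Fisher stage and multiple testing

Every orthogroup is first scored with a two-sided Fisher exact test
(probability-mass definition, with the conventional `1 + 1e-7` relative
slack against floating-point ties) on the 2x2 table over isolates with an
observed trait state. P-values are corrected either within each trait or
pooled across all traits and orthogroups (`trait_wise` vs global scope)
with `native` (none), `bonferroni`, or `fdr_bh` (Benjamini–Hochberg
step-up). Only orthogroups whose q-value passes the configured
`method:alpha` gate proceed to the contrasting-pairs statistic and the
permutation test — the expensive step runs on candidates only, which is
what makes many-trait runs tractable; `permuteAll = TRUE` removes the gate.
Records are sorted by ascending Fisher p (ties by orthogroup id) and
truncated to `maxGenes` (default 50). A trait is *significant* when at
least one orthogroup passes the gate; only significant traits appear in the
summary table and receive report bundles. Probabilities are clamped at
1e-300 before log transforms.

## Automatic binarization of continuous phenotypes

The pairwise-comparisons machinery needs binary phenotypes. Numeric traits
are converted per trait by one of:

* **k-means** (`binarizeKmeans`): exact two-cluster partition in one
  dimension (the optimal 2-partition by squared distance is a contiguous
  split of the sorted values, found by prefix-sum scan). Every observed
  isolate is labeled; label 1 is always the larger-mean cluster; exact SSE
  ties place the boundary point in the lower-mean cluster.
* **Gaussian mixture** (`binarizeGmm`, default): a two-component univariate
  mixture fit by EM. An isolate is labeled by the larger-mean component
  only if its maximum posterior probability reaches the cutoff (default
  0.85); otherwise it abstains and is excluded from that trait's
  association. Abstention trades sample size for label confidence, which is
  what rescues weak-effect phenotypes.

Numerical choices for the EM, made deliberately: initialization from the
exact two-means partition (cluster means, weights and within-cluster
variances, variances floored at 1% of the data variance), and convergence
when the mean per-sample log-likelihood improves by less than 1e-3 — the
conventions of mainstream mixture implementations. Both matter. The
unconstrained unequal-variance likelihood in one dimension is unbounded:
a component collapsing onto a few extreme points is the formal MLE, and a
tightly converged EM drifts there even from a good start, silently turning
the binarization into "confident majority class vs abstain". During
development a spread-quantile initialization with a 1e-8 tolerance did
exactly that on well-separated benchmark data (an independent fitter
confirmed the spike as the unconstrained optimum); the two-means start plus
the 1e-3 stopping rule keeps the two-cluster solution. Both choices are
invariant under increasing affine transforms of the data, so labels are
too. *Failure* is operationalized as: no convergence within 500
iterations, a component weight below 2/n, or a variance collapsing below
1e-10 of the data variance; the `onFailure` policy then either skips the
trait (logged) or falls back to k-means. Binary input traits bypass the
module untouched. A 0.5-posterior point — e.g. the exact midpoint of a
symmetric fit — always abstains at any cutoff above 1/2, and raising the
cutoff can only increase the number of abstentions.

## Synthetic data

The simulator provides the two study designs used to validate the method:

* `randomDataset(nGenes, nGenomes)`: i.i.d. Bernoulli(1/2) presence and a
  Bernoulli(1/2) trait — no phylogenetic signal, used for runtime-scaling
  measurements.
* `evolvePangenome(nGenomes, nGenes)`: a uniform random bifurcating
  topology (coalescent-style pairwise joining), each gene evolved from a
  Bernoulli(1/2) root state with a symmetric per-branch gain/loss
  probability (default 0.1, giving realistic levels of homoplasy and
  clade-correlated gene content); fixed genes are re-evolved until
  polymorphic, and the designated causal gene until its frequency lies in
  [20%, 80%]. `simulatePhenotype` then draws N(0, 1) for non-carriers and
  N(effect, 1) for carriers of the causal gene.

`rankRecovery` chains the two with binarization and association and
reports the causal gene's rank per replicate, ranking all orthogroups by
ascending Fisher p with ties broken by empirical permutation p and then
id; Fisher p is the primary key because the output tables are
Fisher-sorted. The default benchmark conditions are 20 replicates per
setting, genome counts {25, 50, 75, 100, 150, 200} and effect sizes
{0.5, 1, 1.5, 2, 3}; a replicate whose trait cannot be binarized at all
scores the sentinel rank `nGenes + 1`. What the simulator does *not*
emulate: recombination and horizontal transfer networks, rate
heterogeneity across branches and genes, measurement error in phenotypes,
and correlated traits — passing benchmarks here demonstrate correct
behavior of the statistical machinery under the stated generative model,
not performance on any particular real collection.

```{r power, eval = FALSE}
ranks <- rankRecovery(nGenomes = 75, effectSize = 1.5,
                      nReplicates = 20, seed = 1)
mean(ranks <= 4)   # fraction of replicates with the causal gene in top 4
```

## Trees

Input trees are newick; square-bracket comments are stripped, duplicate
labels and unbalanced parentheses are fatal. Polytomies (including
unrooted basal trifurcations) are resolved to binary by a left-fold over
children in input order with zero-length edges, with a warning, because
pair counts can depend on the resolution. Branch lengths are carried but
ignored: only the branching pattern enters the statistic, which also means
topology errors propagate into results. When no tree is supplied, a UPGMA
(average-linkage) tree on Hamming distances between binarized genotype
rows is inferred; isolates are pre-sorted lexicographically so the result
is deterministic and invariant to input order. The package uses the tree
root as given and does not re-root.

## Reports

Significant traits are clustered for the overview using symmetrized
distances: numeric pairs use `1 - |Pearson r|` over co-observed isolates,
binary pairs `1 - max(J(a, b), J(a, not b))` with Jaccard index `J`, and
mixed pairs compare the binary trait against the numeric trait's binarized
view. The symmetrization formulas are this package's choice; the goal they
implement is that strongly anti-correlated traits cluster together. Pairs
with fewer than 3 co-observed isolates, and zero-variance traits, get
distance 1. The dendrogram uses average linkage with trait ids pre-sorted
for deterministic tie-breaking, and the per-trait panels show -log10 of
the best Fisher q, the best empirical p, and their product. Per-trait
bundles contain the isolate tree, candidate statistics with 2x2 pie
counts, a coverage matrix of raw gene counts (plus gene-identifier lists
when the input was a gene-list table), raw numeric values with class
labels (abstained isolates marked `excluded`), and verbatim hyperlink URL
templates — the same information an interactive results viewer needs, as
static TSV/JSON.

## Determinism and parallelism

A single master seed governs every stochastic stage; per-unit streams are
derived by stable string hashing, so adding or removing traits never
changes other traits' results, and outputs are byte-identical for any
worker count (`nCpus`) and for cold vs warm permutation caches. The
configuration echo (`config.tsv`) and the timing log (`run.log`) record
the invocation rather than results and are the only files expected to
differ between such runs. Test-suite and benchmark problem sizes (e.g. 20
replicates, 75 genomes, ~100 genes, 6x6 scaling subgrid of the [5..100]
range) were chosen to exercise the study conditions at desk scale.

## Known limitations

* Only binary phenotypic transitions are modeled; Brownian-motion-style
  continuous-trait tests are out of scope.
* The permutation p-value is Monte Carlo, bounded below by `1/(n+1)`.
* A gene/trait combination explained by a single ancestral event yields
  few contrasting pairs and cannot reach significance in the post hoc
  test — by design, at some cost in power.
* Orthogroup counts above 1 are binarized at presence >= 1 for the
  association; raw copy numbers appear only in coverage matrices.
* The 85% cutoff is applied to the maximum posterior; with two components
  this is the same as the assigned component's posterior.
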