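---
title: "Iterative random forests, leave-one-out networks, and GO permutation validation"
author: "irfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative random forests, leave-one-out networks, and GO permutation validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irfnet)
```

# The problem

Gene-expression compendia routinely carry tens of thousands of genes measured
over a few hundred genotypes. Which genes predict which other genes? Pairwise
correlation answers a weaker question (which genes co-vary), while a random
forest trained to predict one gene from all the others measures each
predictor's *conditional* contribution, and does so for non-linear and
interacting effects. `irfnet` implements this programme in three layers:

1. **Weighted-candidate random forests** (`growForest`): CART trees with
   bootstrap resampling in which the features examined at each node are drawn
   from a *weighted* distribution rather than uniformly.
2. **Iterative random forests** (`runIRF`): a Lasso-like boosting loop in
   which each forest's normalized impurity importance becomes the sampling
   weights of the next forest, progressively eliminating irrelevant features.
3. **iRF-LOOP** (`irfLoop`): one iRF per gene, with that gene as target and
   all others as predictors; the final importance vectors are assembled into
   a directed, column-normalized adjacency matrix — a Predictive Expression
   Network (PEN).

A PEN is validated against prior knowledge by intersecting its thresholded
edge set with a Gene Ontology co-annotation network and standardizing the
resulting intersect score against a node-label permutation null
(`scoreAgainstGO`).

# The forest model

Trees are grown by standard CART recursion. A node holding samples with
response $y$ is split at the (feature, threshold) pair maximizing the
impurity decrease; candidate thresholds are the midpoints between consecutive
distinct sorted values of a candidate feature. For regression the decrease is
the drop in the within-node sum of squared deviations,

$$\Delta = \mathrm{SS}(\text{parent}) - \mathrm{SS}(\text{left}) - \mathrm{SS}(\text{right}),$$

and for classification the node-proportion-weighted Gini decrease
$\Delta = G_p - \tfrac{n_L}{n}G_L - \tfrac{n_R}{n}G_R$. A node becomes a leaf
when it holds fewer than `2 * minNodeSize` samples, its response is constant,
or no candidate split has strictly positive decrease; there is no depth cap.
Each tree sees a bootstrap sample of $m$ of the $m$ rows, drawn with
replacement. The per-feature **impurity importance** is the sum of $\Delta$
over all nodes splitting on that feature, across all trees, divided by the
number of trees; a feature never split on scores exactly zero.

## Weighted candidate sampling

At every node, `mtry` candidate features are drawn *without replacement*
from the current feature weights by sequential draws with renormalization:
each draw picks feature $j$ with probability $w_j / \sum_{k \in
\text{remaining}} w_k$ and removes it. A feature with weight zero can never
be drawn, so it can never be split on — this is what makes the iterative
loop's feature elimination absorbing.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nTrees` | 500 | trees per forest; see `recommendTreeCount` below |
| `mtry` | $\lfloor\sqrt{p}\rfloor$ | candidate features per node |
| `minNodeSize` | 5 (regression), 1 (classification) | leaf-size floor |
| `nIterations` | 3 | iRF boosting iterations |
| `masterSeed` | 1 | root of all derived seeds |

`recommendTreeCount(p, mtry, coverage)` sizes a forest so a given feature has
probability at least `coverage` (default 0.95) of entering a candidate set in
the first two tree layers (three decision nodes) of at least one tree. Each
node includes a given feature with probability `mtry/p`; we solve the
conservative exponential-rate form $1 - e^{-3T\,\mathrm{mtry}/p} \ge c$,
i.e. $T = \lceil -\ln(1-c)\,p\,/\,(3\,\mathrm{mtry}) \rceil$, which never
recommends fewer trees than the exact binomial form. At $p = 1.71$ million
features and $\mathrm{mtry} = 1308$ it recommends 1306 trees, consistent with
running $\sqrt{p}$-scale forests on million-SNP panels. The three-node
reading of "the first two layers" is an interpretive choice; the package
documents it rather than claiming it as an external fact.

# Determinism across workers

A forest is reproducible from `(data, weights, parameters, masterSeed)`
alone. Tree $t$'s seed is `deriveSeed(masterSeed, 1, t)`, a pure splitmix64
hash independent of how trees are partitioned across workers
(`planSubforests`), so aggregating sub-forests is plain concatenation and the
result is bit-identical for any worker count. The same scheme yields
per-iteration seeds (`stream 2`) and per-target seeds in the LOOP
(`stream 3`). All tree-level randomness flows through a self-contained
splitmix64 generator rather than compiler-dependent standard-library
distributions, so results are reproducible across platforms, not only across
partitions.

Two fine points about determinism that the test suite pins down:

* **Tie-breaking.** Equal impurity decreases break to the lowest feature
  index, then the lowest threshold. Ties are not merely theoretical: under
  bootstrap resampling an extreme sample is often duplicated, and *any*
  feature can isolate those copies with an identical decrease. The
  deterministic tie-break keeps runs reproducible, but it is not equivariant
  under feature relabeling; the invariant that *is* exact — identical fitted
  partitions, hence identical training predictions and total importance — is
  what the symmetry test asserts (with `mtry = p` and bootstrap disabled,
  where a tree is a pure function of the sample set).
* **Split arithmetic.** Decreases are computed from cumulative sums in
  stable sorted order, so an independent oracle using `cumsum()` in R
  reproduces the chosen split bit for bit; the oracle-equivalence test
  exploits this.

# The iterative loop

Iteration 1 grows an unweighted forest. Iteration $k+1$ uses
`normalizeImportance` (sum-normalization, no floor) of iteration $k$'s
importance as sampling weights. Zero importance therefore stays zero
forever, and weight concentrates on features that keep earning impurity
decrease — the planted-signal tests assert that a true parent's normalized
share rises monotonically from iteration 1 to the last. An all-zero
importance vector (nothing was learned) falls back to uniform weights with a
warning rather than failing. If `weightsPath` is set, weights are written
after each iteration and re-read before the next at full double precision
(`%.17g`), so the file-mediated run is bit-identical to the in-memory run.

# iRF-LOOP and thresholding

For an $n$-gene matrix, `irfLoop` runs $n$ independent iRFs (target gene $j$
against the other $n-1$), zeroes each target's self-importance, and
column-normalizes: every column sums to 1 or is all zero (constant targets
produce a warning and a zero column). The matrix is directed and asymmetric
by construction — A may predict B better than B predicts A — and no test
asserts symmetry.

`thresholdEdges` pools the strictly positive entries, takes the
`ceiling(f * count)`-th largest as the cutoff, and keeps every edge at or
above it. Ties at the cutoff are included, so edge counts can slightly
exceed the nominal fraction; this also makes the thresholded networks nested
($f_1 \le f_2$ implies the $f_1$-network is a subset of the $f_2$-network).
Thresholding is over the pooled nonzero distribution, not per column.

# GO validation

`buildGONetwork` connects genes sharing a term. A term annotated to $n$
genes contributes all $\binom{n}{2}$ pairs at weight $1/(n-1)$: a pair
linked by a rare, specific term is worth up to 1, while broad terms
contribute little, and terms with 1000 or more genes (strictly) are dropped
entirely. A pair sharing several terms keeps its maximum weight. The
**intersect score** of a predicted network is the sum of GO weights over the
unordered gene pairs present in both networks — a pair predicted in both
directions counts once.

The **permutation null** relabels the predicted network's own node set by a
uniform random bijection 1000 times (the GO network is never permuted;
predicted-network genes absent from GO are retained, where they dilute
permuted scores) and rescores. The **t-statistic** is
$(\text{observed} - \bar{s}_{\text{null}}) / \mathrm{sd}_{\text{null}}$ with
the sample ($n-1$) standard deviation — the convention chosen here for an
empirical null of 1000 draws. `nullQQPlot` provides the normality
diagnostic that justifies reading the t-statistic on a normal scale.

`coexpressionNetwork` is the comparator: all-pairs Pearson correlation,
ranked by $|r|$ (treating repression and activation symmetrically — the
signed value is preserved in the output), thresholded with the same
tie-inclusive rule. Constant genes are excluded with a warning.

# Synthetic data: what it emulates and what it does not

The generators make every stage testable without external downloads:

* `simulateExpression` draws root genes as standard normal and each child as
  the effect-weighted sum of its parents plus Gaussian noise
  (`noiseSd = 0.2` by default) — a linear-Gaussian DAG, the simplest
  structure whose parents forest importance provably detects.
  `randomPlantedNetwork(20, 15)` with 200 samples is the reference recovery
  condition used by the tests; effect magnitudes are uniform in
  $[0.75, 1.25]$ with random sign, so planted signals are strong but not
  degenerate against the noise floor.
* `generateGOAnnotations` builds terms of requested sizes with controllable
  inter-term overlap, enough to exercise the $1/(n-1)$ weight law, the max
  collapse, and the strict term-size cutoff.
* `generateEQTLDataset` draws 0/1/2 dosages binomially at uniform random
  minor-allele frequencies, plants additive effects into a normal-noise
  target, and applies missingness after the target is formed.
  `filterGenotypes` then applies the panel filters (MAF strictly greater
  than 0.01, missing fraction strictly below 10%, mean-dosage imputation
  afterwards).

None of this reproduces real expression data: no heteroscedastic TPM noise,
no shared batch or population structure, no linkage disequilibrium, no
nonlinear or epistatic regulation. Passing the recovery tests therefore
shows that the machinery ranks genuinely predictive features above noise
under favourable, known-truth conditions — not that any particular biological
network would be recovered at these settings.

# Numerical and degenerate-case decisions

* Split thresholds are midpoints of consecutive distinct values; a midpoint
  that underflows onto a neighbouring value is skipped.
* Impurity decrease must be *strictly* positive to split; constant-target
  nodes are leaves before any candidate is drawn.
* `normalizeColumns` leaves all-zero columns untouched; `normalizeImportance`
  warns and falls back to uniform.
* Degenerate permutation nulls (zero standard deviation, e.g. a complete
  graph whose edge set is label-invariant) raise an error rather than
  returning an infinite t-statistic.
* Classification majority votes and leaf majorities break ties to the first
  class level.
* Seeds derived by hashing stay below $2^{53}$ and fold into the 32-bit
  range where base R's generator is seeded.

# Problem sizes used by the checks

The shipped tests run the method at desk scale, chosen so the suite
exercises every contract in about a minute: determinism is checked on a
1000-feature, 200-sample iRF (100 trees, 3 iterations, worker counts 1, 2
and 4); root-split oracle equivalence on 200 random instances of up to 50
samples by 5 features; planted-network recovery on the 20-gene, 15-edge,
200-sample condition (3 iterations, 300 trees, 5 seeds, mean AUROC at least
0.85); and the permutation-null checks on synthetic GO networks over 200
genes with 1000 permutations. The eQTL recovery benchmark uses 400 SNPs,
300 samples and 3 planted effects over 10 seeds.

# Known limitations

* The forest core is single-threaded; `nWorkers` controls partitioning (and
  proves the aggregation contract) but not wall-clock parallelism.
* Importance is impurity-based only; permutation importance is out of scope.
* GO scoring uses literal shared annotations — no ancestor-term propagation
  up the ontology graph, and no enrichment p-values.
* The co-expression comparator ranks by $|r|$; whether signed ranking is
  preferable is data-dependent and left to the caller (the signed weight is
  reported).
* `readVCFDosage` handles biallelic GT records only; multiallelic records
  are counted and skipped, not decomposed.
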