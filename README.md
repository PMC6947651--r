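# irfnet

Iterative random forests and Predictive Expression Networks, with Gene
Ontology permutation validation.

## What it is for

Given a gene-expression matrix (genes × samples), which genes predict which
other genes? `irfnet` answers this with **iRF-LOOP**: for each gene *j*, an
iterative random forest (iRF) is trained to predict gene *j* from all other
genes, and the per-gene impurity importances are assembled into an *n* × *n*
directed adjacency matrix — a **Predictive Expression Network (PEN)** —
whose entry (*i*, *j*) is gene *i*'s importance for predicting gene *j*.
The same machinery runs single-target analyses where the features are SNP
dosages and the target is one gene's expression (an explainable-AI eQTL
scan), including the standard biallelic-panel filters (MAF > 0.01, < 10%
missing).

An iRF chains forests: iteration 1 is an ordinary random forest; each later
iteration samples its candidate features at every tree node from the
previous iteration's sum-normalized importance,

> w⁽ᵏ⁺¹⁾ = I⁽ᵏ⁾ / Σ I⁽ᵏ⁾,  I = impurity importance (Δ sum-of-squares for
> regression, weighted Gini decrease for classification, summed over splits
> and divided by the number of trees),

so irrelevant features are progressively eliminated (weight 0 is absorbing).
Forests are grown from deterministically seeded sub-forests: tree *t*'s seed
is a pure hash of (masterSeed, *t*), so the aggregate is **bit-identical for
any worker count**.

A PEN is validated against known biology by thresholding it to its top
edges, intersecting with a **GO co-annotation network** (genes sharing a
term of *n* < 1000 genes are connected at weight 1/(*n*−1), max over shared
terms), and standardizing the summed weight of shared pairs against a null
of 1000 random node-label permutations:

> t = (observed − null mean) / null s.d.

Seeded synthetic generators (planted regulatory DAGs, term-structured
annotations, genotype panels with planted eQTLs) make the whole pipeline
testable without external data.

## Worked example

```r
library(irfnet)

net <- randomPlantedNetwork(8, 6, noiseSd = 0.2, seed = 4)   # 8 genes, 6 true edges
sim <- simulateExpression(net, 150, seed = 4)
pen <- irfLoop(sim$X, nIterations = 3, nTrees = 200, masterSeed = 4)
pen
#> PredictiveNetwork: 8 genes, 56 nonzero directed edges

thresholdEdges(pen, 0.10)       # top 10% of nonzero edge scores
#>   source target    weight
#> 1     g4     g7 0.9945638
#> 2     g7     g4 0.9942977
#> 3     g1     g5 0.9933407
#> 4     g5     g1 0.9895019
#> 5     g3     g8 0.9109492
#> 6     g3     g2 0.8835909
```

Five of the six top edges correspond to planted edges (g4→g7, g1→g5, g3→g8
among the truth; prediction is near-symmetric, so reverse edges score high
too — direction reflects predictive weight, not causal orientation). Scoring
against module-structured annotations:

```r
ann <- data.frame(gene = c("g2","g3","g8", "g1","g5","g6", "g4","g7"),
                  term = rep(c("GO:MOD1", "GO:MOD2", "GO:MOD3"), c(3, 3, 2)))
go  <- buildGONetwork(ann)
scoreAgainstGO(thresholdEdges(pen, 0.10), go, nPermutations = 1000, seed = 4)
#> ScoreReport: intersect score 2.5000 | null mean 0.5575, s.d. 0.5773 (1000 permutations) | t = 3.36
```

The observed intersect score sits 3.4 null standard deviations above random
relabelings: the network has recovered annotated structure well beyond
chance. For forest sizing at scale, `recommendTreeCount(1710000, 1308)`
returns `1306`: the tree count giving every one of 1.71 million features a
95% chance of entering a candidate set in the first two layers of at least
one tree.

A thin command-line wrapper covers the same pipeline
(`inst/cli/irfnet.R`; commands `irf`, `loop`, `score-go`, `coexpr`,
`simulate`, `filter-genotypes`), e.g.

```sh
Rscript inst/cli/irfnet.R simulate expression --genes 20 --edges 15 --out-prefix sim
Rscript inst/cli/irfnet.R loop --input sim.expr.tsv --trees 300 --seed 1 \
        --top-fraction 0.01,0.1 --out-prefix pen
```

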