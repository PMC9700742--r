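# hypergraphMT

Mixed-membership community detection and hyperedge prediction in weighted
hypergraphs.

Many relational systems — group conversations, co-voting, gene–disease
associations, co-purchasing — record interactions among *sets* of units, not
just pairs. Reducing such data to a graph by clique expansion multiplies
every size-`d` interaction into `d(d-1)/2` edges and can both distort
community structure and blow up computation. `hypergraphMT` models the
hypergraph directly: it infers overlapping community memberships, assigns a
probability of existence to *any* candidate hyperedge (missing-data
prediction), and samples synthetic hypergraphs with planted communities. It
is aimed at network scientists and computational biologists working with
higher-order interaction data.

## The model

Each potential hyperedge `e` (any node subset of size `2..D`, with `D` the
maximum observed size) carries an independent Poisson count

```
A_e ~ Poisson(λ_e),   λ_e = Σ_k  w_{d_e k}  Π_{i ∈ e} u_{ik}
```

where `u` is an `N × K` nonnegative membership matrix and `w` a
`(D−1) × K` assortative affinity matrix (`w_{dk}` = density of size-`d`
hyperedges inside community `k`). A hyperedge is likely when *all* its
members share mass in the same community; a single zero membership nulls
the contribution. Inference is maximum likelihood (or MAP, with a sparsity
prior or simplex-constrained memberships) via EM:

* **E-step** — responsibilities `ρ_{ek} ∝ w_{d_e k} Π_{i∈e} u_{ik}`;
* **M-step** — multiplicative updates
  `u_{ik} = Σ_e B_{ie} ρ_{ek} / Σ_{e∈Ω, i∈e} w_{d_e k} Π_{j≠i} u_{jk}` and
  `w_{dk} = Σ_{e: d_e=d} A_e ρ_{ek} / Σ_{e∈Ω: d_e=d} Π_{j∈e} u_{jk}`.

The denominators sum over the combinatorially large space `Ω` of all
potential hyperedges. They are evaluated in `O(NDK)` — no enumeration —
through elementary symmetric polynomials of the membership columns,
`C_k(d) = Σ_{|S|=d} Π_{j∈S} u_{jk}`, maintained incrementally with
leave-one-out deflation (`C_k(d) = C_k^{(−i)}(d) + u_{ik} C_k^{(−i)}(d−1)`).
Hyperedge prediction scores a candidate by its Poisson positivity
probability `1 − exp(−λ_e)`; the clique-expansion baseline (Graph-MT)
scores it as the product of its pairs' probabilities, and Pairs-MT uses
only the registered pairwise interactions.

## Worked example

Sample a two-block hypergraph with 10% overlapping nodes from the model
itself, refit it, and evaluate:

```r
library(hypergraphMT)
st  <- plantedState(N = 60, K = 2, DMax = 3, overlap = 0.1,
                    wStrength = c(0.12, 0.01), seed = 3)
h   <- sampleHypergraph(st, seed = 3)
h
#> Hypergraph: 60 nodes, 166 hyperedges (total weight 177)
#>   sizes: 2..3 (mean 2.43), % pairwise 57.2%

fit <- fitHypergraphMT(h, K = 2, nRestarts = 10, seed = 7)
fit
#> LatentState: N = 60 nodes, K = 2 communities, sizes 2..3
#>   log-likelihood -728.554 (restart 8 of 10, converged)

meta <- setNames(c("block1", "block2")[max.col(st@u)], nodeLabels(h))
f1VsMetadata(fit, meta)                      # 0.933
cosineVsMetadata(fit, meta)$mean             # 0.947
existenceScoreHyper(fit, c(1, 2))            # within-block pair: 0.067
existenceScoreHyper(fit, c(1, 60))           # cross-block pair:  0

cv <- crossValidate(h, K = 2, folds = 5, seed = 11, nComparisons = 1000)
round(cv$mean, 3)
#> hypergraph hypergraph_pairs  graph  graph_pairs  pairs
#>      0.778            0.742  0.776        0.732  0.558
```

The F1 (0.93) and cosine similarity (0.95) say the hard and soft partitions
recover the planted blocks up to the deliberately overlapping nodes. The
existence scores show the assortative structure the fit learned: a
within-block pair has a 6.7% chance of interacting, a cross-block pair
essentially none. The cross-validated AUCs (chance = 0.5) show both
higher-order and clique-expansion fits predict held-out hyperedges well on
this easy benchmark, while the pairs-only baseline — blind to the 43% of
interactions that are triples — trails.

Workflow wrappers (`runFit`, `runSample`, `runCV`, `runSummarize`) write
CSV/JSON artifacts with recorded seeds; a thin command-line dispatcher over
them ships in `inst/cli/hypergraph-mt.R`.

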