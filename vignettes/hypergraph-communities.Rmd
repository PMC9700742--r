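---
title: "Modelling overlapping communities in hypergraphs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling overlapping communities in hypergraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypergraphMT)
```

## The generative model and its assumptions

A weighted hypergraph on `N` nodes records, for each observed hyperedge
`e` of size `d_e >= 2`, a positive integer count `A_e` — how many times
that exact group interacted. `hypergraphMT` treats every *potential*
hyperedge (every node subset of size `2..D`, the set `Omega`) as an
independent Poisson variable with rate

$$\lambda_e \;=\; \sum_{k=1}^{K} w_{d_e k} \prod_{i \in e} u_{ik},$$

where `u` (`N x K`, nonnegative) holds mixed memberships and `w`
(`(D-1) x K`, nonnegative) holds per-size within-community densities. The
model is *assortative*: a hyperedge's rate only collects contributions from
communities in which **all** its members carry mass, so one zero membership
nulls a community's term. This is the restriction that keeps the affinity
object a matrix rather than a `K^d` tensor per size, and it encodes the
homophily assumption that groups form inside communities. Conditional
independence of hyperedges given `(u, w)` is assumed throughout. Three
consequences worth keeping in mind:

* weights are counts; continuous weights would need a different emission;
* `Omega` is truncated at the maximum *observed* size `D` — the model
  assigns no mass to larger hyperedges, and sizes in `2..D` that were never
  observed keep their affinity row at zero, which removes them from the
  likelihood penalty automatically;
* the model has no degree correction: hub structure is absorbed into
  membership magnitudes.

## Inference

The log-likelihood (parameter-free factorial term dropped) is

$$L(u, w) = -\sum_{e \in \Omega} \lambda_e
            + \sum_{e \in \mathcal{E}} A_e \log \lambda_e .$$

Jensen's inequality with a per-hyperedge variational distribution
`rho_{ek}` over communities gives the EM algorithm implemented in
`fitHypergraphMT()`: the E-step sets `rho_{ek}` proportional to
`w_{d_e k} prod_i u_{ik}` (`eStep()`), the M-step applies the closed-form
multiplicative updates of `u` then `w` (`updateU()`, `updateW()`). Both
steps are exact conditional maximizations, so the bound — and hence the
log-likelihood evaluated after each full iteration — is non-decreasing; the
test suite checks this to `1e-9` on planted instances.

### Sums over the potential-hyperedge space

The update denominators and the penalty term sum over all
`choose(N, 2) + ... + choose(N, D)` potential hyperedges. Because the rate
factorizes, these reduce to elementary symmetric polynomials of the
membership columns,

$$C_k(d) = \sum_{|S| = d} \prod_{j \in S} u_{jk},$$

built once per sweep by the standard one-node-at-a-time recurrence in
`O(NDK)` (`buildSymPoly()`). The per-node denominators need the
leave-one-out values, obtained by deflation
`C_k^{(-i)}(d) = C_k(d) - u_{ik} C_k^{(-i)}(d-1)` and refolded with the
freshly updated entry, so a full membership sweep costs `O(NDK)` instead of
enumerating subsets. The whole scheme is guarded by brute-force subset
enumeration in the tests (instances up to `N = 12`, `D = 4`, `K = 3`,
agreement to `1e-8` relative).

Numerical hygiene for the deflation: subtraction can cancel
catastrophically when `u_{ik} C^{(-i)}(d-1)` nearly equals `C(d)`.
Negative intermediates within `-1e-12` are clipped to zero; anything more
negative triggers a full cache rebuild for the node, and every sweep starts
from a fresh cache, so drift cannot accumulate across iterations (the
refolded cache is additionally tested against a fresh build to `1e-6`).

### Degenerate and ill-conditioned cases

An observed hyperedge whose rate is identically zero cannot be attributed;
its responsibility row is set uniform and flagged (`degenerate` attribute /
slot) rather than raising, which keeps the M-step defined while signalling
model–data incompatibility. A zero numerator zeroes the membership entry
(zeros are absorbing under multiplicative updates); a zero denominator
against a positive numerator leaves the entry unchanged for that sweep and
flags the node as ill-conditioned. `-Inf` log-likelihoods are reported, not
raised.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | — | number of communities; in metadata-driven analyses set to the number of attribute categories |
| `nRestarts` | 10 | independent random initializations; the fixed point with the largest log-likelihood wins |
| `maxIter` | 500 | EM iterations per restart |
| `tol` | `1e-6` | relative log-likelihood change; convergence requires it at two consecutive checks |
| `checkEvery` | 10 | iterations between convergence checks |
| `mode` | `"ml"` | `"sparsity"` adds an exponential-prior rate to membership denominators; `"normalized"` keeps membership rows on the simplex |
| `gamma` | 1 | sparsity-prior rate (dimensionless, same scale as the denominators) |

Initialization draws every `u` and (observed-size) `w` entry independently
uniform on `(0, 1)`; restart `r` uses seed `seed + r - 1`, so a fit is a
pure function of `(data, K, seed, options)`.

Design choices that were genuinely open, and how we resolved them:

* **MAP variants.** The sparsity mode is realized as an exponential prior
  on `u`, whose MAP update adds the constant rate `gamma` to each
  denominator — one admissible member of the family of priors that
  contribute a denominator constant. The normalized mode renormalizes each
  row immediately after its multiplicative update (zero rows become
  uniform); renormalizing only at convergence would be the other option,
  but per-iteration renormalization keeps the iterates interpretable as
  probability vectors throughout.
* **Duplicate hyperedges** in input merge by summing weights: counts of
  repeated events add.
* **Clique-expansion weights** on a pair sum over the hyperedges containing
  it, preserving total pairwise interaction counts.
* **c-core peeling** (`cCore()`) uses the unweighted node degree (number of
  incident hyperedges) as the threshold quantity — the only reading that
  typechecks for nodes — with hyperedges shrinking as members are peeled
  and dropped below size 2; shrunken hyperedges that collide are merged.
* **`M` statistic.** Summaries expose `M` as the total weight
  `sum_e A_e` (and `E` as the number of distinct hyperedges); other
  conventions exist for "number of weighted hyperedges", so the summary
  labels both explicitly.
* **Pairwise reduction.** On an input with only size-2 hyperedges the
  updates coincide (to `1e-10` in the tests) with a directly coded
  assortative pairwise mixed-membership model, i.e. the graph special case
  of the same family.

## The synthetic-data generator

`plantedState()` + `sampleHypergraph()` generate benchmarks *from the model
itself*: hard contiguous blocks (optionally with an `overlap` fraction of
nodes splitting mass between two blocks), a common assortative strength per
size, and independent Poisson draws for every potential hyperedge.
`injectNoisyHyperedge()` reproduces the spurious-event construction — one
size-20 hyperedge joining 10 fresh "guest" nodes to 10 random existing
nodes — used to probe robustness of hypergraph fits versus clique-expanded
fits.

What the generator emulates: block community structure, size-dependent
densities, Poisson-weighted repeat interactions, membership overlap. What
it does not: degree heterogeneity, size distributions decoupled from the
affinity (e.g. heavy-tailed hyperedge sizes), non-assortative mixing, and
any generating process different from the model's own. Passing recovery
tests on these benchmarks therefore demonstrates correctness of the
inference machinery under the model's assumptions — not performance on
real data, where the model is at best a useful approximation. Sampling
enumerates the potential space explicitly and refuses (with a clear error)
instances where `sum_d choose(N, d)` exceeds `10^6`; the package targets
benchmark-scale generation, not scalable simulation.

## Evaluation protocols

* **Hyperedge prediction** (`crossValidate()`): distinct hyperedges are
  split uniformly into 5 folds (train = 80%); a candidate's score is the
  Poisson positivity probability `1 - exp(-lambda_e)` — any strictly
  increasing transform of the rate gives the same AUC, positivity is simply
  the probabilistically meaningful one. The clique-expansion baseline
  scores a hyperedge as the product of its pairs' existence probabilities,
  and the pairs-only baseline is evaluated on held-out pairs (with the
  hypergraph and graph models also reported on that subset for a balanced
  comparison). Held-out hyperedges larger than the training `D` get score
  0 — the trained model assigns them no mass.
* **Sampled AUC** (`aucScores()`): `10^3` positives drawn with replacement
  from the test fold are compared element-wise against negatives sampled to
  match the positives' size distribution exactly, each negative a uniform
  random subset not observed *anywhere* in the dataset (excluding train
  positives avoids mislabelling true hyperedges as negatives; the
  alternative — excluding only test positives — would bias the AUC down).
  `AUC = (#(R1 > R0) + 0.5 #(R1 == R0)) / |R1|`.
* **Community evaluation**: `f1VsMetadata()` hard-assigns by row-argmax
  (ties to the lowest index), matches communities to categories by
  maximum-weight bipartite matching (exhaustive over permutations for
  `K <= 8`), and reports micro-F1, which for single-label assignments
  equals the matched accuracy; `cosineVsMetadata()` is the soft
  counterpart; `majorityProfile()` labels hyperedges by strict-majority
  attribute (ties kept as their own class) and profiles each node's
  incident labels. All metrics are invariant to community relabelling.

## Problem sizes and numerical tolerances used in the checks

The test suite and the reproduction script run at benchmark scale, chosen
so that brute-force enumeration remains an exact oracle and a full run
stays interactive: oracle instances up to `N = 12, D = 4, K = 3` (100
instances, `1e-8` relative); monotonicity on 20 planted two-block
hypergraphs (`N = 50, D = 3`, drop tolerance `1e-9`); recovery on
`N = 100, K = 2, D = 3` with within-block pair rate 0.1 and triple rate
0.005 — sparse but clearly assortative, about 400 observed hyperedges —
demanding 90% accuracy in at least 80% of 20 seeds; robustness with 20
seeds of the size-20 guest construction. These sizes are the package's
benchmark conditions, small enough to audit and large enough for the
effects to be unambiguous.

## Known limitations

* Assortative affinities only; disassortative or core–periphery structure
  is out of reach by construction.
* `K` is fixed by the user; no model selection is provided beyond running
  the CV machinery at different `K`.
* The EM fixed point is local; restarts mitigate but do not guarantee the
  global optimum.
* Sampling and negative-set rejection are enumeration-based and meant for
  desk-scale benchmarks; inference itself scales as `O((N D + E) K)` per
  sweep.
* No degree correction, temporal structure, multilayer hyperedges, or node
  attributes in the likelihood.
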