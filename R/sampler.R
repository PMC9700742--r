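#' Planted-community latent state
#'
#' Builds a latent state with hard block memberships for benchmark
#' generation: nodes are assigned to `K` contiguous, near-equal blocks; an
#' `overlap` fraction of nodes (a seeded random subset) splits its mass
#' equally between its own block and the next one. The affinity is
#' assortative with a common strength per size: `w[d-1, k] = wStrength[d-1]`
#' for every community.
#'
#' @param N number of nodes (`N >= K`).
#' @param K number of communities.
#' @param DMax maximum hyperedge size (>= 2).
#' @param overlap fraction in `[0, 1]` of nodes with mixed membership.
#' @param wStrength numeric vector of length `DMax - 1`: the density of
#'   hyperedges of sizes `2..DMax` within each community; recycled scalar
#'   allowed.
#' @param seed RNG seed (used to pick the overlapping nodes).
#' @return A [LatentState-class].
#' @export
plantedState <- function(N, K, DMax = 2, overlap = 0, wStrength = 0.1,
                         seed = 1) {
  stopifnot(N >= K, K >= 1, DMax >= 2, overlap >= 0, overlap <= 1,
            all(wStrength >= 0))
  block <- rep(seq_len(K), length.out = N)
  block <- sort(block)                       # contiguous near-equal blocks
  u <- matrix(0, N, K)
  u[cbind(seq_len(N), block)] <- 1
  nOver <- round(overlap * N)
  if (nOver > 0 && K > 1) {
    set.seed(seed)
    over <- sort(sample.int(N, nOver))
    other <- block[over] %% K + 1L
    u[cbind(over, block[over])] <- 0.5
    u[cbind(over, other)] <- 0.5
  }
  w <- matrix(rep_len(as.numeric(wStrength), DMax - 1), DMax - 1, K)
  latentState(u, w)
}

#' Sample a hypergraph from the generative model
#'
#' Draws, for every potential hyperedge `e` (every node subset of size
#' `2..D`), an independent Poisson count with rate
#' `lambda_e = sum_k w[d-1,k] prod_{i in e} u[i,k]`, and returns the
#' hyperedges with a positive count, weighted by the count. Sampling
#' enumerates the potential-hyperedge space explicitly and is meant for
#' benchmark-scale problems; the enumeration budget guards against
#' accidental combinatorial blow-up.
#'
#' @param state a [LatentState-class]
#' @param seed RNG seed.
#' @param nodeLabels labels for the sampled nodes (default `"n1".."nN"`).
#' @param maxEnumeration cap on `sum_d choose(N, d)`; exceeding it is an
#'   error suggesting a smaller `N` or `D`.
#' @return A [Hypergraph-class] (possibly with zero hyperedges).
#' @export
sampleHypergraph <- function(state, seed = 1,
                             nodeLabels = paste0("n", seq_len(nrow(state@u))),
                             maxEnumeration = 1e6) {
  u <- state@u
  w <- state@w
  N <- nrow(u)
  D <- nrow(w) + 1L
  total <- sum(choose(N, 2:D))
  if (total > maxEnumeration)
    stop(sprintf(paste0("potential-hyperedge space has %.3g subsets, above ",
                        "the enumeration budget %.3g; reduce N or the ",
                        "maximum size (scalable sampling is out of scope)"),
                 total, maxEnumeration))
  set.seed(seed)
  edges <- list(); weights <- numeric(0)
  for (d in 2:D) {
    if (all(w[d - 1, ] == 0)) next
    cmb <- combn(N, d)
    lam <- numeric(ncol(cmb))
    for (k in seq_len(ncol(u))) {
      if (w[d - 1, k] == 0) next
      p <- u[cmb[1, ], k]
      for (r in 2:d) p <- p * u[cmb[r, ], k]
      lam <- lam + w[d - 1, k] * p
    }
    a <- rpois(length(lam), lam)
    hit <- which(a > 0)
    if (length(hit)) {
      edges <- c(edges, lapply(hit, function(j) as.integer(cmb[, j])))
      weights <- c(weights, a[hit])
    }
  }
  m <- .mergeDuplicateEdges(edges, weights)
  new("Hypergraph", nodeLabels = as.character(nodeLabels),
      edges = m$edges, weights = m$weights)
}

#' Inject a large noisy hyperedge
#'
#' Emulates a one-off spurious event — e.g. a party attended by external
#' guests and a random subset of existing nodes — by appending
#' `nNewNodes` fresh "guest" nodes and one hyperedge of the given size
#' containing all guests plus a seeded random subset of
#' `size - nNewNodes` existing nodes, with weight 1. Under clique
#' expansion such a hyperedge floods the graph with `size (size-1) / 2`
#' pairwise edges, which is what makes projected-graph methods fragile to
#' it.
#'
#' @param h a [Hypergraph-class]
#' @param size total size of the injected hyperedge (>= 2).
#' @param nNewNodes number of fresh guest nodes (`size - nNewNodes <= N`).
#' @param seed RNG seed for the choice of existing nodes.
#' @param guestPrefix label prefix for the new nodes.
#' @return A [Hypergraph-class] with `nNewNodes` extra nodes and one extra
#'   hyperedge.
#' @export
injectNoisyHyperedge <- function(h, size, nNewNodes, seed = 1,
                                 guestPrefix = "guest") {
  stopifnot(size >= 2, nNewNodes >= 0, nNewNodes <= size)
  nExisting <- size - nNewNodes
  if (nExisting > numNodes(h))
    stop("size - nNewNodes exceeds the number of existing nodes")
  guests <- character(0)
  if (nNewNodes > 0) {
    guests <- paste0(guestPrefix, seq_len(nNewNodes))
    while (any(guests %in% h@nodeLabels))
      guests <- paste0(guestPrefix, "_", guests)
  }
  labels <- c(h@nodeLabels, guests)
  set.seed(seed)
  existing <- if (nExisting > 0) sort(sample.int(numNodes(h), nExisting))
              else integer(0)
  newEdge <- sort(c(existing, numNodes(h) + seq_len(nNewNodes)))
  m <- .mergeDuplicateEdges(c(h@edges, list(as.integer(newEdge))),
                            c(h@weights, 1))
  new("Hypergraph", nodeLabels = labels, edges = m$edges,
      weights = m$weights)
}
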