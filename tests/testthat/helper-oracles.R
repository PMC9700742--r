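# Brute-force oracles: explicit enumeration of the potential-hyperedge
# space (all node subsets of size 2..D). Deliberately naive and independent
# of the package's symmetric-polynomial path; only usable at small N.

bruteEsp <- function(u, D) {
  N <- nrow(u); K <- ncol(u)
  C <- matrix(0, D + 1, K)
  C[1, ] <- 1
  for (d in seq_len(D)) {
    if (d > N) break
    cmb <- combn(N, d)
    for (k in seq_len(K))
      C[d + 1, k] <- sum(apply(cmb, 2, function(S) prod(u[S, k])))
  }
  C
}

# sum_{e in Omega} lambda_e
bruteOmega <- function(u, w) {
  D <- nrow(w) + 1
  s <- 0
  for (d in 2:D) {
    if (d > nrow(u)) break
    cmb <- combn(nrow(u), d)
    for (k in seq_len(ncol(u)))
      s <- s + w[d - 1, k] *
        sum(apply(cmb, 2, function(S) prod(u[S, k])))
  }
  s
}

# denominator of the membership update for node i:
# sum over potential hyperedges containing i of w_{d,k} prod_{j != i} u_jk
bruteUDenom <- function(u, w, i) {
  N <- nrow(u); D <- nrow(w) + 1
  den <- numeric(ncol(u))
  others <- setdiff(seq_len(N), i)
  for (d in 2:D) {
    if (d - 1 > length(others)) break
    cmb <- combn(others, d - 1)
    for (k in seq_len(ncol(u)))
      den[k] <- den[k] + w[d - 1, k] *
        sum(apply(cmb, 2, function(S) prod(u[S, k])))
  }
  den
}

# denominator of the affinity update: sum over potential size-d hyperedges
bruteWDenom <- function(u, d) {
  cmb <- combn(nrow(u), d)
  vapply(seq_len(ncol(u)), function(k)
    sum(apply(cmb, 2, function(S) prod(u[S, k]))), numeric(1))
}

bruteRate <- function(u, w, e) {
  sum(vapply(seq_len(ncol(u)), function(k)
    w[length(e) - 1, k] * prod(u[e, k]), numeric(1)))
}

bruteLogLik <- function(u, w, h) {
  lam <- vapply(hyperedges(h), function(e) bruteRate(u, w, e), numeric(1))
  if (any(lam == 0)) return(-Inf)
  unname(-bruteOmega(u, w) + sum(edgeWeights(h) * log(lam)))
}

# Independently coded assortative pairwise (graph) model: direct loops over
# node pairs, no symmetric polynomials. Mirrors one EM iteration with the
# same sequential (Gauss-Seidel) node order.
refPairwiseIteration <- function(u, w2, h) {
  edges <- hyperedges(h)
  A <- edgeWeights(h)
  N <- nrow(u); K <- length(w2)
  stopifnot(all(lengths(edges) == 2))
  lam <- t(vapply(edges, function(e)
    w2 * u[e[1], ] * u[e[2], ], numeric(K)))
  rho <- matrix(0, length(edges), K)
  for (e in seq_along(edges)) {
    s <- sum(lam[e, ])
    rho[e, ] <- if (s > 0) lam[e, ] / s else rep(1 / K, K)
  }
  num <- matrix(0, N, K)
  for (e in seq_along(edges))
    for (i in edges[[e]]) num[i, ] <- num[i, ] + A[e] * rho[e, ]
  for (i in seq_len(N)) {
    den <- w2 * (colSums(u) - u[i, ])
    for (k in seq_len(K)) {
      u[i, k] <- if (num[i, k] == 0) 0
                 else if (den[k] == 0) u[i, k]
                 else num[i, k] / den[k]
    }
  }
  wNum <- colSums(rho * A)
  wDen <- numeric(K)
  for (k in seq_len(K)) {
    s <- 0
    for (i in seq_len(N - 1)) for (j in (i + 1):N) s <- s + u[i, k] * u[j, k]
    wDen[k] <- s
  }
  w2 <- ifelse(wDen > 0 & wNum > 0, wNum / wDen, 0)
  list(u = u, w2 = w2, rho = rho)
}

# random test instance: hypergraph + compatible latent state
randomInstance <- function(seed, N = 8, D = 3, K = 2, nEdges = 6) {
  set.seed(seed)
  N <- N; D <- D; K <- K   # force promises before drawing edges
  edges <- lapply(seq_len(nEdges), function(e)
    sort(sample.int(N, sample(rep(2:D, 2), 1))))
  h <- Hypergraph(lapply(edges, as.character),
                  weights = sample(1:3, nEdges, replace = TRUE),
                  nodeLabels = as.character(seq_len(N)))
  # relabel ids to match label order ("1".."N")
  u <- matrix(runif(N * K), N, K)
  w <- matrix(runif((D - 1) * K), D - 1, K)
  list(h = h, u = u, w = w,
       state = latentState(u, w))
}

toyHypergraph <- function() {
  Hypergraph(list(c("a", "b", "c"), c("a", "b"), c("b", "c", "d"),
                  c("c", "d")), weights = c(1, 2, 1, 3))
}

makeManyEdges <- function(E = 100, N = 40, seed = 1) {
  set.seed(seed)
  edges <- list()
  keys <- character(0)
  while (length(edges) < E) {
    e <- sort(sample.int(N, sample(2:4, 1)))
    k <- paste(e, collapse = ",")
    if (!(k %in% keys)) { keys <- c(keys, k); edges <- c(edges, list(e)) }
  }
  Hypergraph(lapply(edges, as.character), nodeLabels = as.character(1:N))
}

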