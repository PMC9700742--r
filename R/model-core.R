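#' Construct a latent state
#'
#' @param u `N x K` nonnegative membership matrix.
#' @param w `(D-1) x K` nonnegative affinity matrix; row `d-1` holds the
#'   within-community density of size-`d` hyperedges, for sizes `2..D`. A row
#'   must be present for every size up to `D` even if all-zero.
#' @return A [LatentState-class].
#' @export
latentState <- function(u, w) {
  new("LatentState", u = as.matrix(u), w = as.matrix(w))
}

#' Accessors for latent states and fits
#'
#' `memberships` returns the `N x K` matrix `u`, `affinity` the
#' `(D-1) x K` matrix `w` (rows are hyperedge sizes `2..D`), and
#' `numCommunities` the number of communities `K`.
#'
#' @param x a [LatentState-class] or [HypergraphMTFit-class]
#' @name LatentState-accessors
#' @aliases memberships affinity numCommunities
NULL

#' @rdname LatentState-accessors
#' @export
setMethod("memberships", "LatentState", function(x) x@u)

#' @rdname LatentState-accessors
#' @export
setMethod("affinity", "LatentState", function(x) x@w)

#' @rdname LatentState-accessors
#' @export
setMethod("numCommunities", "LatentState", function(x) ncol(x@u))

setMethod("show", "LatentState", function(object) {
  cat(sprintf("LatentState: N = %d nodes, K = %d communities, sizes 2..%d\n",
              nrow(object@u), ncol(object@u), nrow(object@w) + 1))
})

setMethod("show", "HypergraphMTFit", function(object) {
  callNextMethod()
  cat(sprintf("  log-likelihood %.6g (restart %d of %d, %s)\n",
              object@logLik, object@bestRestart, length(object@traces),
              if (object@converged[object@bestRestart]) "converged"
              else "max iterations reached"))
})

.stateD <- function(state) nrow(state@w) + 1L

.checkStateEdge <- function(state, e) {
  d <- length(e)
  if (d < 2 || d > .stateD(state))
    stop(sprintf("hyperedge size %d outside the model's range 2..%d",
                 d, .stateD(state)))
  if (any(e < 1) || any(e > nrow(state@u))) stop("node id out of range")
}

#' Poisson rate of a potential hyperedge
#'
#' Computes `lambda_e = sum_k w[d-1, k] * prod_{i in e} u[i, k]` for a node
#' set `e` of size `d`. A single zero membership among the members sends the
#' corresponding community's contribution to zero, so hyperedges containing
#' a node with an all-zero row have rate 0.
#'
#' @param state a [LatentState-class]
#' @param e integer vector of distinct 1-based node ids, `2 <= length(e) <= D`.
#' @return nonnegative scalar rate.
#' @export
expectedRate <- function(state, e) {
  e <- as.integer(e)
  .checkStateEdge(state, e)
  as.numeric(.ratesCpp(list(e), length(e), state@u, state@w))
}

#' Elementary-symmetric-polynomial cache over the potential-hyperedge space
#'
#' Sums over the space of all potential hyperedges (all node subsets of size
#' `2..D`) appear in the likelihood penalty term and in the update
#' denominators. They reduce to elementary symmetric polynomials of the
#' membership columns: `C_k(d) = sum_{|S| = d} prod_{j in S} u[j, k]`.
#' This builds the full table `C_k(d)`, `d = 0..D`, by the one-node-at-a-time
#' recurrence in `O(NDK)`, avoiding any subset enumeration. Leave-one-out
#' values follow from the deflation identity
#' `C_k(d) = C_k^{(-i)}(d) + u[i,k] C_k^{(-i)}(d-1)`.
#'
#' @param u membership matrix, or a [LatentState-class] (then `D` defaults
#'   to the state's maximum size).
#' @param D maximum subset size.
#' @return `(D+1) x K` matrix; row `d+1` is degree `d` (row 1 is all ones).
#' @export
buildSymPoly <- function(u, D = NULL) {
  if (is(u, "LatentState")) {
    if (is.null(D)) D <- .stateD(u)
    u <- u@u
  }
  stopifnot(!is.null(D), D >= 1)
  .espCacheCpp(as.matrix(u), as.integer(D))
}

.checkStateHypergraph <- function(state, h) {
  if (nrow(state@u) != numNodes(h))
    stop("state and hypergraph disagree on the number of nodes")
  if (maxEdgeSize(h) > .stateD(state))
    stop("hypergraph contains hyperedges larger than the state's D")
}

#' Log-likelihood of a hypergraph under a latent state
#'
#' The Poisson log-likelihood with the parameter-free factorial term
#' dropped: `L = -sum_{e in Omega} lambda_e + sum_{e observed} A_e log
#' lambda_e`, where `Omega` is every node subset of size `2..D`. The first
#' term is evaluated through the symmetric-polynomial cache as
#' `-sum_{d,k} w[d-1,k] C_k(d)`; the second runs over observed hyperedges
#' only. An observed hyperedge with rate 0 yields `-Inf` (returned, not
#' raised).
#'
#' @param state a [LatentState-class]
#' @param h a [Hypergraph-class]
#' @return scalar log-likelihood (possibly `-Inf`).
#' @export
hyperLogLik <- function(state, h) {
  .checkStateHypergraph(state, h)
  cache <- .espCacheCpp(state@u, .stateD(state))
  pen <- .omegaTermCpp(state@w, cache)
  if (!numHyperedges(h)) return(-pen)
  lam <- .ratesCpp(h@edges, edgeSizes(h), state@u, state@w)
  if (any(lam == 0)) return(-Inf)
  -pen + sum(h@weights * log(lam))
}

#' Variational E-step: hyperedge community responsibilities
#'
#' For each observed hyperedge, `rho[e, k]` is the probability that the
#' hyperedge is explained by community `k`: `rho[e, k] = w[d-1, k] prod u /
#' sum_k' (...)`. Rows whose rate is identically zero cannot be attributed
#' and are set uniform, with the row flagged in the `"degenerate"` attribute.
#'
#' @param state a [LatentState-class]
#' @param h a [Hypergraph-class]
#' @return `E x K` matrix of responsibilities, rows summing to 1, with a
#'   logical `"degenerate"` attribute.
#' @export
eStep <- function(state, h) {
  .checkStateHypergraph(state, h)
  res <- .eStepCpp(h@edges, edgeSizes(h), state@u, state@w)
  structure(res$rho, degenerate = res$degenerate)
}

#' One multiplicative membership update sweep
#'
#' Updates every entry of `u` once, in node order (Gauss-Seidel). The
#' numerator of `u[i, k]` sums `A_e rho[e, k]` over the observed hyperedges
#' incident to `i` (sparse); the denominator sums, over all *potential*
#' incident hyperedges, `w[d-1,k]` times the product of the other members'
#' memberships — evaluated as `sum_d w[d-1,k] C_k^{(-i)}(d-1)` using
#' leave-one-out deflation of the symmetric-polynomial cache, which is then
#' refolded with the freshly written value. A zero numerator zeroes the
#' entry; a zero denominator against a positive numerator leaves the entry
#' unchanged for the sweep and flags the node.
#'
#' @param state a [LatentState-class]
#' @param h a [Hypergraph-class]
#' @param rho responsibilities from [eStep()] at the current state.
#' @param gamma nonnegative rate of the exponential sparsity prior; its MAP
#'   update adds `gamma` to every denominator. 0 disables the prior.
#' @param normalized logical; if `TRUE`, each row is renormalized to sum to
#'   1 after its update (all-zero rows become uniform).
#' @return list with the updated `u`, the refreshed `cache`, and
#'   `illConditioned` node ids.
#' @export
updateU <- function(state, h, rho, gamma = 0, normalized = FALSE) {
  .checkStateHypergraph(state, h)
  .updateUCpp(h@edges, h@weights, edgeSizes(h), state@u, state@w, rho,
              as.numeric(gamma), isTRUE(normalized))
}

#' Affinity matrix update
#'
#' `w[d-1, k] = sum_{observed e of size d} A_e rho[e, k] / C_k(d)`, the
#' denominator being the symmetric-polynomial sum over all potential
#' size-`d` hyperedges. Sizes with no observed hyperedge, and entries with a
#' zero denominator, are set to 0 (which removes those sizes from the
#' likelihood penalty automatically).
#'
#' @param h a [Hypergraph-class]
#' @param rho responsibilities from [eStep()].
#' @param cache symmetric-polynomial cache for the *current* `u`
#'   (see [buildSymPoly()]).
#' @return updated `(D-1) x K` affinity matrix.
#' @export
updateW <- function(h, rho, cache) {
  .updateWCpp(h@weights, edgeSizes(h), rho, cache)
}

#' Variational lower bound on the log-likelihood
#'
#' The EM objective `L(rho, theta) = -sum_{e in Omega} lambda_e +
#' sum_e A_e sum_k rho[e,k] log(w[d-1,k] prod u / rho[e,k])` (with
#' `0 log 0 = 0`). Equals [hyperLogLik()] when `rho` is the E-step optimum;
#' it is non-decreasing along EM iterations.
#'
#' @param state a [LatentState-class]
#' @param h a [Hypergraph-class]
#' @param rho responsibilities.
#' @return scalar bound (possibly `-Inf`).
#' @export
variationalObjective <- function(state, h, rho) {
  .checkStateHypergraph(state, h)
  cache <- .espCacheCpp(state@u, .stateD(state))
  val <- -.omegaTermCpp(state@w, cache)
  sizes <- edgeSizes(h)
  for (e in seq_along(h@edges)) {
    mem <- h@edges[[e]]
    for (k in seq_len(ncol(state@u))) {
      r <- rho[e, k]
      if (r == 0) next
      lamk <- state@w[sizes[e] - 1, k] * prod(state@u[mem, k])
      val <- val + h@weights[e] * r * (log(lamk) - log(r))
    }
  }
  val
}

#' Fit the mixed-membership hypergraph model by EM
#'
#' Runs `nRestarts` independent EM runs from random nonnegative
#' initializations (restart `r` is seeded with `seed + r - 1`), alternating
#' the variational E-step with the multiplicative M-step updates of `u` and
#' `w`, and returns the restart with the highest final log-likelihood.
#' The log-likelihood is recorded every iteration; convergence is declared
#' when its relative change stays below `tol` at two consecutive checks
#' (every `checkEvery` iterations). Affinity rows of sizes never observed in
#' `h` are kept at zero throughout, which excises those sizes from the
#' potential-hyperedge space.
#'
#' Estimation modes: `"ml"` is plain maximum likelihood; `"sparsity"` places
#' an exponential prior of rate `gamma` on the memberships, whose MAP update
#' adds `gamma` to each membership denominator; `"normalized"` constrains
#' each membership row to sum to 1 (renormalized after every sweep).
#'
#' @param h a [Hypergraph-class] with at least one hyperedge.
#' @param K number of communities (>= 1).
#' @param nRestarts independent random restarts (default 10).
#' @param maxIter maximum EM iterations per restart.
#' @param tol relative log-likelihood tolerance.
#' @param checkEvery iterations between convergence checks.
#' @param seed base RNG seed.
#' @param mode `"ml"`, `"sparsity"` or `"normalized"`.
#' @param gamma sparsity-prior rate (used when `mode = "sparsity"`).
#' @param verbose print per-restart summaries.
#' @return A [HypergraphMTFit-class]; a warning is attached to the
#'   `converged` slot when the winner hit `maxIter`.
#' @examples
#' set.seed(1)
#' st <- plantedState(N = 30, K = 2, DMax = 2, wStrength = 0.4)
#' h <- sampleHypergraph(st, seed = 7)
#' fit <- fitHypergraphMT(h, K = 2, nRestarts = 3, seed = 11)
#' fit
#' @export
fitHypergraphMT <- function(h, K, nRestarts = 10, maxIter = 500,
                            tol = 1e-6, checkEvery = 10, seed = 1,
                            mode = c("ml", "sparsity", "normalized"),
                            gamma = 1, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(K >= 1, K == round(K), numHyperedges(h) >= 1, tol > 0,
            nRestarts >= 1, maxIter >= 1, checkEvery >= 1)
  K <- as.integer(K)
  N <- numNodes(h)
  D <- maxEdgeSize(h)
  sizes <- edgeSizes(h)
  observedSizes <- sort(unique(sizes))
  gam <- if (mode == "sparsity") as.numeric(gamma) else 0
  normalized <- mode == "normalized"

  traces <- vector("list", nRestarts)
  finals <- numeric(nRestarts)
  converged <- logical(nRestarts)
  states <- vector("list", nRestarts)
  seeds <- as.integer(seed + seq_len(nRestarts) - 1L)

  for (r in seq_len(nRestarts)) {
    set.seed(seeds[r])
    u <- matrix(runif(N * K), N, K)
    if (normalized) u <- u / rowSums(u)
    w <- matrix(0, D - 1, K)
    w[observedSizes - 1L, ] <- runif(length(observedSizes) * K)

    trace <- numeric(0)
    okStreak <- 0L
    llPrev <- NA_real_
    conv <- FALSE
    for (it in seq_len(maxIter)) {
      es <- .eStepCpp(h@edges, sizes, u, w)
      up <- .updateUCpp(h@edges, h@weights, sizes, u, w, es$rho,
                        gam, normalized)
      u <- up$u
      w <- .updateWCpp(h@weights, sizes, es$rho, up$cache)
      lam <- .ratesCpp(h@edges, sizes, u, w)
      ll <- -.omegaTermCpp(w, up$cache) +
        if (any(lam == 0)) -Inf else sum(h@weights * log(lam))
      trace[it] <- ll
      if (it %% checkEvery == 0) {
        if (is.finite(ll) && is.finite(llPrev)) {
          rel <- abs(ll - llPrev) / (abs(llPrev) + .Machine$double.eps)
          okStreak <- if (rel < tol) okStreak + 1L else 0L
          if (okStreak >= 2L) { conv <- TRUE }
        }
        llPrev <- ll
        if (conv) break
      }
    }
    traces[[r]] <- trace
    finals[r] <- trace[length(trace)]
    converged[r] <- conv
    states[[r]] <- list(u = u, w = w)
    if (verbose)
      message(sprintf("restart %d/%d: logLik %.6g after %d iterations%s",
                      r, nRestarts, finals[r], length(trace),
                      if (conv) " (converged)" else ""))
  }

  best <- which.max(finals)
  if (!converged[best])
    warning("best restart did not converge within maxIter")
  ub <- states[[best]]$u
  wb <- states[[best]]$w
  es <- .eStepCpp(h@edges, sizes, ub, wb)
  rownames(ub) <- nodeLabels(h)
  rownames(wb) <- as.character(2:D)
  new("HypergraphMTFit", u = ub, w = wb,
      logLik = finals[best], traces = traces, bestRestart = as.integer(best),
      seeds = seeds, converged = converged, rho = es$rho,
      degenerate = es$degenerate,
      config = list(K = K, nRestarts = nRestarts, maxIter = maxIter,
                    tol = tol, checkEvery = checkEvery, seed = seed,
                    mode = mode, gamma = gamma))
}
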