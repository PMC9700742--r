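#' Weighted hypergraph
#'
#' An undirected hypergraph on `N` labelled nodes whose hyperedges carry
#' positive integer weights (counts of repeated interactions, e.g. the number
#' of times a group of individuals was in close contact). Hyperedges are
#' stored as sorted vectors of internal 1-based node ids, giving a canonical
#' key; duplicate hyperedges are merged at construction by summing weights.
#'
#' @slot nodeLabels character vector of external node labels, in order of
#'   first appearance; internal id `i` corresponds to `nodeLabels[i]`.
#' @slot edges list of strictly increasing integer vectors (node ids), each
#'   of length at least 2.
#' @slot weights numeric vector of positive integer hyperedge weights, one
#'   per entry of `edges`.
#'
#' @seealso [Hypergraph()] for construction, [readHyperedgeList()] for file
#'   input, [cliqueExpand()], [pairsOnly()], [cCore()].
#' @export
setClass("Hypergraph",
  slots = c(nodeLabels = "character", edges = "list", weights = "numeric"))

setValidity("Hypergraph", function(object) {
  N <- length(object@nodeLabels)
  if (anyDuplicated(object@nodeLabels)) return("duplicated node labels")
  if (length(object@edges) != length(object@weights))
    return("edges and weights lengths differ")
  if (length(object@weights) &&
      (any(object@weights < 1) || any(object@weights != round(object@weights))))
    return("weights must be positive integers")
  keys <- character(length(object@edges))
  for (e in seq_along(object@edges)) {
    ids <- object@edges[[e]]
    if (!is.integer(ids)) return(sprintf("hyperedge %d: ids must be integer", e))
    if (length(ids) < 2) return(sprintf("hyperedge %d has size < 2", e))
    if (any(ids < 1L) || any(ids > N))
      return(sprintf("hyperedge %d: node id out of range", e))
    if (is.unsorted(ids, strictly = TRUE))
      return(sprintf("hyperedge %d: ids must be strictly increasing", e))
    keys[e] <- paste(ids, collapse = ",")
  }
  if (anyDuplicated(keys)) return("duplicate hyperedges (identical node sets)")
  TRUE
})

#' Latent state of the mixed-membership hypergraph model
#'
#' Holds the model parameters: the nonnegative membership matrix `u`
#' (`N x K`, how much node `i` belongs to community `k`) and the assortative
#' affinity matrix `w` (`(D-1) x K`; row `d-1` is hyperedge size `d`, so row
#' 1 is pairs), whose entry `w[d-1, k]` is the density of size-`d` hyperedges
#' inside community `k`. The Poisson rate of a potential hyperedge `e` is
#' `lambda_e = sum_k w[d_e - 1, k] prod_{i in e} u[i, k]`.
#'
#' @slot u numeric matrix, `N x K`, entries >= 0.
#' @slot w numeric matrix, `(D-1) x K`, entries >= 0; rows are sizes `2..D`.
#'
#' @seealso [latentState()], [expectedRate()], [fitHypergraphMT()]
#' @export
setClass("LatentState", slots = c(u = "matrix", w = "matrix"))

setValidity("LatentState", function(object) {
  if (!is.numeric(object@u) || !is.numeric(object@w))
    return("u and w must be numeric matrices")
  if (any(object@u < 0) || any(object@w < 0))
    return("u and w must be nonnegative")
  if (ncol(object@u) != ncol(object@w))
    return("u and w must have the same number of columns (communities)")
  if (nrow(object@w) < 1) return("w needs at least one row (size 2)")
  TRUE
})

#' Fitted mixed-membership hypergraph model
#'
#' Extends [LatentState-class] with the outcome of the EM fit: the
#' per-restart log-likelihood traces, the index and seed of the winning
#' restart, convergence flags and the final variational responsibilities.
#'
#' @slot logLik final log-likelihood of the selected restart.
#' @slot traces list (one numeric vector per restart) of the per-iteration
#'   log-likelihood.
#' @slot bestRestart integer index of the restart with the highest final
#'   log-likelihood.
#' @slot seeds integer vector of per-restart RNG seeds.
#' @slot converged logical vector, one flag per restart.
#' @slot rho numeric matrix `E x K` of responsibilities for the winning
#'   state (rows of observed hyperedges sum to 1 unless degenerate).
#' @slot degenerate logical vector flagging observed hyperedges whose rate
#'   was identically zero at the final E-step.
#' @slot config list of fitting options as used.
#' @export
setClass("HypergraphMTFit", contains = "LatentState",
  slots = c(logLik = "numeric", traces = "list", bestRestart = "integer",
            seeds = "integer", converged = "logical", rho = "matrix",
            degenerate = "logical", config = "list"))
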