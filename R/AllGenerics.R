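#' @rdname Hypergraph-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname Hypergraph-accessors
#' @export
setGeneric("numHyperedges", function(x) standardGeneric("numHyperedges"))

#' @rdname Hypergraph-accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname Hypergraph-accessors
#' @export
setGeneric("hyperedges", function(x) standardGeneric("hyperedges"))

#' @rdname Hypergraph-accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname Hypergraph-accessors
#' @export
setGeneric("edgeSizes", function(x) standardGeneric("edgeSizes"))

#' @rdname Hypergraph-accessors
#' @export
setGeneric("maxEdgeSize", function(x) standardGeneric("maxEdgeSize"))

#' @rdname Hypergraph-accessors
#' @export
setGeneric("totalWeight", function(x) standardGeneric("totalWeight"))

#' @rdname Hypergraph-accessors
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @rdname LatentState-accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname LatentState-accessors
#' @export
setGeneric("affinity", function(x) standardGeneric("affinity"))

#' @rdname LatentState-accessors
#' @export
setGeneric("numCommunities", function(x) standardGeneric("numCommunities"))
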