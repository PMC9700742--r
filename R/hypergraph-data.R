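#' Construct a weighted hypergraph
#'
#' Builds a [Hypergraph-class] from a list of hyperedges. Hyperedges may be
#' given as character vectors of node labels (labels are mapped to internal
#' ids in order of first appearance) or, when `nodeLabels` is supplied, as
#' integer vectors of 1-based node ids. Node sets are canonicalized by
#' sorting; hyperedges with identical node sets are merged by summing their
#' weights, since weights are Poisson counts of repeated interactions.
#'
#' @param edges list of character vectors (node labels) or integer vectors
#'   (node ids if `nodeLabels` is given). Each must contain at least two
#'   distinct nodes.
#' @param weights positive integer weights, recycled scalar allowed;
#'   default 1 per hyperedge.
#' @param nodeLabels optional character vector fixing the node set and its
#'   order. Required when `edges` contain integer ids; when `edges` use
#'   labels it may add isolated nodes.
#' @return A [Hypergraph-class] object.
#' @examples
#' h <- Hypergraph(list(c("a", "b", "c"), c("a", "b")), weights = c(2, 1))
#' numNodes(h); numHyperedges(h); totalWeight(h)
#' @export
Hypergraph <- function(edges, weights = 1, nodeLabels = NULL) {
  stopifnot(is.list(edges))
  weights <- rep_len(as.numeric(weights), length(edges))
  if (is.null(nodeLabels)) {
    if (length(edges) && !all(vapply(edges, is.character, logical(1))))
      stop("edges must be character label vectors when nodeLabels is NULL")
    nodeLabels <- unique(unlist(edges, use.names = FALSE))
  }
  nodeLabels <- as.character(nodeLabels)
  idEdges <- vector("list", length(edges))
  for (e in seq_along(edges)) {
    ed <- edges[[e]]
    ids <- if (is.character(ed)) match(ed, nodeLabels) else as.integer(ed)
    if (anyNA(ids)) stop(sprintf("hyperedge %d: unknown node label", e))
    if (anyDuplicated(ids)) stop(sprintf("hyperedge %d: repeated node", e))
    if (length(ids) < 2) stop(sprintf("hyperedge %d has size < 2", e))
    idEdges[[e]] <- sort(as.integer(ids))
  }
  m <- .mergeDuplicateEdges(idEdges, weights)
  new("Hypergraph", nodeLabels = nodeLabels, edges = m$edges,
      weights = m$weights)
}

# merge hyperedges with identical (sorted) node sets by summing weights;
# keeps first-appearance order
.mergeDuplicateEdges <- function(idEdges, weights) {
  if (!length(idEdges)) return(list(edges = list(), weights = numeric(0)))
  keys <- vapply(idEdges, paste, character(1), collapse = ",")
  first <- !duplicated(keys)
  w <- vapply(split(weights, factor(keys, levels = keys[first])),
              sum, numeric(1))
  list(edges = idEdges[first], weights = unname(w))
}

# subset of hyperedges by index, node set preserved
.keepEdges <- function(h, idx) {
  new("Hypergraph", nodeLabels = h@nodeLabels, edges = h@edges[idx],
      weights = h@weights[idx])
}

# canonical string keys of all observed hyperedges
.edgeKeys <- function(h) {
  vapply(h@edges, paste, character(1), collapse = ",")
}

#' Accessors for Hypergraph objects
#'
#' `numNodes` (N), `numHyperedges` (E, distinct hyperedges),
#' `totalWeight` (M, the summed weights), `maxEdgeSize` (D),
#' `edgeSizes` (d_e per hyperedge), `nodeDegrees` (number of distinct
#' incident hyperedges per node), `hyperedges` (list of 1-based id
#' vectors), `edgeWeights` and `nodeLabels`.
#'
#' @param x a [Hypergraph-class]
#' @return scalar, vector or list as described.
#' @name Hypergraph-accessors
#' @aliases numNodes numHyperedges nodeLabels hyperedges edgeWeights
#'   edgeSizes maxEdgeSize totalWeight nodeDegrees
NULL

#' @rdname Hypergraph-accessors
#' @export
setMethod("numNodes", "Hypergraph", function(x) length(x@nodeLabels))

#' @rdname Hypergraph-accessors
#' @export
setMethod("numHyperedges", "Hypergraph", function(x) length(x@edges))

#' @rdname Hypergraph-accessors
#' @export
setMethod("nodeLabels", "Hypergraph", function(x) x@nodeLabels)

#' @rdname Hypergraph-accessors
#' @export
setMethod("hyperedges", "Hypergraph", function(x) x@edges)

#' @rdname Hypergraph-accessors
#' @export
setMethod("edgeWeights", "Hypergraph", function(x) x@weights)

#' @rdname Hypergraph-accessors
#' @export
setMethod("edgeSizes", "Hypergraph",
          function(x) vapply(x@edges, length, integer(1)))

#' @rdname Hypergraph-accessors
#' @export
setMethod("maxEdgeSize", "Hypergraph",
          function(x) if (length(x@edges)) max(edgeSizes(x)) else 0L)

#' @rdname Hypergraph-accessors
#' @export
setMethod("totalWeight", "Hypergraph", function(x) sum(x@weights))

#' @rdname Hypergraph-accessors
#' @export
setMethod("nodeDegrees", "Hypergraph", function(x) {
  deg <- integer(numNodes(x))
  for (e in x@edges) deg[e] <- deg[e] + 1L
  names(deg) <- x@nodeLabels
  deg
})

setMethod("show", "Hypergraph", function(object) {
  sz <- edgeSizes(object)
  cat(sprintf("Hypergraph: %d nodes, %d hyperedges (total weight %g)\n",
              numNodes(object), numHyperedges(object), totalWeight(object)))
  if (length(sz))
    cat(sprintf("  sizes: %d..%d (mean %.2f), %% pairwise %.1f%%\n",
                min(sz), max(sz), mean(sz), 100 * mean(sz == 2)))
})

#' Read a hyperedge list from a TSV file
#'
#' Each non-comment line is `label1,label2,...<TAB>weight`; the weight column
#' is optional and defaults to 1. Lines beginning with `#` and blank lines
#' are skipped, except that an optional `# nodes: a,b,...` directive (as
#' written by [writeHyperedgeList()]) fixes the node set and its order, so
#' isolated nodes survive a round trip. Duplicate hyperedges (same node set)
#' are merged by summing weights; otherwise node labels are kept in order of
#' first appearance.
#'
#' @param path path to the file.
#' @return A [Hypergraph-class].
#' @seealso [writeHyperedgeList()]
#' @export
readHyperedgeList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  nodeLabels <- NULL
  nodesDir <- grep("^#\\s*nodes:", lines)
  if (length(nodesDir))
    nodeLabels <- trimws(strsplit(sub("^#\\s*nodes:", "", lines[nodesDir[1]]),
                                  ",", fixed = TRUE)[[1]])
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) {
    if (!is.null(nodeLabels))
      return(Hypergraph(list(), numeric(0), nodeLabels = nodeLabels))
    stop("no hyperedge lines in ", path)
  }
  lineNo <- which(keep)
  edges <- vector("list", length(lineNo))
  weights <- numeric(length(lineNo))
  for (j in seq_along(lineNo)) {
    ln <- lineNo[j]
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1 || length(parts) > 2)
      stop(sprintf("line %d: expected 'labels<TAB>weight'", ln))
    labs <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
    labs <- trimws(labs)
    if (length(labs) < 2)
      stop(sprintf("line %d: hyperedge has size %d (< 2)", ln, length(labs)))
    if (anyDuplicated(labs))
      stop(sprintf("line %d: repeated node within hyperedge", ln))
    w <- 1
    if (length(parts) == 2) {
      w <- suppressWarnings(as.numeric(trimws(parts[2])))
      if (is.na(w) || w != round(w) || w < 1)
        stop(sprintf("line %d: weight must be a positive integer", ln))
    }
    edges[[j]] <- labs
    weights[j] <- w
  }
  if (is.null(nodeLabels))
    nodeLabels <- unique(unlist(edges, use.names = FALSE))
  Hypergraph(edges, weights, nodeLabels = nodeLabels)
}

#' Write a hypergraph as a hyperedge-list TSV
#'
#' Inverse of [readHyperedgeList()]: one line per hyperedge, comma-separated
#' node labels then the weight, preceded by a `#` header comment listing the
#' node labels (so isolated nodes survive a round trip).
#'
#' @param h a [Hypergraph-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHyperedgeList <- function(h, path) {
  hdr <- c("# hyperedge list: node_labels<TAB>weight",
           paste0("# nodes: ", paste(h@nodeLabels, collapse = ",")))
  body <- vapply(seq_along(h@edges), function(e) {
    paste0(paste(h@nodeLabels[h@edges[[e]]], collapse = ","), "\t",
           format(h@weights[e], scientific = FALSE))
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a node metadata table
#'
#' TSV with column 1 = node label and column 2 = categorical attribute
#' (e.g. school class, department, political party). Metadata categories are
#' commonly used to fix the number of communities `K` for a fit and to
#' evaluate inferred partitions.
#'
#' @param path path to the TSV.
#' @param h optional [Hypergraph-class]; if given, every labelled node must
#'   exist in `h`.
#' @return named character vector: `names` are node labels, values are
#'   categories.
#' @seealso [f1VsMetadata()], [cosineVsMetadata()], [majorityProfile()]
#' @export
readNodeMetadata <- function(path, h = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    colClasses = "character")
  if (ncol(tab) < 2) stop("metadata needs two columns: label<TAB>category")
  meta <- setNames(trimws(tab[[2]]), trimws(tab[[1]]))
  if (any(meta == "")) stop("empty category string in metadata")
  if (anyDuplicated(names(meta))) stop("duplicated node label in metadata")
  if (!is.null(h)) {
    missing <- setdiff(names(meta), nodeLabels(h))
    if (length(missing))
      stop("metadata labels not in hypergraph: ",
           paste(head(missing, 5), collapse = ", "))
  }
  meta
}

#' Clique expansion of a hypergraph
#'
#' Projects a hypergraph onto a graph: a hyperedge of size `d` is decomposed
#' into its `d(d-1)/2` unordered pairs, each inheriting the hyperedge's full
#' weight; weights of the same pair arising from different hyperedges are
#' summed, preserving total pairwise interaction counts. The node set is
#' preserved (isolated nodes allowed).
#'
#' @param h a [Hypergraph-class]
#' @return A [Hypergraph-class] whose hyperedges all have size 2.
#' @seealso [pairsOnly()]
#' @export
cliqueExpand <- function(h) {
  pairs <- list(); pw <- numeric(0)
  n <- 0L
  for (e in seq_along(h@edges)) {
    ids <- h@edges[[e]]
    if (length(ids) == 2) {
      n <- n + 1L; pairs[[n]] <- ids; pw[n] <- h@weights[e]
    } else {
      cmb <- combn(ids, 2)
      for (j in seq_len(ncol(cmb))) {
        n <- n + 1L; pairs[[n]] <- cmb[, j]; pw[n] <- h@weights[e]
      }
    }
  }
  pairs <- lapply(pairs, as.integer)
  m <- .mergeDuplicateEdges(pairs, pw)
  new("Hypergraph", nodeLabels = h@nodeLabels, edges = m$edges,
      weights = m$weights)
}

#' Pairwise subset of a hypergraph
#'
#' Keeps exactly the size-2 hyperedges (registered pairwise interactions),
#' with unchanged weights; the node set is preserved, so nodes appearing only
#' in larger hyperedges become isolated.
#'
#' @param h a [Hypergraph-class]
#' @return A [Hypergraph-class] with only size-2 hyperedges (possibly none).
#' @export
pairsOnly <- function(h) .keepEdges(h, which(edgeSizes(h) == 2L))

#' c-core of a hypergraph
#'
#' The maximal subhypergraph in which every remaining node is incident to at
#' least `c` hyperedges. Obtained by iterative peeling: nodes of unweighted
#' degree below `c` are removed, affected hyperedges shrink to their
#' surviving nodes (dropping those that fall below size 2; shrunken
#' hyperedges that collapse onto the same node set are merged by summing
#' weights), until stable. The empty hypergraph is a legal result.
#'
#' @param h a [Hypergraph-class]
#' @param c positive integer degree threshold.
#' @return A [Hypergraph-class] on the surviving nodes.
#' @export
cCore <- function(h, c) {
  stopifnot(length(c) == 1, c >= 1, c == round(c))
  alive <- rep(TRUE, numNodes(h))
  edges <- h@edges
  weights <- h@weights
  repeat {
    deg <- integer(numNodes(h))
    for (e in edges) deg[e] <- deg[e] + 1L
    drop <- alive & deg < c
    if (!any(drop)) break
    alive[drop] <- FALSE
    edges <- lapply(edges, function(ids) ids[alive[ids]])
    keep <- lengths(edges) >= 2L
    edges <- edges[keep]
    weights <- weights[keep]
    m <- .mergeDuplicateEdges(edges, weights)
    edges <- m$edges; weights <- m$weights
    if (!length(edges)) { alive[] <- FALSE; break }
  }
  newIds <- cumsum(alive)
  new("Hypergraph", nodeLabels = h@nodeLabels[alive],
      edges = lapply(edges, function(ids) as.integer(newIds[ids])),
      weights = weights)
}

#' Summary statistics of a hypergraph and its clique expansion
#'
#' Bookkeeping in the style of higher-order dataset tables: node and
#' hyperedge counts for the hypergraph (`N`, `E`, `M`) and for its clique
#' expansion (`E_G`, `M_G`), mean/SD of node degree and hyperedge size, the
#' maximum size `D`, the percentage of pairwise hyperedges (`pct_d2`), and
#' `pct_dgt2_in_G`: the percentage of distinct 2-subsets of hyperedges of
#' size > 2 that are already observed as size-2 hyperedges in the data.
#'
#' @param h a [Hypergraph-class]
#' @param g its clique expansion; computed if omitted.
#' @return named list of scalars.
#' @export
hypergraphSummary <- function(h, g = cliqueExpand(h)) {
  sz <- edgeSizes(h)
  deg <- nodeDegrees(h)
  pairKeys <- .edgeKeys(pairsOnly(h))
  bigSubsets <- character(0)
  for (e in h@edges[sz > 2]) {
    cmb <- combn(e, 2)
    bigSubsets <- c(bigSubsets,
                    apply(cmb, 2, paste, collapse = ","))
  }
  bigSubsets <- unique(bigSubsets)
  list(
    N = numNodes(h), E = numHyperedges(h), E_G = numHyperedges(g),
    M = totalWeight(h), M_G = totalWeight(g),
    mean_degree = if (length(deg)) mean(deg) else 0,
    sd_degree = if (length(deg) > 1) sd(deg) else 0,
    mean_size = if (length(sz)) mean(sz) else 0,
    sd_size = if (length(sz) > 1) sd(sz) else 0,
    D = maxEdgeSize(h),
    pct_d2 = if (length(sz)) 100 * mean(sz == 2) else 0,
    pct_dgt2_in_G = if (length(bigSubsets))
      100 * mean(bigSubsets %in% pairKeys) else 0
  )
}

#' Write a summary record as a flat key/value text file
#'
#' @param s result of [hypergraphSummary()]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummary <- function(s, path) {
  writeLines(paste(names(s), vapply(s, format, character(1)), sep = "\t"),
             path)
  invisible(path)
}
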