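#' K-fold split of the observed hyperedges
#'
#' Partitions the distinct hyperedges uniformly at random into `folds`
#' near-equal groups (sizes differ by at most 1); each trial trains on
#' `folds - 1` groups (80% of the hyperedges for the default 5 folds) and
#' tests on the held-out one. Weighted hyperedges count once.
#'
#' @param h a [Hypergraph-class] with at least `folds` hyperedges.
#' @param folds number of folds (default 5).
#' @param seed RNG seed.
#' @return list with `fold` (0-based fold id per hyperedge), `train` and
#'   `test` (lists of hyperedge index vectors, one per fold), and `seed`.
#' @export
kfoldSplit <- function(h, folds = 5, seed = 1) {
  E <- numHyperedges(h)
  if (E < folds) stop("fewer hyperedges than folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(folds) - 1L, length.out = E))
  test <- lapply(seq_len(folds) - 1L, function(f) which(fold == f))
  train <- lapply(seq_len(folds) - 1L, function(f) which(fold != f))
  list(fold = fold, train = train, test = test, seed = seed, folds = folds)
}

# rate that tolerates sizes above the fitted D (no such hyperedge can be
# generated, so the rate is 0); used when scoring held-out hyperedges
.safeRate <- function(state, e) {
  d <- length(e)
  if (d < 2) stop("hyperedge size < 2")
  if (d > .stateD(state)) return(0)
  as.numeric(.ratesCpp(list(as.integer(e)), d, state@u, state@w))
}

#' Existence probability of a hyperedge under the hypergraph model
#'
#' The Poisson positivity probability `P(A_e > 0) = 1 - exp(-lambda_e)`, a
#' strictly increasing function of the rate, used as the prediction score
#' for held-out hyperedges.
#'
#' @param state a [LatentState-class]
#' @param e integer vector of node ids.
#' @return probability in `[0, 1)`.
#' @export
existenceScoreHyper <- function(state, e) {
  1 - exp(-expectedRate(state, as.integer(e)))
}

#' Existence probability of a hyperedge under a pairwise (graph) model
#'
#' For a model fitted on a projected graph (`D = 2`), the probability that
#' a hyperedge exists is the product over its 2-combination set of the
#' probabilities that each pair exists:
#' `P(A_e) = prod_{(ij) in e2} (1 - exp(-lambda_ij))` — all the pairwise
#' interactions have to exist for the hyperedge to.
#'
#' @param state a [LatentState-class] fitted on a graph.
#' @param e integer vector of node ids (any size >= 2).
#' @return probability in `[0, 1)`.
#' @export
existenceScoreGraph <- function(state, e) {
  e <- as.integer(e)
  if (length(e) < 2) stop("hyperedge size < 2")
  if (length(e) == 2)
    return(1 - exp(-.safeRate(state, e)))
  cmb <- combn(e, 2)
  p <- 1
  for (j in seq_len(ncol(cmb)))
    p <- p * (1 - exp(-.safeRate(state, cmb[, j])))
  p
}

#' Sample balanced positive/negative score sets for AUC
#'
#' Draws `nComparisons` positives uniformly with replacement from the test
#' hyperedges and, for each positive of size `d`, one negative: a uniform
#' random `d`-subset of nodes that is not observed anywhere in the dataset
#' (rejection sampling), so the negative set matches the positives' size
#' distribution exactly. Both sets are scored with the same scorer.
#'
#' @param testEdges list of node-id vectors (the held-out hyperedges).
#' @param h the full [Hypergraph-class] (every observed hyperedge, train or
#'   test, is excluded from the negatives).
#' @param scorer function taking a node-id vector and returning a score.
#' @param nComparisons number of paired comparisons (default `10^3`).
#' @param seed RNG seed.
#' @param maxTries rejection budget per negative draw.
#' @return list with numeric vectors `R1` (positives) and `R0` (negatives)
#'   of equal length, and `sizes` of the sampled positives.
#' @export
sampleScoreSets <- function(testEdges, h, scorer, nComparisons = 1000,
                            seed = 1, maxTries = 1000) {
  if (!length(testEdges)) stop("empty test set")
  set.seed(seed)
  N <- numNodes(h)
  observed <- .edgeKeys(h)
  pos <- sample.int(length(testEdges), nComparisons, replace = TRUE)
  sizes <- vapply(testEdges, length, integer(1))[pos]
  R1 <- vapply(testEdges[pos], scorer, numeric(1))
  R0 <- numeric(nComparisons)
  for (j in seq_len(nComparisons)) {
    d <- sizes[j]
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      cand <- sort(sample.int(N, d))
      if (!(paste(cand, collapse = ",") %in% observed)) {
        R0[j] <- scorer(cand); ok <- TRUE; break
      }
    }
    if (!ok)
      stop(sprintf(paste0("could not sample an unobserved size-%d subset ",
                          "within %d tries (hypergraph too dense)"),
                   d, maxTries))
  }
  list(R1 = R1, R0 = R0, sizes = sizes, seed = seed)
}

#' Sampled AUC from paired comparisons
#'
#' `AUC = (#(R1 > R0) + 0.5 #(R1 == R0)) / |R1|`: the estimated probability
#' that a random true positive is scored above a random true negative, from
#' element-wise comparisons of equally long score vectors. 1 is perfect
#' ranking, 0.5 is chance.
#'
#' @param R1 scores of sampled positives, or a list with components
#'   `R1`/`R0` (as returned by [sampleScoreSets()]).
#' @param R0 scores of sampled negatives.
#' @return scalar in `[0, 1]`.
#' @export
aucScores <- function(R1, R0 = NULL) {
  if (is.list(R1)) { R0 <- R1$R0; R1 <- R1$R1 }
  if (length(R1) != length(R0) || !length(R1))
    stop("R1 and R0 must be non-empty and of equal length")
  (sum(R1 > R0) + 0.5 * sum(R1 == R0)) / length(R1)
}

# contingency table of hard assignments (rows = inferred communities,
# columns = categories in sorted order)
.contingency <- function(hard, cats, K, categories) {
  tab <- matrix(0, K, length(categories),
                dimnames = list(NULL, categories))
  for (i in seq_along(hard))
    tab[hard[i], cats[i]] <- tab[hard[i], cats[i]] + 1
  tab
}

# maximum-weight matching of communities to categories on a square score
# table: exhaustive over permutations for K <= 8, greedy beyond.
# Returns perm with perm[k] = category index assigned to community k.
.matchCommunities <- function(tab) {
  K <- nrow(tab)
  if (K <= 8) {
    perms <- .permutations(K)
    scores <- vapply(seq_len(nrow(perms)), function(p)
      sum(tab[cbind(seq_len(K), perms[p, ])]), numeric(1))
    perms[which.max(scores), ]
  } else {
    perm <- integer(K)
    free <- rep(TRUE, K)
    for (k in order(-apply(tab, 1, max))) {
      j <- which.max(ifelse(free, tab[k, ], -Inf))
      perm[k] <- j; free[j] <- FALSE
    }
    perm
  }
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(j)
    cbind(j, sub + (sub >= j))))
}

.metaPrep <- function(u, meta, nodeLabels = rownames(u)) {
  if (is.null(nodeLabels))
    stop("u must have row names (node labels) or nodeLabels must be given")
  if (!all(nodeLabels %in% names(meta)))
    stop("metadata missing for some nodes")
  cats <- meta[nodeLabels]
  categories <- sort(unique(unname(meta)))
  if (ncol(u) != length(categories))
    stop(sprintf("K = %d does not match the %d metadata categories",
                 ncol(u), length(categories)))
  catIdx <- match(cats, categories)
  list(catIdx = catIdx, categories = categories)
}

#' F1-score of inferred communities against node metadata
#'
#' Hard-membership classification accuracy: nodes are hard-assigned by the
#' row-argmax of `u` (argmax ties broken toward the lowest community index),
#' communities are matched to metadata categories by maximum-weight
#' bipartite matching on the contingency table (so the score is invariant
#' to community relabelling), and the micro-averaged F1 of the matched
#' labelling is returned. Ranges in `[0, 1]`, 1 = perfect agreement.
#'
#' @param u `N x K` membership matrix with node labels as row names (a
#'   [HypergraphMTFit-class] is accepted).
#' @param meta named character vector of node categories
#'   (see [readNodeMetadata()]); the number of distinct categories must
#'   equal `K`.
#' @param nodeLabels optional labels overriding `rownames(u)`.
#' @return scalar F1 in `[0, 1]`.
#' @export
f1VsMetadata <- function(u, meta, nodeLabels = NULL) {
  if (is(u, "LatentState")) u <- memberships(u)
  if (is.null(nodeLabels)) nodeLabels <- rownames(u)
  mp <- .metaPrep(u, meta, nodeLabels)
  hard <- max.col(u, ties.method = "first")
  tab <- .contingency(hard, mp$categories[mp$catIdx], ncol(u),
                      mp$categories)
  perm <- .matchCommunities(tab)
  # single-label multiclass: micro-F1 equals the matched accuracy
  sum(tab[cbind(seq_len(ncol(u)), perm)]) / nrow(u)
}

#' Cosine similarity of mixed memberships against node metadata
#'
#' A soft-membership counterpart of [f1VsMetadata()]: after matching
#' communities to categories (same maximum-weight protocol), each node's
#' membership row is compared with the one-hot vector of its category by
#' cosine similarity. Nodes with an all-zero membership row get 0.
#'
#' @inheritParams f1VsMetadata
#' @return list with `perNode` (named numeric vector) and `mean`.
#' @export
cosineVsMetadata <- function(u, meta, nodeLabels = NULL) {
  if (is(u, "LatentState")) u <- memberships(u)
  if (is.null(nodeLabels)) nodeLabels <- rownames(u)
  mp <- .metaPrep(u, meta, nodeLabels)
  hard <- max.col(u, ties.method = "first")
  tab <- .contingency(hard, mp$categories[mp$catIdx], ncol(u),
                      mp$categories)
  perm <- .matchCommunities(tab)
  # reorder columns so column j corresponds to category j
  uPerm <- u[, order(perm), drop = FALSE]
  nrm <- sqrt(rowSums(uPerm^2))
  cs <- ifelse(nrm > 0,
               uPerm[cbind(seq_len(nrow(u)), mp$catIdx)] / nrm, 0)
  names(cs) <- nodeLabels
  list(perNode = cs, mean = mean(cs))
}

#' Hyperedge-majority profile of each node
#'
#' Labels every hyperedge by the strict-majority category of its members
#' (or `"tie"` when the top count is shared), then reports, for each node,
#' the fraction of its incident hyperedges carrying each label. This
#' summarizes whether a node's interactions align with its own attribute —
#' e.g. whether a judge mostly votes alongside members of the other party.
#'
#' @param h a [Hypergraph-class]
#' @param meta named character vector covering every node of `h`.
#' @return `N x (C+1)` matrix of fractions, columns the sorted categories
#'   plus `"tie"`, rows named by node label; rows of isolated nodes are 0.
#' @export
majorityProfile <- function(h, meta) {
  labs <- nodeLabels(h)
  if (!all(labs %in% names(meta))) stop("metadata missing for some nodes")
  categories <- sort(unique(unname(meta)))
  catIdx <- match(meta[labs], categories)
  C <- length(categories)
  edgeLab <- vapply(h@edges, function(e) {
    cnt <- tabulate(catIdx[e], nbins = C)
    top <- max(cnt)
    if (sum(cnt == top) > 1) C + 1L else which.max(cnt)
  }, integer(1))
  prof <- matrix(0, numNodes(h), C + 1,
                 dimnames = list(labs, c(categories, "tie")))
  deg <- integer(numNodes(h))
  for (e in seq_along(h@edges)) {
    ids <- h@edges[[e]]
    deg[ids] <- deg[ids] + 1L
    prof[ids, edgeLab[e]] <- prof[ids, edgeLab[e]] + 1
  }
  pos <- deg > 0
  prof[pos, ] <- prof[pos, , drop = FALSE] / deg[pos]
  prof
}

#' Cross-validated hyperedge prediction
#'
#' The full prediction protocol: the observed hyperedges are split into
#' `folds` groups; for each trial the model is trained on the remaining
#' groups and the held-out hyperedges are scored against size-matched
#' unobserved negatives, giving a sampled AUC per fold. Three structures
#' can be evaluated on the same folds: the hypergraph itself
#' (`"hypergraph"`), the clique expansion of the training hyperedges
#' (`"graph"`, scored by the pairwise product rule), and the pairs-only
#' training subgraph (`"pairs"`, evaluated on held-out pairs). For the
#' first two, the AUC restricted to held-out pairs is also reported
#' (`*_pairs`), which measures how much large hyperedges help predict
#' pairwise interactions.
#'
#' @param h a [Hypergraph-class]
#' @param K number of communities.
#' @param folds number of CV folds (default 5).
#' @param seed base seed for the split, fits and score sampling.
#' @param methods subset of `c("hypergraph", "graph", "pairs")`.
#' @param nComparisons paired comparisons per AUC (default `10^3`).
#' @param nRestarts,maxIter,tol passed to [fitHypergraphMT()].
#' @return list with `perFold` (data.frame of AUCs by fold and method),
#'   `mean` and `sd` per method, and the `plan` from [kfoldSplit()].
#' @export
crossValidate <- function(h, K, folds = 5, seed = 1,
                          methods = c("hypergraph", "graph", "pairs"),
                          nComparisons = 1000, nRestarts = 3,
                          maxIter = 200, tol = 1e-6) {
  methods <- match.arg(methods, several.ok = TRUE)
  plan <- kfoldSplit(h, folds, seed)
  cols <- c(if ("hypergraph" %in% methods) c("hypergraph", "hypergraph_pairs"),
            if ("graph" %in% methods) c("graph", "graph_pairs"),
            if ("pairs" %in% methods) "pairs")
  res <- matrix(NA_real_, folds, length(cols),
                dimnames = list(NULL, cols))
  for (f in seq_len(folds)) {
    hTrain <- .keepEdges(h, plan$train[[f]])
    testEdges <- h@edges[plan$test[[f]]]
    testPairs <- testEdges[lengths(testEdges) == 2L]
    foldSeed <- seed + 1000 * f
    if ("hypergraph" %in% methods) {
      fitH <- fitHypergraphMT(hTrain, K, nRestarts = nRestarts,
                              maxIter = maxIter, tol = tol, seed = foldSeed)
      scH <- function(e) 1 - exp(-.safeRate(fitH, e))
      res[f, "hypergraph"] <- aucScores(
        sampleScoreSets(testEdges, h, scH, nComparisons, seed = foldSeed))
      if (length(testPairs))
        res[f, "hypergraph_pairs"] <- aucScores(
          sampleScoreSets(testPairs, h, scH, nComparisons,
                          seed = foldSeed + 1))
    }
    if ("graph" %in% methods) {
      fitG <- fitHypergraphMT(cliqueExpand(hTrain), K, nRestarts = nRestarts,
                              maxIter = maxIter, tol = tol,
                              seed = foldSeed + 2)
      scG <- function(e) existenceScoreGraph(fitG, e)
      res[f, "graph"] <- aucScores(
        sampleScoreSets(testEdges, h, scG, nComparisons,
                        seed = foldSeed + 3))
      if (length(testPairs))
        res[f, "graph_pairs"] <- aucScores(
          sampleScoreSets(testPairs, h, scG, nComparisons,
                          seed = foldSeed + 4))
    }
    if ("pairs" %in% methods) {
      hp <- pairsOnly(hTrain)
      if (numHyperedges(hp) && length(testPairs)) {
        fitP <- fitHypergraphMT(hp, K, nRestarts = nRestarts,
                                maxIter = maxIter, tol = tol,
                                seed = foldSeed + 5)
        scP <- function(e) 1 - exp(-.safeRate(fitP, e))
        res[f, "pairs"] <- aucScores(
          sampleScoreSets(testPairs, h, scP, nComparisons,
                          seed = foldSeed + 6))
      }
    }
  }
  perFold <- data.frame(fold = seq_len(folds) - 1L, res,
                        check.names = FALSE)
  list(perFold = perFold,
       mean = colMeans(res, na.rm = TRUE),
       sd = apply(res, 2, sd, na.rm = TRUE),
       plan = plan)
}
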