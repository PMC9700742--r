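#' @name workflows
#' @title Canned command-style workflows
#'
#' @description
#' Reproducible end-to-end runs tying the package together: each workflow
#' reads its inputs, executes the corresponding analysis, and writes plain
#' artifacts (CSV/TSV/JSON) into an output directory. Every artifact records
#' the global seed and an MD5 hash of the configuration, and all randomness
#' flows from that one seed, so re-running a workflow from its recorded
#' configuration reproduces the artifacts bit for bit. A thin command-line
#' dispatcher over these functions ships in `inst/cli/hypergraph-mt.R`
#' (subcommands `fit`, `sample`, `cv`, `summarize`).
#'
#' @param input path to a hyperedge-list TSV (see [readHyperedgeList()]).
#' @param outDir output directory (created if missing).
#' @param K number of communities.
#' @param seed global seed.
#' @param verbose print progress (per-restart log-likelihoods, per-sweep
#'   timing) via `message()`.
NULL

.configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(cfg, file = f)
  unname(tools::md5sum(f))
}

.writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname workflows
#' @param ... passed to [fitHypergraphMT()] (e.g. `nRestarts`, `mode`).
#' @return `runFit`: invisibly, a list with the fit and the artifact paths
#'   (`u.csv`, `w.csv`, `report.json`).
#' @export
runFit <- function(input, K, outDir, seed = 1, verbose = FALSE, ...) {
  if (K < 1) stop("K must be a positive integer")
  h <- readHyperedgeList(input)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  fit <- fitHypergraphMT(h, K, seed = seed, verbose = verbose, ...)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (verbose)
    message(sprintf("fit: %.2fs total, %.4fs per EM sweep", elapsed,
                    elapsed / max(1, sum(lengths(fit@traces)))))
  uPath <- file.path(outDir, "u.csv")
  wPath <- file.path(outDir, "w.csv")
  write.csv(data.frame(node = rownames(fit@u), fit@u, check.names = FALSE,
                       row.names = NULL), uPath, row.names = FALSE)
  write.csv(data.frame(size = 2:(nrow(fit@w) + 1), fit@w,
                       check.names = FALSE, row.names = NULL),
            wPath, row.names = FALSE)
  cfg <- c(list(command = "fit", input = input, K = K, seed = seed),
           fit@config)
  report <- list(
    config = cfg, config_md5 = .configHash(cfg), seed = seed,
    restart_seeds = fit@seeds,
    final_loglik = vapply(fit@traces, function(t) t[length(t)], numeric(1)),
    best_restart = fit@bestRestart, loglik = fit@logLik,
    converged = fit@converged,
    iterations = vapply(fit@traces, length, integer(1)),
    degenerate_hyperedges = sum(fit@degenerate))
  .writeReport(report, file.path(outDir, "report.json"))
  invisible(list(fit = fit, u = uPath, w = wPath,
                 report = file.path(outDir, "report.json")))
}

#' @rdname workflows
#' @param config for `runSample`: either a YAML file path or a named list
#'   with fields `N`, `K`, `DMax`, `overlap`, `wStrength`, `seed`
#'   (see [plantedState()]).
#' @return `runSample`: invisibly, paths of `hyperedges.tsv`, `u_true.csv`,
#'   `w_true.csv` and `report.json`.
#' @export
runSample <- function(config, outDir, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$N), !is.null(config$K))
  cfg <- modifyList(list(DMax = 2, overlap = 0, wStrength = 0.1, seed = 1),
                    config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  st <- plantedState(cfg$N, cfg$K, cfg$DMax, cfg$overlap, cfg$wStrength,
                     seed = cfg$seed)
  h <- sampleHypergraph(st, seed = cfg$seed)
  if (verbose)
    message(sprintf("sampled %d hyperedges on %d nodes",
                    numHyperedges(h), numNodes(h)))
  tsv <- file.path(outDir, "hyperedges.tsv")
  writeHyperedgeList(h, tsv)
  uPath <- file.path(outDir, "u_true.csv")
  write.csv(data.frame(node = nodeLabels(h), st@u, check.names = FALSE,
                       row.names = NULL), uPath, row.names = FALSE)
  wPath <- file.path(outDir, "w_true.csv")
  write.csv(data.frame(size = 2:(nrow(st@w) + 1), st@w,
                       check.names = FALSE, row.names = NULL),
            wPath, row.names = FALSE)
  report <- list(config = cfg, config_md5 = .configHash(cfg),
                 seed = cfg$seed, N = numNodes(h), E = numHyperedges(h),
                 M = totalWeight(h))
  .writeReport(report, file.path(outDir, "report.json"))
  invisible(list(hyperedges = tsv, u = uPath, w = wPath,
                 report = file.path(outDir, "report.json")))
}

#' @rdname workflows
#' @param folds,methods,nComparisons,nRestarts see [crossValidate()].
#' @return `runCV`: invisibly, the [crossValidate()] result plus the path
#'   of `cv_report.json` (per-fold and aggregate AUCs).
#' @export
runCV <- function(input, K, outDir, folds = 5, seed = 1,
                  methods = c("hypergraph", "graph", "pairs"),
                  nComparisons = 1000, nRestarts = 3, verbose = FALSE) {
  h <- readHyperedgeList(input)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cv <- crossValidate(h, K, folds = folds, seed = seed, methods = methods,
                      nComparisons = nComparisons, nRestarts = nRestarts)
  if (verbose)
    message(paste(sprintf("%s: AUC %.3f +/- %.3f", names(cv$mean),
                          cv$mean, cv$sd), collapse = "\n"))
  cfg <- list(command = "cv", input = input, K = K, folds = folds,
              seed = seed, methods = methods, nComparisons = nComparisons,
              nRestarts = nRestarts)
  report <- list(config = cfg, config_md5 = .configHash(cfg), seed = seed,
                 fold_of_hyperedge = cv$plan$fold,
                 per_fold = cv$perFold, auc_mean = as.list(cv$mean),
                 auc_sd = as.list(cv$sd))
  path <- file.path(outDir, "cv_report.json")
  .writeReport(report, path)
  invisible(c(cv, list(report = path)))
}

#' @rdname workflows
#' @return `runSummarize`: invisibly, the summary list; written as a flat
#'   key/value `summary.tsv`.
#' @export
runSummarize <- function(input, outDir, verbose = FALSE) {
  h <- readHyperedgeList(input)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  s <- hypergraphSummary(h)
  writeSummary(s, file.path(outDir, "summary.tsv"))
  if (verbose)
    message(sprintf("N=%d E=%d M=%g D=%d", s$N, s$E, s$M, s$D))
  invisible(s)
}

#' @importFrom utils modifyList write.csv
NULL
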