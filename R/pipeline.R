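#' Assemble and validate a run configuration
#'
#' A plain validated list capturing every knob of the two-part workflow;
#' [writeRunConfig()]/[readRunConfig()] round-trip it losslessly through
#' YAML. The CLI layers flag parsing on top of this (precedence: flags >
#' config file > defaults).
#'
#' @param input path to the expression CSV (may be `NULL` for analyze-only
#'   runs).
#' @param outputDir where outputs land; defaults to the input's directory.
#' @param removeZeros,log2,zscore preprocessing flags, applied in this
#'   order.
#' @param missingTokens tokens read as missing, see [loadExpression()].
#' @param minPairs validity floor for correlations, see [pairwisePCC()].
#' @param binSize,cutoff,minBinCount binning settings, see
#'   [binQuantiles()].
#' @param absolute threshold `|pcc|` instead of signed pcc.
#' @param weighted carry correlations as edge weights.
#' @param largestComponent analyze only the largest connected component.
#' @param method,resolution,seed community detection settings.
#' @param closeness `"harmonic"` or `"classic"`.
#' @return A validated list of class `"slidenet_config"`.
#' @export
runConfig <- function(input = NULL, outputDir = NULL,
                      removeZeros = FALSE, log2 = FALSE, zscore = FALSE,
                      missingTokens = DEFAULT_MISSING_TOKENS,
                      minPairs = 3L, binSize = 10L, cutoff = 0.005,
                      minBinCount = 50L, absolute = FALSE, weighted = FALSE,
                      largestComponent = FALSE, method = "louvain",
                      resolution = 1, seed = 42L, closeness = "harmonic") {
  if (cutoff <= 0 || cutoff >= 1) abortUsage("cutoff must lie in (0, 1)")
  if (binSize < 1) abortUsage("binSize must be >= 1")
  if (minPairs < 1) abortUsage("minPairs must be >= 1")
  if (minBinCount < 1) abortUsage("minBinCount must be >= 1")
  if (!method %in% c("louvain", "leiden"))
    abortUsage("method must be 'louvain' or 'leiden'")
  if (!closeness %in% c("harmonic", "classic"))
    abortUsage("closeness must be 'harmonic' or 'classic'")
  cfg <- list(input = input, outputDir = outputDir,
              removeZeros = isTRUE(removeZeros), log2 = isTRUE(log2),
              zscore = isTRUE(zscore),
              missingTokens = as.character(missingTokens),
              minPairs = as.integer(minPairs), binSize = as.integer(binSize),
              cutoff = as.numeric(cutoff),
              minBinCount = as.integer(minBinCount),
              absolute = isTRUE(absolute), weighted = isTRUE(weighted),
              largestComponent = isTRUE(largestComponent), method = method,
              resolution = as.numeric(resolution), seed = as.integer(seed),
              closeness = closeness)
  structure(cfg, class = "slidenet_config")
}

#' @rdname runConfig
#' @param config a `slidenet_config` object.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) abortData("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abortUsage("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

resolveOutputDir <- function(config, fallback) {
  dir <- config$outputDir
  if (is.null(dir)) dir <- dirname(fallback)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Construct the network: expression CSV to edge list
#'
#' Runs the whole construction half — load, optional transforms,
#' pairwise-complete correlation, binned quantiles, sliding-threshold fit,
#' edge selection — and writes `edge_list.csv`, `threshold_curve.csv`,
#' `threshold_params.txt` and a machine-readable `build_report.json` next
#' to the input (or in `outputDir`).
#'
#' @param config a [runConfig()] object with `input` set.
#' @return Invisibly, a summary list: node and edge counts, fitted
#'   parameters, R-squared, the retained-bin table and output paths.
#' @export
runBuild <- function(config) {
  if (is.null(config$input)) abortUsage("config$input is required for build")
  outDir <- resolveOutputDir(config, config$input)

  stageMessage("preprocess", "loading ", config$input)
  expr <- loadExpression(config$input, missingTokens = config$missingTokens)
  expr <- applyTransforms(expr, removeZeros = config$removeZeros,
                          log2 = config$log2, zscore = config$zscore)

  stageMessage("correlation", "pairwise-complete PCC over ",
               nrow(expr), " genes")
  stats <- pairwisePCC(expr, minPairs = config$minPairs)

  stageMessage("threshold", sprintf("binning (size %d) at cutoff %g",
                                    config$binSize, config$cutoff))
  bins <- binQuantiles(stats, binSize = config$binSize,
                       cutoff = config$cutoff,
                       minBinCount = config$minBinCount)
  model <- fitThresholdCurve(bins)
  stageMessage("threshold", sprintf("fit R^2 = %.4f", rSquared(model)))
  edges <- selectEdges(stats, model, weighted = config$weighted,
                       absolute = config$absolute)

  edgePath <- file.path(outDir, "edge_list.csv")
  writeEdgeList(edges, edgePath)
  writeThresholdReport(model, file.path(outDir, "threshold_curve.csv"),
                       file.path(outDir, "threshold_params.txt"))

  summary <- list(
    nodes = length(unique(c(edges$Source, edges$Target))),
    edges = nrow(edges),
    parameters = as.list(thresholdParams(model)),
    r_squared = rSquared(model),
    bins = binTable(bins),
    outputs = list(edge_list = edgePath,
                   threshold_curve = file.path(outDir, "threshold_curve.csv"),
                   threshold_params = file.path(outDir, "threshold_params.txt")))
  jsonlite::write_json(summary[c("nodes", "edges", "parameters", "r_squared")],
                       file.path(outDir, "build_report.json"),
                       auto_unbox = TRUE, digits = NA)
  stageMessage("build", summary$nodes, " nodes, ", summary$edges, " edges")
  invisible(summary)
}

#' Analyze a network: edge list to node-property table
#'
#' The analysis half is independent of the construction half: any edge list
#' in the `Source,Target[,Weight]` dialect is accepted. Writes
#' `node_table.csv`, the three distribution summaries and
#' `analysis_report.json`.
#'
#' @param edgeListPath path to an edge-list CSV.
#' @param config a [runConfig()] object (analysis settings are used).
#' @return Invisibly, a summary list with node, edge and core-node counts,
#'   modularity and output paths.
#' @export
runAnalyze <- function(edgeListPath, config = runConfig()) {
  outDir <- resolveOutputDir(config, edgeListPath)
  stageMessage("network", "reading ", edgeListPath)
  edges <- readEdgeList(edgeListPath)
  g <- buildGraph(edges, useWeights = config$weighted,
                  largestComponentOnly = config$largestComponent)
  props <- nodePropertyTable(g, method = config$method,
                             resolution = config$resolution,
                             seed = config$seed,
                             closenessVariant = config$closeness)
  tablePath <- file.path(outDir, "node_table.csv")
  write.csv(props$table, tablePath, row.names = FALSE, quote = FALSE)
  for (nm in names(props$summaries))
    write.csv(props$summaries[[nm]],
              file.path(outDir, sprintf("%s_distribution.csv", nm)),
              row.names = FALSE)

  coreCount <- sum(props$table$IsCore)
  summary <- list(nodes = as.integer(igraph::vcount(g)),
                  edges = as.integer(igraph::ecount(g)),
                  core_nodes = as.integer(coreCount),
                  modularity = props$modularity,
                  communities = nrow(props$summaries$communities),
                  outputs = c(node_table = tablePath))
  jsonlite::write_json(summary[c("nodes", "edges", "core_nodes",
                                 "modularity", "communities")],
                       file.path(outDir, "analysis_report.json"),
                       auto_unbox = TRUE, digits = NA)
  stageMessage("analyze", summary$nodes, " nodes, ", summary$edges,
               " edges, ", coreCount, " core nodes")
  invisible(summary)
}

#' Sweep cutoff values and report network size
#'
#' Re-runs binning, fitting and edge selection for each cutoff on a single
#' correlation computation, reporting node and edge counts so the user can
#' pick the cutoff that keeps most nodes connected with fewest edges.
#'
#' @param config a [runConfig()] object with `input` set.
#' @param cutoffs numeric vector of cutoff values to try.
#' @return A data.frame with columns `cutoff`, `nodes`, `edges`,
#'   `r_squared` (also written to `cutoff_sweep.csv`).
#' @export
runSweep <- function(config, cutoffs = c(0.005, 0.01, 0.02)) {
  if (is.null(config$input)) abortUsage("config$input is required for sweep")
  outDir <- resolveOutputDir(config, config$input)
  expr <- loadExpression(config$input, missingTokens = config$missingTokens)
  expr <- applyTransforms(expr, removeZeros = config$removeZeros,
                          log2 = config$log2, zscore = config$zscore)
  stats <- pairwisePCC(expr, minPairs = config$minPairs)
  rows <- lapply(cutoffs, function(p) {
    bins <- binQuantiles(stats, binSize = config$binSize, cutoff = p,
                         minBinCount = config$minBinCount)
    model <- fitThresholdCurve(bins)
    edges <- selectEdges(stats, model, weighted = config$weighted,
                         absolute = config$absolute)
    data.frame(cutoff = p,
               nodes = length(unique(c(edges$Source, edges$Target))),
               edges = nrow(edges), r_squared = rSquared(model))
  })
  out <- do.call(rbind, rows)
  write.csv(out, file.path(outDir, "cutoff_sweep.csv"), row.names = FALSE)
  out
}

#' Simulate an expression matrix to disk
#'
#' Writes `expression.csv` (loadable by [loadExpression()]) and
#' `module_labels.csv` with the planted ground truth.
#'
#' @param outDir output directory.
#' @inheritParams generateBlockExpression
#' @return Invisibly, a list with the two paths and the simulation.
#' @export
runSimulate <- function(outDir, nGenes = 100L, nConditions = 200L,
                        nModules = 4L, withinCorr = 0.8, noiseSd = 1,
                        missingRate = 0, seed = 42L) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  sim <- generateBlockExpression(nGenes = nGenes, nConditions = nConditions,
                                 nModules = nModules,
                                 withinCorr = withinCorr, noiseSd = noiseSd,
                                 missingRate = missingRate, seed = seed)
  matPath <- file.path(outDir, "expression.csv")
  labPath <- file.path(outDir, "module_labels.csv")
  writeExpression(sim$expr, matPath)
  write.csv(data.frame(Id = names(sim$modules), Module = sim$modules),
            labPath, row.names = FALSE, quote = FALSE)
  stageMessage("simulate", nGenes, " genes x ", nConditions,
               " conditions -> ", matPath)
  invisible(list(expression = matPath, labels = labPath, sim = sim))
}
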