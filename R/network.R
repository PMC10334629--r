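#' Build an undirected co-expression graph from an edge list
#'
#' Self-loops are dropped and duplicate edges collapsed to their first
#' occurrence, each with a warning. When `useWeights` is set the `Weight`
#' column is attached as edge weights (all weights must be finite and
#' positive — weighted shortest-path lengths use 1/weight, so high
#' co-expression means short distance). With `largestComponentOnly` the
#' graph is restricted to its largest connected component; among
#' equally-sized components the one containing the lexicographically
#' smallest node id wins.
#'
#' @param edges edge-list data.frame (`Source`, `Target`, optional
#'   `Weight`).
#' @param useWeights use the `Weight` column as edge weights.
#' @param largestComponentOnly restrict to the largest connected component.
#' @return An [igraph::igraph] object with graph attributes `weighted` and
#'   `largest_component`.
#' @export
buildGraph <- function(edges, useWeights = FALSE, largestComponentOnly = FALSE) {
  if (!all(c("Source", "Target") %in% names(edges)))
    abortData("edge list needs 'Source' and 'Target' columns")
  if (useWeights && !"Weight" %in% names(edges))
    abortData("useWeights requires a 'Weight' column")

  loops <- edges$Source == edges$Target
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- ifelse(edges$Source < edges$Target,
                paste(edges$Source, edges$Target, sep = "\r"),
                paste(edges$Target, edges$Source, sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) dropped (first kept)", call. = FALSE)
    edges <- edges[!dup, , drop = FALSE]
  }

  g <- igraph::graph_from_data_frame(edges[c("Source", "Target")],
                                     directed = FALSE)
  if (useWeights) {
    w <- edges$Weight
    if (any(!is.finite(w)) || any(w <= 0))
      abortData("weighted graphs require finite positive weights")
    igraph::E(g)$weight <- w
  }
  g <- igraph::set_graph_attr(g, "weighted", useWeights)
  if (largestComponentOnly && igraph::vcount(g) > 0L) {
    comp <- igraph::components(g)
    big <- which(comp$csize == max(comp$csize))
    if (length(big) > 1L) {
      anchor <- vapply(big, function(k)
        min(igraph::V(g)$name[comp$membership == k]), "")
      big <- big[order(anchor)][1L]
    }
    g <- igraph::induced_subgraph(g, comp$membership == big)
  }
  igraph::set_graph_attr(g, "largest_component", largestComponentOnly)
}

isWeighted <- function(g) isTRUE(igraph::graph_attr(g, "weighted"))

graphWeights <- function(g) if (isWeighted(g)) igraph::E(g)$weight else NULL

graphDistances <- function(g) {
  w <- graphWeights(g)
  igraph::distances(g, weights = if (is.null(w)) NA else 1 / w)
}

#' k-core decomposition and core genes
#'
#' Peels the graph: nodes of degree < k are removed repeatedly, k rising
#' from 1 until the graph is empty; a node's coreness is the largest k it
#' survives. The "core" genes are those of maximal coreness — the last
#' batch removed. Always computed on the unweighted topology.
#'
#' @param g an igraph graph from [buildGraph()].
#' @return A list with `coreness` (named integer vector) and `coreNodes`
#'   (character vector of maximal-coreness node ids).
#' @export
kcoreDecomposition <- function(g) {
  if (igraph::vcount(g) == 0L)
    return(list(coreness = integer(), coreNodes = character()))
  cores <- igraph::coreness(g)
  storage.mode(cores) <- "integer"
  list(coreness = cores,
       coreNodes = sort(names(cores)[cores == max(cores)]))
}

#' Detect communities by modularity optimisation
#'
#' Runs Louvain or Leiden (modularity objective) on the graph, using edge
#' weights when the graph is weighted. Community ids are 0-based and
#' ordered by decreasing community size (ties by smallest member id), so id
#' 0 is always the largest community.
#'
#' @param g an igraph graph from [buildGraph()].
#' @param method `"louvain"` or `"leiden"`.
#' @param resolution modularity resolution parameter; larger values favour
#'   more, smaller communities.
#' @param seed RNG seed — both heuristics are stochastic; a fixed seed
#'   makes the partition reproducible.
#' @return A list with `membership` (named 0-based integer vector) and
#'   `modularity` (the partition's modularity Q on `g`).
#' @export
detectCommunities <- function(g, method = c("louvain", "leiden"),
                              resolution = 1, seed = 42L) {
  if (length(method) == 1L && !method %in% c("louvain", "leiden"))
    abortUsage("unknown community method '", method,
               "'; use 'louvain' or 'leiden'")
  method <- match.arg(method)
  if (igraph::vcount(g) == 0L)
    return(list(membership = integer(), modularity = NA_real_))
  w <- graphWeights(g)
  set.seed(seed)
  cl <- switch(method,
    louvain = igraph::cluster_louvain(g, weights = w, resolution = resolution),
    leiden = igraph::cluster_leiden(g, objective_function = "modularity",
                                    weights = w, resolution = resolution,
                                    n_iterations = 10))
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  anchor <- vapply(names(sizes), function(k) min(names(memb)[memb == k]), "")
  ord <- names(sizes)[order(-as.integer(sizes), anchor)]
  remap <- stats::setNames(seq_along(ord) - 1L, ord)
  membership <- stats::setNames(as.integer(remap[as.character(memb)]),
                                names(memb))
  q <- igraph::modularity(g, memb, weights = w)
  list(membership = membership, modularity = q)
}

#' Node degree (unweighted) or strength (weighted)
#'
#' @param g an igraph graph from [buildGraph()].
#' @return Named numeric vector: edge count per node, or the sum of
#'   incident edge weights when the graph is weighted.
#' @export
degreeOrStrength <- function(g) {
  if (igraph::vcount(g) == 0L) return(numeric())
  if (isWeighted(g)) igraph::strength(g) else igraph::degree(g)
}

#' Eigenvector centrality by power iteration
#'
#' Entries of the principal eigenvector of the (possibly weighted)
#' adjacency matrix, computed per connected component with shifted power
#' iteration (iterating A + I, whose dominant eigenvector equals A's Perron
#' vector while immune to the +/-lambda oscillation of bipartite
#' components). Within each component the vector is non-negative with unit
#' Euclidean norm; singleton components get entry 1.
#'
#' @param g an igraph graph from [buildGraph()].
#' @param tol convergence tolerance on the max absolute change per
#'   iteration.
#' @param maxIter iteration cap; exceeding it is an error suggesting a
#'   larger cap.
#' @return Named numeric vector of centralities.
#' @export
eigenvectorCentrality <- function(g, tol = 1e-12, maxIter = 10000L) {
  nv <- igraph::vcount(g)
  if (nv == 0L) return(numeric())
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE,
                                   attr = if (isWeighted(g)) "weight" else NULL)
  comp <- igraph::components(g)$membership
  out <- stats::setNames(numeric(nv), igraph::V(g)$name)
  for (k in unique(comp)) {
    members <- which(comp == k)
    if (length(members) == 1L) {
      out[members] <- 1
      next
    }
    Ak <- A[members, members]
    v <- rep(1 / sqrt(length(members)), length(members))
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      vNew <- as.numeric(Ak %*% v) + v       # shifted: (A + I) v
      vNew <- vNew / sqrt(sum(vNew^2))
      if (max(abs(vNew - v)) < tol) {
        v <- vNew
        converged <- TRUE
        break
      }
      v <- vNew
    }
    if (!converged)
      abortNumeric("eigenvector centrality did not converge in ", maxIter,
                   " iterations; increase maxIter")
    out[members] <- abs(v)                    # Perron vector is non-negative
  }
  out
}

#' Betweenness centrality
#'
#' Unnormalised shortest-path betweenness: for each node, the number of
#' shortest paths between other node pairs that pass through it (fractional
#' credit when a pair has several shortest paths; endpoints excluded). On
#' weighted graphs path lengths use 1/weight.
#'
#' @param g an igraph graph from [buildGraph()].
#' @return Named numeric vector.
#' @export
betweennessCentrality <- function(g) {
  if (igraph::vcount(g) == 0L) return(numeric())
  w <- graphWeights(g)
  igraph::betweenness(g, directed = FALSE,
                      weights = if (is.null(w)) NA else 1 / w)
}

#' Closeness centrality (harmonic or classic)
#'
#' The default harmonic variant is the sum over all other nodes of the
#' reciprocal shortest-path distance, with unreachable nodes contributing
#' 0 — well defined on disconnected graphs. The classic variant is
#' (number reachable) / (sum of distances to them), computed within each
#' component; isolated nodes get 0. Weighted distances use 1/weight.
#'
#' @param g an igraph graph from [buildGraph()].
#' @param variant `"harmonic"` (default) or `"classic"`.
#' @return Named numeric vector.
#' @export
closenessCentrality <- function(g, variant = c("harmonic", "classic")) {
  if (length(variant) == 1L && !variant %in% c("harmonic", "classic"))
    abortUsage("unknown closeness variant '", variant,
               "'; use 'harmonic' or 'classic'")
  variant <- match.arg(variant)
  if (igraph::vcount(g) == 0L) return(numeric())
  d <- graphDistances(g)
  diag(d) <- Inf                              # exclude self
  if (variant == "harmonic") {
    rowSums(1 / d)                            # 1/Inf = 0 handles unreachable
  } else {
    apply(d, 1L, function(row) {
      reach <- is.finite(row)
      if (!any(reach)) 0 else sum(reach) / sum(row[reach])
    })
  }
}

#' Compute the full node-property table and distribution summaries
#'
#' One row per node with all property families: degree or strength,
#' community id, coreness, core flag, eigenvector, betweenness and
#' closeness centrality. Also returns compact distribution summaries
#' (degree histogram on the unweighted topology, community sizes, coreness
#' counts) matching the tool's summary figures.
#'
#' @param g an igraph graph from [buildGraph()].
#' @param method,resolution,seed community-detection settings, see
#'   [detectCommunities()].
#' @param closenessVariant see [closenessCentrality()].
#' @return A list with `table` (data.frame with columns `Id`, `Degree`,
#'   `Community`, `Coreness`, `IsCore`, `Eigenvector`, `Betweenness`,
#'   `Closeness`), `summaries` (list of data.frames `degree`,
#'   `communities`, `coreness`) and `modularity`.
#' @export
nodePropertyTable <- function(g, method = "louvain", resolution = 1,
                              seed = 42L, closenessVariant = "harmonic") {
  if (igraph::vcount(g) == 0L) {
    empty <- data.frame(Id = character(), Degree = numeric(),
                        Community = integer(), Coreness = integer(),
                        IsCore = logical(), Eigenvector = numeric(),
                        Betweenness = numeric(), Closeness = numeric())
    return(list(table = empty,
                summaries = list(degree = data.frame(degree = integer(),
                                                     count = integer()),
                                 communities = data.frame(community = integer(),
                                                          size = integer()),
                                 coreness = data.frame(coreness = integer(),
                                                       count = integer())),
                modularity = NA_real_))
  }
  ids <- igraph::V(g)$name
  deg <- degreeOrStrength(g)
  comm <- detectCommunities(g, method = method, resolution = resolution,
                            seed = seed)
  kc <- kcoreDecomposition(g)
  tab <- data.frame(
    Id = ids,
    Degree = as.numeric(deg[ids]),
    Community = as.integer(comm$membership[ids]),
    Coreness = as.integer(kc$coreness[ids]),
    IsCore = ids %in% kc$coreNodes,
    Eigenvector = as.numeric(eigenvectorCentrality(g)[ids]),
    Betweenness = as.numeric(betweennessCentrality(g)[ids]),
    Closeness = as.numeric(closenessCentrality(g, closenessVariant)[ids]),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  topoDeg <- igraph::degree(g)
  degTab <- as.data.frame(table(topoDeg), stringsAsFactors = FALSE)
  names(degTab) <- c("degree", "count")
  degTab$degree <- as.integer(degTab$degree)
  commTab <- as.data.frame(table(tab$Community), stringsAsFactors = FALSE)
  names(commTab) <- c("community", "size")
  commTab$community <- as.integer(commTab$community)
  coreTab <- as.data.frame(table(tab$Coreness), stringsAsFactors = FALSE)
  names(coreTab) <- c("coreness", "count")
  coreTab$coreness <- as.integer(coreTab$coreness)

  list(table = tab,
       summaries = list(degree = degTab, communities = commTab,
                        coreness = coreTab),
       modularity = comm$modularity)
}
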