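# Independent oracles and fixture builders. Everything here is deliberately
# naive (loops, Floyd-Warshall, dense eigen, iterative peeling) so the fast
# implementations in R/ are checked against a different route.

exprFromMatrix <- function(v) {
  if (is.null(rownames(v))) rownames(v) <- sprintf("g%02d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("c%02d", seq_len(ncol(v)))
  ExpressionData(v)
}

randomMaskedMatrix <- function(nGenes, nConds, missingRate = 0) {
  v <- matrix(rnorm(nGenes * nConds), nGenes, nConds)
  if (missingRate > 0)
    v[matrix(runif(nGenes * nConds) < missingRate, nGenes, nConds)] <- NA
  exprFromMatrix(v)
}

# explicit pair-loop pairwise-complete PCC
loopPCC <- function(v, minPairs = 3L) {
  n <- nrow(v)
  r <- matrix(NA_real_, n, n)
  cnt <- matrix(NA_integer_, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- !is.na(v[i, ]) & !is.na(v[j, ])
    cnt[i, j] <- sum(shared)
    if (sum(shared) >= minPairs) {
      a <- v[i, shared]; b <- v[j, shared]
      if (sd(a) > 0 && sd(b) > 0)
        r[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
          ((length(a) - 1) * sd(a) * sd(b))
    }
  }
  list(pcc = r, count = cnt)
}

# PairStatistics with prescribed per-pair pcc and paired counts, for
# threshold-module tests that need full control of the pair population
makePairStats <- function(pcc, counts, minPairs = 3L) {
  nPairs <- length(pcc)
  n <- ceiling((1 + sqrt(1 + 8 * nPairs)) / 2)
  stopifnot(n * (n - 1) / 2 >= nPairs)
  ids <- sprintf("g%03d", seq_len(n))
  pm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  cm <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  ut <- which(upper.tri(pm), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE][seq_len(nPairs), ,
                                                      drop = FALSE]
  pm[ut] <- pcc
  cm[ut] <- as.integer(counts)
  new("PairStatistics", geneIds = ids, pcc = pm, pairedCount = cm,
      minPairs = as.integer(minPairs))
}

makeModel <- function(alpha, eta, lambda, beta) {
  bins <- data.frame(bin_low = 1L, bin_high = 1L, x_rep = 1, n_pairs = 1L,
                     q_thresh = 0)
  new("ThresholdModel", alpha = alpha, eta = eta, lambda = lambda,
      beta = beta, rSquared = 1,
      bins = new("BinQuantileTable", binSize = 1L, cutoff = 0.5,
                 minBinCount = 1L, bins = bins),
      residuals = 0)
}

edgesFromAdjacency <- function(adj, ids = sprintf("n%02d", seq_len(nrow(adj)))) {
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  e <- data.frame(Source = ids[idx[, 1L]], Target = ids[idx[, 2L]],
                  stringsAsFactors = FALSE)
  if (any(adj[idx] != 1)) e$Weight <- adj[idx]
  e
}

randomGraph <- function(nNodes, edgeProb = 0.25, weighted = FALSE) {
  adj <- matrix(0, nNodes, nNodes)
  ut <- upper.tri(adj)
  adj[ut] <- (runif(sum(ut)) < edgeProb) * 1
  if (weighted) adj[ut] <- adj[ut] * runif(sum(ut), 0.2, 1)
  adj + t(adj)
}

# adjacency -> matrix of edge lengths (1 or 1/weight), Inf off-edges
lengthMatrix <- function(adj, weighted = FALSE) {
  len <- ifelse(adj > 0, if (weighted) 1 / adj else (adj > 0) * 1, Inf)
  diag(len) <- 0
  len
}

floydWarshall <- function(len) {
  n <- nrow(len)
  d <- len
  for (k in seq_len(n)) {
    viaK <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, viaK)
  }
  d
}

# shortest-path counts from source s, by DP in distance order
pathCounts <- function(len, d, s) {
  n <- nrow(len)
  sigma <- numeric(n)
  sigma[s] <- 1
  ord <- order(d[s, ])
  for (v in ord) {
    if (v == s || !is.finite(d[s, v])) next
    pred <- which(is.finite(len[, v]) & len[, v] > 0 &
                    abs(d[s, ] + len[, v] - d[s, v]) < 1e-10)
    sigma[v] <- sum(sigma[pred])
  }
  sigma
}

fwBetweenness <- function(adj, weighted = FALSE) {
  len <- lengthMatrix(adj, weighted)
  d <- floydWarshall(len)
  n <- nrow(adj)
  sigma <- t(vapply(seq_len(n), function(s) pathCounts(len, d, s),
                    numeric(n)))  # sigma[s, v]
  bc <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (abs(d[s, v] + d[v, t] - d[s, t]) < 1e-10)
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    bc[v] <- acc
  }
  bc
}

fwHarmonic <- function(adj, weighted = FALSE) {
  d <- floydWarshall(lengthMatrix(adj, weighted))
  diag(d) <- Inf
  rowSums(1 / d)
}

fwClassic <- function(adj, weighted = FALSE) {
  d <- floydWarshall(lengthMatrix(adj, weighted))
  diag(d) <- Inf
  apply(d, 1L, function(row) {
    reach <- is.finite(row)
    if (!any(reach)) 0 else sum(reach) / sum(row[reach])
  })
}

bruteCoreness <- function(adj) {
  n <- nrow(adj)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 1L
  while (any(alive)) {
    repeat {
      deg <- rowSums(adj[, alive, drop = FALSE])[alive]
      drop <- which(alive)[deg < k]
      if (length(drop) == 0L) break
      core[drop] <- k - 1L
      alive[drop] <- FALSE
    }
    if (any(alive)) core[alive] <- k  # survivors of the k-core so far
    k <- k + 1L
  }
  core
}

denseEigenvector <- function(adj) {
  # principal eigenvector per connected component, unit norm, non-negative
  n <- nrow(adj)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected"))$membership
  out <- numeric(n)
  for (k in unique(comp)) {
    m <- which(comp == k)
    if (length(m) == 1L) { out[m] <- 1; next }
    ev <- eigen(adj[m, m], symmetric = TRUE)
    v <- ev$vectors[, which.max(ev$values)]
    out[m] <- abs(v) / sqrt(sum(v^2))
  }
  out
}

directModularity <- function(adj, membership) {
  m2 <- sum(adj)  # 2m for unweighted 0/1 or weighted adjacency
  k <- rowSums(adj)
  same <- outer(membership, membership, `==`)
  sum((adj - outer(k, k) / m2) * same) / m2
}
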