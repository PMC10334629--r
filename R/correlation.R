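#' Pairwise-complete Pearson correlations with paired-condition counts
#'
#' For every unordered gene pair, both expression profiles are restricted to
#' the conditions where *both* genes are observed; the paired count is the
#' size of that restriction and the correlation is the sample Pearson
#' coefficient on it. A pair's correlation is left undefined (`NA`) when the
#' paired count is below `minPairs` or either restricted profile has zero
#' variance; such pairs are excluded from binning and edge selection but
#' their paired counts are still reported.
#'
#' The computation uses a dense masked cross-product formulation (one pass
#' over the matrix rather than a loop over the N(N-1)/2 pairs), after
#' centring each gene by its overall observed mean — a per-gene constant
#' shift that leaves every pairwise correlation unchanged while improving
#' floating-point conditioning. Memory and time scale as N^2; matrices up to
#' roughly N = 20,000 genes are practical on commodity hardware.
#'
#' @param x an [ExpressionData-class] object with N >= 2 genes.
#' @param minPairs minimum paired count for a correlation to be defined.
#'   The default of 3 exists because a Pearson correlation over 2 points is
#'   +/-1 by construction, which would guarantee spurious edges.
#' @return A [PairStatistics-class] object.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
#' s <- pairwisePCC(ExpressionData(m))
#' pccMatrix(s)["gA", "gB"]    # 1: perfectly linear
#' pairedCounts(s)["gA", "gB"] # 3 shared conditions
#' @export
pairwisePCC <- function(x, minPairs = 3L) {
  if (minPairs < 1L) abortUsage("minPairs must be a positive integer")
  X <- exprValues(x)
  n_genes <- nrow(X)
  if (n_genes < 2L) abortUsage("need at least 2 genes")

  X <- X - rowMeans(X, na.rm = TRUE)       # correlation-invariant recentring
  X[is.na(X)] <- 0                          # masked entries contribute 0
  P <- (exprValues(x) * 0 + 1)
  P[is.na(P)] <- 0                          # presence indicators

  n <- tcrossprod(P)                        # paired counts
  Sx <- tcrossprod(X, P)                    # sum of gene i over overlap with j
  Sxy <- tcrossprod(X)
  Sxx <- tcrossprod(X * X, P)

  num <- n * Sxy - Sx * t(Sx)
  v1 <- n * Sxx - Sx^2                      # n^2 * var of i over the overlap
  v2 <- t(v1)
  den <- sqrt(pmax(v1, 0) * pmax(v2, 0))
  r <- num / den
  r[!is.finite(r)] <- NA_real_
  r[v1 <= 1e-12 * n * Sxx | v2 <= 1e-12 * n * t(Sxx)] <- NA_real_  # zero variance
  r[n < minPairs] <- NA_real_
  r <- pmin(pmax(r, -1), 1)

  keepUpper <- function(m) {
    m[lower.tri(m, diag = TRUE)] <- NA
    m
  }
  cnt <- keepUpper(matrix(as.integer(round(n)), n_genes, n_genes,
                          dimnames = dimnames(n)))
  new("PairStatistics", geneIds = rownames(exprValues(x)),
      pcc = keepUpper(r), pairedCount = cnt, minPairs = as.integer(minPairs))
}

upperTriangularLines <- function(m, ids) {
  chr <- matrix("", nrow(m), ncol(m))
  ut <- upper.tri(m) & !is.na(m)
  chr[ut] <- as.character(m[ut])
  c(paste(c("", ids), collapse = ","),
    paste(ids, apply(chr, 1L, paste, collapse = ","), sep = ","))
}

#' Write correlation and paired-count matrices as upper-triangular CSVs
#'
#' Each file is an N x N table with gene ids as header and index; cells on
#' or below the diagonal are empty, as are undefined correlations.
#'
#' @param s a [PairStatistics-class] object.
#' @param pccPath,countPath output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
writeUpperTriangular <- function(s, pccPath = NULL, countPath = NULL) {
  ids <- s@geneIds
  if (!is.null(pccPath))
    writeLines(upperTriangularLines(pccMatrix(s), ids), pccPath)
  if (!is.null(countPath))
    writeLines(upperTriangularLines(pairedCounts(s), ids), countPath)
  invisible(c(pccPath, countPath))
}
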