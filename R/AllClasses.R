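#' @include conditions.R
NULL

TRANSFORM_NAMES <- c("remove_zeros", "log2", "zscore")

# ---------------------------------------------------------------------------
# ExpressionData
# ---------------------------------------------------------------------------

#' ExpressionData: an expression matrix with explicit missingness
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"exprs"` assay (genes in rows, experimental conditions in columns,
#' `NA` for missing cells) plus the ordered list of transformations that have
#' been applied, kept in `metadata(x)$transforms`.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @seealso [loadExpression()], [removeZeros()], [log2Rescale()],
#'   [zscoreColumns()]
#' @exportClass ExpressionData
setClass("ExpressionData", contains = "SummarizedExperiment")

setValidity("ExpressionData", function(object) {
  msg <- character()
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  if (nrow(object) < 2L)
    msg <- c(msg, "at least 2 genes (rows) are required")
  if (ncol(object) < 1L)
    msg <- c(msg, "at least 1 condition (column) is required")
  gid <- rownames(object)
  cid <- colnames(object)
  if (is.null(gid) || anyDuplicated(gid))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(cid) || anyDuplicated(cid))
    msg <- c(msg, "condition ids must be present and unique")
  tr <- metadata(object)$transforms
  if (!is.character(tr) || !all(tr %in% TRANSFORM_NAMES))
    msg <- c(msg, sprintf("metadata()$transforms must be a character vector drawn from {%s}",
                          paste(TRANSFORM_NAMES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionData object
#'
#' @param values numeric matrix, genes x conditions; `NA` marks missing cells.
#' @param geneIds,conditionIds identifiers; default to the dimnames of
#'   `values`.
#' @param transforms ordered character vector of transformations already
#'   applied (normally empty).
#' @return An [ExpressionData-class] object.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("gA", "gB"), c("c1", "c2")))
#' ExpressionData(m)
#' @export
ExpressionData <- function(values, geneIds = rownames(values),
                           conditionIds = colnames(values),
                           transforms = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    abortUsage("'values' must be a numeric matrix")
  storage.mode(values) <- "double"
  if (is.null(geneIds) || is.null(conditionIds))
    abortUsage("gene and condition ids are required (dimnames or arguments)")
  dimnames(values) <- list(as.character(geneIds), as.character(conditionIds))
  se <- SummarizedExperiment(assays = list(exprs = values))
  metadata(se)$transforms <- as.character(transforms)
  new("ExpressionData", se)
}

#' @describeIn ExpressionData gene identifiers (rownames).
#' @param x an `ExpressionData` object.
#' @export
geneIds <- function(x) rownames(x)

#' @describeIn ExpressionData condition identifiers (colnames).
#' @export
conditionIds <- function(x) colnames(x)

#' @describeIn ExpressionData the expression matrix with `NA` for missing.
#' @export
exprValues <- function(x) assay(x, "exprs")

#' @describeIn ExpressionData ordered transformations applied so far.
#' @export
transformsApplied <- function(x) metadata(x)$transforms

setMethod("show", "ExpressionData", function(object) {
  v <- exprValues(object)
  cat(sprintf("ExpressionData: %d genes x %d conditions (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  tr <- transformsApplied(object)
  cat("transforms:", if (length(tr)) paste(tr, collapse = " -> ") else "(none)", "\n")
})

# ---------------------------------------------------------------------------
# PairStatistics
# ---------------------------------------------------------------------------

#' PairStatistics: pairwise-complete correlations and paired counts
#'
#' Holds, for every unordered gene pair, the Pearson correlation computed on
#' the conditions where both genes are observed and the number of those
#' shared conditions. Both matrices are stored upper-triangular: cells on or
#' below the diagonal are `NA`. A correlation is *defined* (non-`NA` in
#' `pccMatrix`) only when the paired count reaches `minPairs` and both
#' restricted profiles have nonzero variance.
#'
#' @slot geneIds character vector of N gene identifiers.
#' @slot pcc numeric N x N matrix, upper triangle only; `NA` marks
#'   undefined correlations.
#' @slot pairedCount integer N x N matrix, upper triangle only.
#' @slot minPairs integer validity floor used when the object was computed.
#' @seealso [pairwisePCC()]
#' @exportClass PairStatistics
setClass("PairStatistics",
         representation(geneIds = "character", pcc = "matrix",
                        pairedCount = "matrix", minPairs = "integer"))

setValidity("PairStatistics", function(object) {
  n <- length(object@geneIds)
  msg <- character()
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "gene ids must be unique")
  if (!all(dim(object@pcc) == n) || !all(dim(object@pairedCount) == n))
    msg <- c(msg, "pcc and pairedCount must be N x N")
  low <- lower.tri(object@pcc, diag = TRUE)
  if (any(!is.na(object@pcc[low])))
    msg <- c(msg, "pcc must be NA on and below the diagonal")
  r <- object@pcc[upper.tri(object@pcc)]
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "defined correlations must lie in [-1, 1]")
  cnt <- object@pairedCount[upper.tri(object@pairedCount)]
  if (any(cnt < 0, na.rm = TRUE))
    msg <- c(msg, "paired counts must be non-negative")
  if (length(object@minPairs) != 1L || object@minPairs < 1L)
    msg <- c(msg, "minPairs must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' @describeIn PairStatistics upper-triangular matrix of defined pairwise
#'   correlations (`NA` elsewhere).
#' @param x a `PairStatistics` object.
#' @export
pccMatrix <- function(x) x@pcc

#' @describeIn PairStatistics upper-triangular matrix of paired-condition
#'   counts.
#' @export
pairedCounts <- function(x) x@pairedCount

#' @describeIn PairStatistics the validity floor on paired counts.
#' @export
minPairs <- function(x) x@minPairs

setMethod("show", "PairStatistics", function(object) {
  ut <- upper.tri(object@pcc)
  cat(sprintf("PairStatistics: %d genes, %d pairs (%d with defined PCC), min_pairs = %d\n",
              length(object@geneIds), sum(ut), sum(!is.na(object@pcc[ut])),
              object@minPairs))
})

# ---------------------------------------------------------------------------
# BinQuantileTable
# ---------------------------------------------------------------------------

#' BinQuantileTable: per-bin top-percentage correlation quantiles
#'
#' Gene pairs are binned by paired count into contiguous intervals of width
#' `binSize`; within each retained bin, `q_thresh` is the k-th largest
#' defined correlation with `k = ceiling(cutoff * n_pairs)`.
#'
#' @slot binSize integer bin width (paired-count units).
#' @slot cutoff top fraction retained per bin, in (0, 1).
#' @slot minBinCount bins with fewer pairs than this were dropped.
#' @slot bins data.frame with columns `bin_low`, `bin_high`, `x_rep`
#'   (arithmetic midpoint), `n_pairs`, `q_thresh`.
#' @seealso [binQuantiles()], [generateNullQuantiles()]
#' @exportClass BinQuantileTable
setClass("BinQuantileTable",
         representation(binSize = "integer", cutoff = "numeric",
                        minBinCount = "integer", bins = "data.frame"))

setValidity("BinQuantileTable", function(object) {
  msg <- character()
  if (object@binSize < 1L) msg <- c(msg, "binSize must be >= 1")
  if (object@cutoff <= 0 || object@cutoff >= 1)
    msg <- c(msg, "cutoff must lie in (0, 1)")
  need <- c("bin_low", "bin_high", "x_rep", "n_pairs", "q_thresh")
  if (!all(need %in% names(object@bins)))
    msg <- c(msg, paste("bins must have columns", paste(need, collapse = ", ")))
  else {
    if (any(abs(object@bins$q_thresh) > 1 + 1e-12))
      msg <- c(msg, "q_thresh must lie in [-1, 1]")
    if (any(object@bins$bin_high < object@bins$bin_low))
      msg <- c(msg, "bin_high must be >= bin_low")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BinQuantileTable the retained-bin table.
#' @param x a `BinQuantileTable` object.
#' @export
binTable <- function(x) x@bins

setMethod("show", "BinQuantileTable", function(object) {
  cat(sprintf("BinQuantileTable: %d bins (width %d, cutoff %g, min bin count %d)\n",
              nrow(object@bins), object@binSize, object@cutoff,
              object@minBinCount))
  if (nrow(object@bins)) print(head(object@bins, 8))
})

# ---------------------------------------------------------------------------
# ThresholdModel
# ---------------------------------------------------------------------------

#' ThresholdModel: the fitted sliding-threshold curve
#'
#' Parameters of \eqn{f(x) = \alpha - 1/(\eta + \lambda e^{-x/\beta})}
#' fitted by bounded least squares to a [BinQuantileTable-class], with the
#' coefficient of determination and per-bin residuals.
#'
#' @slot alpha,eta,lambda,beta fitted curve parameters
#'   (\eqn{\eta > 0, \lambda \ge 0, \beta > 0}).
#' @slot rSquared goodness of fit, \eqn{1 - SS_{res}/SS_{tot}}.
#' @slot bins the quantile table the fit was computed from.
#' @slot residuals per-bin residuals `q_thresh - f(x_rep)`.
#' @seealso [fitThresholdCurve()], [thresholdAt()], [selectEdges()]
#' @exportClass ThresholdModel
setClass("ThresholdModel",
         representation(alpha = "numeric", eta = "numeric", lambda = "numeric",
                        beta = "numeric", rSquared = "numeric",
                        bins = "BinQuantileTable", residuals = "numeric"))

setValidity("ThresholdModel", function(object) {
  msg <- character()
  for (s in c("alpha", "eta", "lambda", "beta", "rSquared"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("%s must be a single finite number", s))
  if (length(msg) == 0L) {
    if (object@eta <= 0) msg <- c(msg, "eta must be > 0")
    if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
    if (object@beta <= 0) msg <- c(msg, "beta must be > 0")
    if (object@rSquared > 1 + 1e-12) msg <- c(msg, "rSquared must be <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ThresholdModel named vector of the four fitted parameters.
#' @param x a `ThresholdModel` object.
#' @export
thresholdParams <- function(x) {
  c(alpha = x@alpha, eta = x@eta, lambda = x@lambda, beta = x@beta)
}

#' @describeIn ThresholdModel the fit's coefficient of determination.
#' @export
rSquared <- function(x) x@rSquared

setMethod("show", "ThresholdModel", function(object) {
  cat(sprintf(
    "ThresholdModel: f(x) = %.4g - 1/(%.4g + %.4g*exp(-x/%.4g)),  R^2 = %.4f\n",
    object@alpha, object@eta, object@lambda, object@beta, object@rSquared))
  cat(sprintf("fitted on %d bins; asymptotic threshold alpha - 1/eta = %.4f\n",
              nrow(binTable(object@bins)), object@alpha - 1 / object@eta))
})
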