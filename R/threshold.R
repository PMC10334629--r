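#' Bin correlations by paired count and take top-percentage quantiles
#'
#' Defined pairwise correlations are grouped into contiguous paired-count
#' intervals of width `binSize` starting at the smallest observed count (the
#' last bin may be shorter). Within each bin the empirical threshold
#' `q_thresh` is the k-th largest correlation, `k = ceiling(cutoff *
#' n_pairs)` — the value a pair must reach to sit in the bin's top `cutoff`
#' fraction. Bins with fewer than `minBinCount` pairs give unstable
#' quantiles and are dropped before curve fitting.
#'
#' @param s a [PairStatistics-class] object with at least one defined
#'   correlation.
#' @param binSize width of the paired-count intervals.
#' @param cutoff top fraction retained per bin, in (0, 1); typical values
#'   0.005, 0.01, 0.02.
#' @param minBinCount minimum pairs per retained bin.
#' @return A [BinQuantileTable-class] object.
#' @export
binQuantiles <- function(s, binSize = 10L, cutoff = 0.005, minBinCount = 50L) {
  if (binSize < 1L) abortUsage("binSize must be >= 1")
  if (cutoff <= 0 || cutoff >= 1) abortUsage("cutoff must lie in (0, 1)")
  ut <- upper.tri(pccMatrix(s))
  r <- pccMatrix(s)[ut]
  cnt <- pairedCounts(s)[ut]
  ok <- !is.na(r)
  if (!any(ok)) abortData("no defined correlations to bin")
  r <- r[ok]
  cnt <- cnt[ok]

  lo <- min(cnt)
  idx <- (cnt - lo) %/% binSize
  rows <- lapply(sort(unique(idx)), function(k) {
    inBin <- idx == k
    nb <- sum(inBin)
    binLow <- lo + k * binSize
    binHigh <- min(binLow + binSize - 1L, max(cnt))
    kth <- ceiling(cutoff * nb)
    data.frame(bin_low = binLow, bin_high = binHigh,
               x_rep = (binLow + binHigh) / 2, n_pairs = nb,
               q_thresh = sort(r[inBin], decreasing = TRUE)[kth])
  })
  bins <- do.call(rbind, rows)
  bins <- bins[bins$n_pairs >= minBinCount, , drop = FALSE]
  if (nrow(bins) == 0L)
    abortData("no bin reaches minBinCount = ", minBinCount,
              "; lower minBinCount or binSize")
  rownames(bins) <- NULL
  new("BinQuantileTable", binSize = as.integer(binSize), cutoff = cutoff,
      minBinCount = as.integer(minBinCount), bins = bins)
}

slidingCurve <- function(p, x) p[1L] - 1 / (p[2L] + p[3L] * exp(-x / p[4L]))

#' Fit the sliding-threshold curve to binned quantiles
#'
#' Fits \eqn{f(x) = \alpha - 1/(\eta + \lambda e^{-x/\beta})} to the
#' `(x_rep, q_thresh)` points by bounded Levenberg–Marquardt least squares
#' ([minpack.lm::nls.lm]), with \eqn{\eta > 0}, \eqn{\lambda \ge 0},
#' \eqn{\beta > 0} so the curve is finite and non-increasing for all
#' \eqn{x \ge 0}. Because \eqn{\lambda} and \eqn{\beta} can be weakly
#' identified (e.g. nearly flat data), the fit is restarted from a fixed
#' grid of starting points and the solution with the smallest residual sum
#' of squares wins: \eqn{\alpha_0 = \max q}, \eqn{\eta_0 = 1/(\alpha_0 -
#' \min q + 0.01)}, \eqn{\lambda_0 \in \{1, 10, 100\}}, \eqn{\beta_0 \in
#' \{range/10, range/3\}}. The start grid is fixed, so the fit is fully
#' deterministic.
#'
#' @param t a [BinQuantileTable-class] with at least 4 retained bins (the
#'   curve has 4 free parameters).
#' @return A [ThresholdModel-class] object. `rSquared` is
#'   \eqn{1 - SS_{res}/SS_{tot}}; for degenerate constant data
#'   (\eqn{SS_{tot} = 0}) it is reported as 1 when the fit is exact and 0
#'   otherwise.
#' @export
fitThresholdCurve <- function(t) {
  bins <- binTable(t)
  if (nrow(bins) < 4L)
    abortNumeric("need >= 4 retained bins to fit 4 parameters; got ",
                 nrow(bins))
  x <- bins$x_rep
  q <- bins$q_thresh
  residFn <- function(p) q - slidingCurve(p, x)

  a0 <- max(q)
  e0 <- 1 / (a0 - min(q) + 0.01)
  rng <- max(diff(range(x)), 1)
  starts <- expand.grid(lambda0 = c(1, 10, 100), beta0 = c(rng / 10, rng / 3))

  best <- NULL
  diagnostics <- character(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(a0, e0, starts$lambda0[i], starts$beta0[i]),
        lower = c(-Inf, 1e-9, 0, 1e-9), fn = residFn,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics[i] <- conditionMessage(fit)
    } else {
      diagnostics[i] <- sprintf("SS_res = %.3g", fit$deviance)
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
  }
  if (is.null(best))
    abortNumeric("sliding-threshold fit failed from every start:\n",
                 paste(sprintf("  start %d: %s", seq_along(diagnostics),
                               diagnostics), collapse = "\n"))
  p <- best$par
  ssRes <- best$deviance
  ssTot <- sum((q - mean(q))^2)
  r2 <- if (ssTot > 1e-30) 1 - ssRes / ssTot else as.numeric(ssRes < 1e-20)
  new("ThresholdModel", alpha = p[1L], eta = p[2L], lambda = p[3L],
      beta = p[4L], rSquared = r2, bins = t,
      residuals = q - slidingCurve(p, x))
}

#' Evaluate the sliding threshold at a paired count
#'
#' @param model a [ThresholdModel-class] object.
#' @param x paired count(s), >= 0; vectorised.
#' @return The correlation threshold \eqn{f(x)}. With \eqn{\lambda = 0} the
#'   curve is flat at \eqn{\alpha - 1/\eta}, which is also its large-x
#'   asymptote.
#' @export
thresholdAt <- function(model, x) {
  slidingCurve(c(model@alpha, model@eta, model@lambda, model@beta), x)
}

#' Select network edges through the fitted threshold curve
#'
#' A pair (i, j) becomes an edge precisely when its correlation is defined
#' and reaches the curve evaluated at the pair's own paired count:
#' `pcc >= thresholdAt(model, paired_count)` (ties at the threshold are
#' kept). By default only the signed upper tail qualifies — strongly
#' negative correlations never form edges; `absolute = TRUE` thresholds
#' `|pcc|` instead.
#'
#' @param s a [PairStatistics-class] object.
#' @param model a [ThresholdModel-class] object.
#' @param weighted attach the correlation as edge weight.
#' @param absolute threshold the absolute correlation.
#' @return A data.frame with columns `Source`, `Target` (and `Weight` when
#'   `weighted`), one row per edge, deduplicated, self-loop-free and sorted
#'   by (Source, Target).
#' @export
selectEdges <- function(s, model, weighted = FALSE, absolute = FALSE) {
  ut <- upper.tri(pccMatrix(s))
  idx <- which(ut & !is.na(pccMatrix(s)), arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(emptyEdgeList(weighted))
  r <- pccMatrix(s)[idx]
  cnt <- pairedCounts(s)[idx]
  val <- if (absolute) abs(r) else r
  sel <- val >= thresholdAt(model, cnt)
  idx <- idx[sel, , drop = FALSE]
  if (nrow(idx) == 0L)
    return(emptyEdgeList(weighted))
  ids <- s@geneIds
  edges <- data.frame(Source = ids[idx[, 1L]], Target = ids[idx[, 2L]],
                      stringsAsFactors = FALSE)
  if (weighted) edges$Weight <- r[sel]
  edges <- edges[order(edges$Source, edges$Target), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

emptyEdgeList <- function(weighted) {
  e <- data.frame(Source = character(), Target = character(),
                  stringsAsFactors = FALSE)
  if (weighted) e$Weight <- numeric()
  e
}

#' Write / read an edge list CSV
#'
#' The on-disk dialect is `Source,Target[,Weight]` with one row per edge —
#' directly importable by Gephi. `readEdgeList` validates each row and
#' reports the first offending line number.
#'
#' @param edges an edge-list data.frame as returned by [selectEdges()].
#' @param path file path.
#' @return `writeEdgeList`: `path` invisibly. `readEdgeList`: the edge-list
#'   data.frame.
#' @export
writeEdgeList <- function(edges, path) {
  write.csv(edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) abortData("edge list not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) abortData("empty edge list file: ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "Source" || header[2L] != "Target")
    abortData("edge list must start with header 'Source,Target[,Weight]': ",
              path)
  hasWeight <- length(header) >= 3L && header[3L] == "Weight"
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  expected <- if (hasWeight) 3L else 2L
  if (any(nf != expected))
    abortData("malformed edge list row at line ",
              which(nf != expected)[1L] + 1L, " of ", path)
  edges <- data.frame(Source = vapply(parts, `[`, "", 1L),
                      Target = vapply(parts, `[`, "", 2L),
                      stringsAsFactors = FALSE)
  if (hasWeight) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
    if (anyNA(w))
      abortData("non-numeric weight at line ", which(is.na(w))[1L] + 1L,
                " of ", path)
    edges$Weight <- w
  }
  edges
}

#' Write the threshold-curve report
#'
#' Emits a CSV of `(x_rep, q_thresh, f_fit)` for the retained bins plus a
#' small text block with the fitted parameters and R-squared.
#'
#' @param model a [ThresholdModel-class] object.
#' @param curvePath CSV output path.
#' @param paramsPath text output path (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
writeThresholdReport <- function(model, curvePath, paramsPath = NULL) {
  bins <- binTable(model@bins)
  out <- data.frame(x_rep = bins$x_rep, q_thresh = bins$q_thresh,
                    f_fit = thresholdAt(model, bins$x_rep))
  write.csv(out, curvePath, row.names = FALSE)
  if (!is.null(paramsPath)) {
    p <- thresholdParams(model)
    writeLines(c(sprintf("alpha  = %.10g", p[["alpha"]]),
                 sprintf("eta    = %.10g", p[["eta"]]),
                 sprintf("lambda = %.10g", p[["lambda"]]),
                 sprintf("beta   = %.10g", p[["beta"]]),
                 sprintf("R2     = %.10g", rSquared(model))),
               paramsPath)
  }
  invisible(c(curvePath, paramsPath))
}
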