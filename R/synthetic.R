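#' Generate a block-structured expression matrix with missing values
#'
#' Emulates the statistical structure the pipeline assumes: co-expressed
#' gene modules, independent noise and missing-at-random entries. Genes are
#' split into `nModules` balanced, contiguous modules (sizes differ by at
#' most 1); gene g in module m gets
#' \deqn{X_{gc} = \sqrt{\rho}\, F_{m c} + \sqrt{1-\rho}\, \sigma\,
#'   \epsilon_{gc}}
#' with standard-normal latent module profiles \eqn{F} and noise
#' \eqn{\epsilon}, so at the default `noiseSd = 1` the expected
#' within-module correlation is exactly `withinCorr` (\eqn{\rho}) and the
#' expected between-module correlation is 0. Entries are then masked
#' missing independently with probability `missingRate`, which makes paired
#' counts vary across gene pairs.
#'
#' @param nGenes,nConditions matrix dimensions.
#' @param nModules number of planted modules (<= `nGenes`).
#' @param withinCorr target within-module correlation, in \[0, 1); 0 gives a
#'   pure-noise matrix with no module structure (useful for null
#'   calibration).
#' @param noiseSd noise scale; values other than 1 shift the realised
#'   within-module correlation to
#'   \eqn{\rho / (\rho + (1-\rho)\sigma^2)}.
#' @param missingRate per-cell missingness probability, in \[0, 1).
#' @param seed RNG seed; the same seed reproduces the matrix bit for bit.
#' @return A list with `expr` (an [ExpressionData-class]) and `modules`
#'   (named integer vector of planted module labels, 1-based).
#' @examples
#' sim <- generateBlockExpression(nGenes = 20, nConditions = 50,
#'                                nModules = 2, seed = 1)
#' table(sim$modules)
#' @export
generateBlockExpression <- function(nGenes = 100L, nConditions = 200L,
                                    nModules = 4L, withinCorr = 0.8,
                                    noiseSd = 1, missingRate = 0,
                                    seed = 42L) {
  if (nModules > nGenes) abortUsage("nModules must be <= nGenes")
  if (withinCorr < 0 || withinCorr >= 1)
    abortUsage("withinCorr must lie in [0, 1)")
  if (missingRate < 0 || missingRate >= 1)
    abortUsage("missingRate must lie in [0, 1)")
  if (noiseSd <= 0) abortUsage("noiseSd must be > 0")
  if (nConditions * (1 - missingRate)^2 < 3)
    warning("expected paired count ",
            round(nConditions * (1 - missingRate)^2, 2),
            " is below 3; most correlations will be undefined",
            call. = FALSE)

  sizes <- rep(nGenes %/% nModules, nModules)
  extra <- nGenes %% nModules
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  modules <- rep(seq_len(nModules), times = sizes)

  set.seed(seed)
  latent <- matrix(rnorm(nModules * nConditions), nModules, nConditions)
  noise <- matrix(rnorm(nGenes * nConditions), nGenes, nConditions)
  values <- sqrt(withinCorr) * latent[modules, , drop = FALSE] +
    sqrt(1 - withinCorr) * noiseSd * noise
  if (missingRate > 0) {
    mask <- matrix(runif(nGenes * nConditions) < missingRate,
                   nGenes, nConditions)
    values[mask] <- NA_real_
  }
  geneIds <- sprintf("g%04d", seq_len(nGenes))
  expr <- ExpressionData(values, geneIds = geneIds,
                         conditionIds = sprintf("c%04d", seq_len(nConditions)))
  list(expr = expr, modules = stats::setNames(modules, geneIds))
}

#' Top-percentage quantiles of the null correlation vs sample size
#'
#' Manufactures the phenomenon the sliding threshold corrects for: the
#' dispersion of a Pearson correlation between independent vectors shrinks
#' roughly as \eqn{1/\sqrt{x}} with the number of paired observations, so
#' the same top-percentage quantile is far larger at small x. For each
#' requested x, `reps` independent pairs of length-x standard-normal
#' vectors are drawn and the k-th largest correlation retained,
#' `k = ceiling(cutoff * reps)`. The result is shaped as a
#' [BinQuantileTable-class] (one degenerate bin per x) ready for
#' [fitThresholdCurve()].
#'
#' @param xValues integer sample sizes, each >= 3.
#' @param reps Monte-Carlo draws per x (>= 1000 for stable tail quantiles).
#' @param cutoff top fraction, in (0, 1).
#' @param seed RNG seed.
#' @return A [BinQuantileTable-class].
#' @export
generateNullQuantiles <- function(xValues, reps = 10000L, cutoff = 0.01,
                                  seed = 42L) {
  if (any(xValues < 3)) abortUsage("every x must be >= 3")
  if (reps < 1000L) abortUsage("reps must be >= 1000 for stable quantiles")
  if (cutoff <= 0 || cutoff >= 1) abortUsage("cutoff must lie in (0, 1)")
  set.seed(seed)
  k <- ceiling(cutoff * reps)
  q <- vapply(xValues, function(x) {
    A <- matrix(rnorm(reps * x), reps, x)
    B <- matrix(rnorm(reps * x), reps, x)
    a <- A - rowMeans(A)
    b <- B - rowMeans(B)
    r <- rowSums(a * b) / sqrt(rowSums(a * a) * rowSums(b * b))
    sort(r, decreasing = TRUE)[k]
  }, numeric(1))
  bins <- data.frame(bin_low = as.integer(xValues),
                     bin_high = as.integer(xValues),
                     x_rep = as.numeric(xValues),
                     n_pairs = as.integer(reps), q_thresh = q)
  new("BinQuantileTable", binSize = 1L, cutoff = cutoff, minBinCount = 1L,
      bins = bins)
}
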