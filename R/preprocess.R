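#' Default tokens interpreted as missing values when reading expression CSVs
#' @export
DEFAULT_MISSING_TOKENS <- c("", "NA", "NaN", "nan")

#' Read an expression matrix from CSV
#'
#' Expects a comma-delimited UTF-8 file whose header row holds condition
#' identifiers and whose first column holds gene identifiers. Any cell equal
#' to one of `missingTokens` (after trimming surrounding whitespace) is
#' recorded as missing; every other cell must parse as a real number.
#'
#' @param path path to the CSV file.
#' @param missingTokens character vector of tokens to treat as missing.
#' @return An [ExpressionData-class] object with no transforms applied.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("gene,c1,c2", "gA,1,2", "gB,3,4"), f)
#' loadExpression(f)
#' @export
loadExpression <- function(path, missingTokens = DEFAULT_MISSING_TOKENS) {
  if (!file.exists(path)) abortData("input file not found: ", path)
  raw <- tryCatch(
    read.csv(path, header = TRUE, colClasses = "character",
             check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) abortData("malformed CSV '", path, "': ",
                                  conditionMessage(e)))
  if (ncol(raw) < 2L)
    abortData("malformed CSV '", path, "': need a gene-id column plus >= 1 condition column")
  geneIds <- trimws(raw[[1L]])
  condIds <- names(raw)[-1L]
  if (anyDuplicated(geneIds))
    abortData("duplicate gene id(s): ",
              paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  if (anyDuplicated(condIds))
    abortData("duplicate condition id(s): ",
              paste(unique(condIds[duplicated(condIds)]), collapse = ", "))
  tokens <- trimws(as.matrix(raw[, -1L, drop = FALSE]))
  vals <- suppressWarnings(array(as.numeric(tokens), dim = dim(tokens)))
  miss <- matrix(tokens %in% missingTokens, nrow(tokens), ncol(tokens))
  vals[miss] <- NA_real_
  bad <- which(is.na(vals) & !miss, arr.ind = TRUE)
  if (nrow(bad))
    abortData(sprintf("non-numeric cell at gene '%s', condition '%s': '%s'",
                      geneIds[bad[1L, 1L]], condIds[bad[1L, 2L]],
                      tokens[bad[1L, , drop = FALSE]]))
  ExpressionData(vals, geneIds = geneIds, conditionIds = condIds)
}

#' Write an expression matrix to CSV
#'
#' Inverse of [loadExpression()]: missing cells are written as empty fields,
#' so a write/load round trip preserves the missingness mask and reproduces
#' finite-decimal values exactly.
#'
#' @param x an [ExpressionData-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  v <- exprValues(x)
  chr <- matrix("", nrow(v), ncol(v))
  pres <- !is.na(v)
  chr[pres] <- as.character(v[pres])
  lines <- c(paste(c("GeneId", conditionIds(x)), collapse = ","),
             paste(geneIds(x), apply(chr, 1L, paste, collapse = ","), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

checkOrder <- function(x, op, forbidden) {
  seen <- intersect(transformsApplied(x), forbidden)
  if (length(seen))
    abortUsage(op, " must precede ", paste(seen, collapse = "/"),
               "; transform order is remove_zeros -> log2 -> zscore")
}

withTransform <- function(x, values, name) {
  ExpressionData(values, geneIds = geneIds(x), conditionIds = conditionIds(x),
                 transforms = c(transformsApplied(x), name))
}

#' Treat exact zeros as missing
#'
#' Marks every stored value equal to exactly 0 as missing, leaving all other
#' cells untouched. Intended for data where zeros denote non-detection
#' (e.g. RNA-seq dropout) rather than true absence of expression; rows are
#' never dropped, even if they become entirely missing. Must be applied
#' before [log2Rescale()] and [zscoreColumns()].
#'
#' @param x an [ExpressionData-class] object.
#' @return A new `ExpressionData` with `remove_zeros` recorded.
#' @export
removeZeros <- function(x) {
  checkOrder(x, "remove_zeros", c("log2", "zscore"))
  v <- exprValues(x)
  v[!is.na(v) & v == 0] <- NA_real_
  withTransform(x, v, "remove_zeros")
}

#' Rescale expression values by log2
#'
#' Replaces each non-missing value v by log2(v). No pseudocount is added:
#' values <= 0 are a hard error, so zero-inflated data must go through
#' [removeZeros()] first.
#'
#' @param x an [ExpressionData-class] object with all non-missing values > 0.
#' @return A new `ExpressionData` with `log2` recorded.
#' @export
log2Rescale <- function(x) {
  checkOrder(x, "log2", c("log2", "zscore"))
  v <- exprValues(x)
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    abortData(sprintf(
      "log2 undefined for value %g at gene '%s', condition '%s' (run removeZeros first?)",
      v[bad[1L, , drop = FALSE]], geneIds(x)[bad[1L, 1L]],
      conditionIds(x)[bad[1L, 2L]]))
  v[!is.na(v)] <- log2(v[!is.na(v)])
  withTransform(x, v, "log2")
}

#' Z-score each condition column
#'
#' Per column, the non-missing entries are centred by their mean and scaled
#' by their sample standard deviation (denominator n - 1). Degenerate
#' columns — fewer than two observed entries, or zero variance — cannot be
#' standardised; they are set entirely missing and reported in a single
#' warning.
#'
#' @param x an [ExpressionData-class] object.
#' @return A new `ExpressionData` with `zscore` recorded.
#' @export
zscoreColumns <- function(x) {
  v <- exprValues(x)
  degenerate <- character()
  for (j in seq_len(ncol(v))) {
    obs <- !is.na(v[, j])
    s <- if (sum(obs) >= 2L) sd(v[obs, j]) else 0
    if (sum(obs) < 2L || s == 0) {
      v[, j] <- NA_real_
      degenerate <- c(degenerate, conditionIds(x)[j])
    } else {
      v[obs, j] <- (v[obs, j] - mean(v[obs, j])) / s
    }
  }
  if (length(degenerate))
    warning("z-score: degenerate column(s) set to missing: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  withTransform(x, v, "zscore")
}

#' Apply the standard transform pipeline
#'
#' Convenience wrapper applying, in the enforced order, any of
#' [removeZeros()], [log2Rescale()] and [zscoreColumns()].
#'
#' @param x an [ExpressionData-class] object.
#' @param removeZeros,log2,zscore logical flags.
#' @return The transformed `ExpressionData`.
#' @export
applyTransforms <- function(x, removeZeros = FALSE, log2 = FALSE,
                            zscore = FALSE) {
  if (removeZeros) x <- removeZeros(x)
  if (log2) x <- log2Rescale(x)
  if (zscore) x <- zscoreColumns(x)
  x
}
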