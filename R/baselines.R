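# Comparator normalizers: per-sample z-score, average-difference scaling to a
# common global mean, and quantile normalization (via limma, whose tie policy
# - tied entries receive the mean of the reference values across their tied
# ranks - is the established convention).

#' Z-score normalization (per sample)
#'
#' Centers and scales every sample (column) to mean 0 and unit sample
#' standard deviation (n - 1 denominator).
#'
#' @param matrix An [expression_matrix()].
#' @return The standardized `expression_matrix`.
#' @export
zscore_normalize <- function(matrix) {
  matrix <- as_expression_matrix(matrix)
  sds <- apply(unclass(matrix), 2, stats::sd)
  if (any(sds == 0)) {
    abort_validation(sprintf("degenerate column: sample '%s' is constant",
                             colnames(matrix)[which(sds == 0)[1]]))
  }
  out <- matrix
  out[] <- scale(unclass(matrix))
  out
}

#' Average-difference scaling
#'
#' Rescales each data source by a single multiplicative factor so every
#' source's global mean equals the grand mean of all inputs; within-source
#' value ratios are unchanged. Defined for log-like intensity data with a
#' positive global mean.
#'
#' @param matrices List of [expression_matrix()] objects (a single matrix is
#'   accepted and returned unchanged up to numerical identity).
#' @return List of rescaled matrices, same names and order.
#' @export
avgdiff_normalize <- function(matrices) {
  if (inherits(matrices, "expression_matrix")) matrices <- list(matrices)
  if (length(matrices) == 0L) abort_validation("avgdiff_normalize: no input matrices")
  matrices <- lapply(matrices, as_expression_matrix)
  means <- vapply(matrices, function(m) mean(unclass(m)), numeric(1))
  if (any(means <= 0)) {
    abort_validation("avgdiff_normalize: a source has non-positive global mean; scaling undefined")
  }
  total_n <- vapply(matrices, length, numeric(1))
  grand <- sum(means * total_n) / sum(total_n)
  lapply(matrices, function(m) { m[] <- unclass(m) * (grand / mean(unclass(m))); m })
}

#' Quantile normalization across pooled samples
#'
#' All samples from all sources are pooled into one probes x samples table and
#' forced onto the common reference distribution: each column's sorted values
#' are replaced by the per-rank mean of all sorted columns. Tied entries
#' receive the mean of the reference values at their tied ranks.
#'
#' @param matrices List of [expression_matrix()] objects sharing the probe
#'   count.
#' @return List of normalized matrices, same shapes and identifiers.
#' @export
quantile_normalize <- function(matrices) {
  if (inherits(matrices, "expression_matrix")) matrices <- list(matrices)
  if (length(matrices) == 0L) abort_validation("quantile_normalize: no input matrices")
  matrices <- lapply(matrices, as_expression_matrix)
  P <- vapply(matrices, nrow, integer(1))
  if (length(unique(P)) != 1L) {
    abort_validation(sprintf("quantile_normalize: probe counts differ (%s)",
                             paste(P, collapse = ", ")))
  }
  pooled <- do.call(cbind, lapply(matrices, unclass))
  normed <- limma::normalizeQuantiles(pooled, ties = TRUE)
  offsets <- c(0L, cumsum(vapply(matrices, ncol, integer(1))))
  out <- lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    m[] <- normed[, (offsets[i] + 1L):offsets[i + 1L], drop = FALSE]
    m
  })
  names(out) <- names(matrices)
  out
}
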