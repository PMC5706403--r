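# Evaluation statistics: binned Kullback-Leibler divergence between value
# pools, six-number summaries, and MA-plot statistics.

#' Kullback-Leibler divergence between two value pools
#'
#' `D(P || Q) = sum_i p_i ln(p_i / q_i)` in nats, over a shared set of equal
#' width bins spanning the union of both pools' ranges. Every bin mass gets
#' `eps` added and is renormalized, so empty bins contribute finitely (the
#' divergence is 0 exactly when the smoothed histograms coincide).
#'
#' The divergence is asymmetric: `kl_divergence(p, q)` and
#' `kl_divergence(q, p)` differ in general; report both when needed.
#'
#' @param pool_p,pool_q [value_pool()] objects (or numeric vectors).
#' @param n_bins Number of shared bins (default 100).
#' @param eps Smoothing mass added to every bin (default 1e-10).
#' @return Non-negative divergence in nats.
#' @examples
#' p <- c(rep(1, 5), rep(3, 5))  # half/half
#' q <- c(rep(1, 9), 3)          # 0.9/0.1
#' kl_divergence(p, q, n_bins = 2)  # ~0.5108
#' @export
kl_divergence <- function(pool_p, pool_q, n_bins = 100L, eps = 1e-10) {
  pool_p <- as_value_pool(pool_p); pool_q <- as_value_pool(pool_q)
  if (!is.numeric(n_bins) || n_bins < 1) abort_validation("n_bins must be a positive integer")
  r <- range(c(as.numeric(pool_p), as.numeric(pool_q)))
  edges <- seq(r[1], r[2], length.out = n_bins + 1L)
  smoothed <- function(v) {
    idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    m <- tabulate(idx, nbins = n_bins) / length(v) + eps
    m / sum(m)
  }
  p <- smoothed(as.numeric(pool_p)); q <- smoothed(as.numeric(pool_q))
  sum(p * log(p / q))
}

#' Six-number summary of a value pool
#'
#' Minimum, lower quartile, median, mean, upper quartile and maximum.
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7, the common default), which the quartile
#' columns of any cross-method comparison table depend on.
#'
#' @param pool A [value_pool()] or numeric vector (a single finite value is
#'   allowed here, unlike for fitting).
#' @return Named numeric vector `Min.`, `1st Qu.`, `Median`, `Mean`,
#'   `3rd Qu.`, `Max.`.
#' @export
summary_stats <- function(pool) {
  x <- if (inherits(pool, "value_pool")) as.numeric(pool) else pool
  if (length(x) == 0L) abort_validation("summary_stats: empty pool")
  if (!is.numeric(x) || any(!is.finite(x))) abort_validation("summary_stats: non-finite values")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c("Min." = min(x), "1st Qu." = qs[1], "Median" = qs[2], "Mean" = mean(x),
    "3rd Qu." = qs[3], "Max." = max(x))
}

#' MA statistics for a pair of samples
#'
#' Per feature, `M = log2(x) - log2(y)` (the log ratio) and
#' `A = (log2(x) + log2(y)) / 2` (the mean log intensity). Well-normalized
#' sample pairs center M at 0. When the data is already on a log scale (as
#' summarized expression values usually are), set `already_log = TRUE` and
#' the logarithm is skipped.
#'
#' @param sample_x,sample_y Equal-length numeric vectors.
#' @param already_log If `FALSE` (default) values must be positive raw
#'   intensities and are log2-transformed first.
#' @return List with `M`, `A`, `median_M` and `IQR_M`.
#' @examples
#' ma_statistics(8, 2)$M  # 2
#' @export
ma_statistics <- function(sample_x, sample_y, already_log = FALSE) {
  if (length(sample_x) != length(sample_y)) {
    abort_validation("ma_statistics: samples must have equal length")
  }
  if (length(sample_x) == 0L) abort_validation("ma_statistics: empty samples")
  if (!already_log && (any(sample_x <= 0) || any(sample_y <= 0))) {
    abort_validation("ma_statistics: raw intensities must be positive (or set already_log = TRUE)")
  }
  lx <- if (already_log) sample_x else log2(sample_x)
  ly <- if (already_log) sample_y else log2(sample_y)
  M <- lx - ly
  A <- (lx + ly) / 2
  list(M = M, A = A, median_M = stats::median(M), IQR_M = stats::IQR(M))
}

#' Before/after normalization report for one source against a target
#'
#' Bundles the paper-style evaluation of a normalization run: six-number
#' summaries of the source before and after and of the target, KL divergence
#' of the source pool against the target pool before and after, and MA
#' statistics (computed between the per-probe mean profiles of source and
#' target, which requires a shared probe set).
#'
#' @param source_before,source_after,target [expression_matrix()] objects;
#'   `source_before`/`source_after` must share dimensions, and MA statistics
#'   need `target` to share the probe count.
#' @param n_bins Bins for the KL divergence (default 100).
#' @param already_log Passed to [ma_statistics()] (default `TRUE`: expression
#'   values are assumed pre-logged).
#' @return A `normalization_report` list.
#' @export
normalization_report <- function(source_before, source_after, target,
                                 n_bins = 100L, already_log = TRUE) {
  source_before <- as_expression_matrix(source_before)
  source_after <- as_expression_matrix(source_after)
  target <- as_expression_matrix(target)
  if (!all(dim(source_before) == dim(source_after))) {
    abort_validation("normalization_report: before/after matrices differ in shape")
  }
  pb <- as.vector(unclass(source_before)); pa <- as.vector(unclass(source_after))
  pt <- as.vector(unclass(target))
  ma_b <- ma_a <- NULL
  if (nrow(source_before) == nrow(target)) {
    prof_t <- rowMeans(unclass(target))
    ma_b <- ma_statistics(rowMeans(unclass(source_before)), prof_t, already_log = already_log)
    ma_a <- ma_statistics(rowMeans(unclass(source_after)), prof_t, already_log = already_log)
  }
  structure(list(
    per_source_summary = list(before = summary_stats(pb), after = summary_stats(pa),
                              target = summary_stats(pt)),
    kl_before = kl_divergence(pb, pt, n_bins = n_bins),
    kl_after = kl_divergence(pa, pt, n_bins = n_bins),
    ma_median_before = if (is.null(ma_b)) NA_real_ else ma_b$median_M,
    ma_median_after = if (is.null(ma_a)) NA_real_ else ma_a$median_M,
    ma_iqr_before = if (is.null(ma_b)) NA_real_ else ma_b$IQR_M,
    ma_iqr_after = if (is.null(ma_a)) NA_real_ else ma_a$IQR_M
  ), class = "normalization_report")
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("normalization_report\n")
  cat(sprintf("  KL vs target: %.4g before -> %.4g after\n", x$kl_before, x$kl_after))
  if (!is.na(x$ma_median_before)) {
    cat(sprintf("  MA median: %.4g -> %.4g, IQR: %.4g -> %.4g\n",
                x$ma_median_before, x$ma_median_after, x$ma_iqr_before, x$ma_iqr_after))
  }
  stats <- do.call(rbind, x$per_source_summary)
  print(round(stats, 4))
  invisible(x)
}
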