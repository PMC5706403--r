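# Core probability-integral transform: cumulative probability under a fitted
# density, its inverse, and the value mapping that equates cumulative
# probabilities between a source and a target distribution.

# Vectorized CDF evaluation. Analytic families use their closed form; fitted
# families interpolate the precomputed monotone grid. Values beyond the
# support evaluate to 0 / 1.
cdf_values <- function(model, x) {
  if (is_analytic(model)) {
    analytic_cdf_fun(model$family, model$coefficients, model$support)(x)
  } else {
    approx(model$grid_x, model$cdf_grid, x, yleft = 0, yright = 1, ties = "ordered")$y
  }
}

#' Cumulative probability of a value under a fitted density
#'
#' The probability that a value drawn from the fitted distribution is at most
#' `x`: the integral of the density from the lower support bound to `x`.
#' Values below the support give 0, above it 1.
#'
#' @param model A `density_model`.
#' @param x Numeric vector of values.
#' @return Cumulative probabilities in `[0, 1]`, non-decreasing in `x`.
#' @seealso [inverse_cdf()], [dbnorm_map()]
#' @export
cdf <- function(model, x) {
  check_model(model)
  if (!is.numeric(x) || any(!is.finite(x))) abort_validation("cdf: x must be finite numeric")
  cdf_values(model, x)
}

#' Quantile (inverse CDF) of a fitted density
#'
#' Returns the value in the support whose cumulative probability equals `p`.
#' Inversion is by bisection against the monotone CDF, which converges to the
#' left endpoint of any flat (zero-density) stretch - a deterministic,
#' documented tie-break.
#'
#' @param model A `density_model`.
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return Values in the support, non-decreasing in `p`.
#' @export
inverse_cdf <- function(model, p) {
  check_model(model)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort_validation("inverse_cdf: p must be in [0, 1]")
  }
  invert_cdf(model, p)
}

# Vector bisection for the smallest x with F(x) >= p; 60 halvings take the
# bracket below 1e-15 of the support width.
invert_cdf <- function(model, p) {
  lo <- rep(model$support[1], length(p))
  hi <- rep(model$support[2], length(p))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    ge <- cdf_values(model, mid) >= p
    hi[ge] <- mid[ge]
    lo[!ge] <- mid[!ge]
  }
  out <- (lo + hi) / 2
  out[p <= 0] <- model$support[1]
  out[p >= 1] <- model$support[2]
  out
}

check_model <- function(model) {
  if (!inherits(model, "density_model")) {
    abort_validation("expected a density_model (see fit_density / make_analytic_model)")
  }
  invisible(model)
}

#' Map values from a source distribution onto a target distribution
#'
#' The distribution-based normalization transform: each value `m` is mapped to
#' the target value `m'` of equal cumulative probability,
#' `m' = G^{-1}(F(m))` with `F` the source CDF and `G` the target CDF. The
#' mapping is monotone, so the rank order of the values (including ties) is
#' unchanged; only the values themselves move.
#'
#' Values outside the source support are clamped to it first, and cumulative
#' probabilities are clamped to the interior `[eps, 1 - eps]` before
#' inversion so extreme values map to finite support points; the number of
#' values affected is reported.
#'
#' @param values Finite numeric vector.
#' @param source_model `density_model` fitted to the source distribution.
#' @param target_model `density_model` of the target distribution.
#' @param eps Interior clamp for cumulative probabilities (default 1e-9).
#' @return A `transform_result`: list with `mapped_values` (aligned with the
#'   input), `clamped_count`, and `max_probability_gap`
#'   (`max |F_src(m) - F_tgt(m')|` over the mapped values).
#' @examples
#' src <- make_analytic_model("gaussian", c(0, 1))
#' tgt <- make_analytic_model("gaussian", c(5, 2))
#' dbnorm_map(c(-1, 0, 1), src, tgt)$mapped_values  # 3, 5, 7
#' @export
dbnorm_map <- function(values, source_model, target_model, eps = 1e-9) {
  check_model(source_model); check_model(target_model)
  if (length(values) == 0L) abort_validation("dbnorm_map: empty input")
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort_validation("dbnorm_map: values must be finite numeric")
  }
  clamped_values <- pmin(pmax(values, source_model$support[1]), source_model$support[2])
  n_outside <- sum(clamped_values != values)
  if (n_outside > 0) {
    dn_log("debug", "%d values outside source support clamped", n_outside)
  }
  p <- cdf_values(source_model, clamped_values)
  p_int <- pmin(pmax(p, eps), 1 - eps)
  clamped_count <- sum(p_int != p) + n_outside
  mapped <- invert_cdf(target_model, p_int)
  gap <- max(abs(cdf_values(target_model, mapped) - p_int))
  structure(list(mapped_values = mapped, clamped_count = as.integer(clamped_count),
                 max_probability_gap = gap),
            class = "transform_result")
}

#' @export
print.transform_result <- function(x, ...) {
  cat(sprintf("transform_result: %d values, %d clamped, max probability gap %.3g\n",
              length(x$mapped_values), x$clamped_count, x$max_probability_gap))
  invisible(x)
}

#' Normalize an expression matrix onto a target distribution
#'
#' Applies [dbnorm_map()] to every entry of the matrix, preserving shape and
#' probe/sample identifiers. If both the matrix and the source model carry a
#' `source_id`, they must agree.
#'
#' @param matrix An [expression_matrix()].
#' @param source_model Model fitted to this matrix's pooled values.
#' @param target_model Model of the desired distribution.
#' @param eps Interior clamp passed to [dbnorm_map()].
#' @return The normalized `expression_matrix`; attributes `clamped_count` and
#'   `max_probability_gap` carry the transform diagnostics.
#' @export
normalize_matrix <- function(matrix, source_model, target_model, eps = 1e-9) {
  matrix <- as_expression_matrix(matrix)
  check_model(source_model); check_model(target_model)
  mid <- attr(matrix, "source_id")
  if (!is.null(mid) && !is.null(source_model$source_id) && mid != source_model$source_id) {
    abort_validation(sprintf(
      "source mismatch: matrix is from '%s' but the source model was fitted to '%s'",
      mid, source_model$source_id))
  }
  res <- dbnorm_map(as.vector(unclass(matrix)), source_model, target_model, eps = eps)
  out <- matrix
  out[] <- res$mapped_values
  attr(out, "clamped_count") <- res$clamped_count
  attr(out, "max_probability_gap") <- res$max_probability_gap
  out
}

#' Pick the target source for normalization
#'
#' When no target is specified, the convention is to normalize everything onto
#' the largest data source. "Largest" defaults to the number of samples
#' (columns); counting probes (rows) is also selectable since sources sharing
#' a probe set tie on rows.
#'
#' @param matrices Named list of [expression_matrix()] objects.
#' @param by `"samples"` (default) or `"probes"`.
#' @return The name (or index, if unnamed) of the chosen target.
#' @export
choose_target <- function(matrices, by = c("samples", "probes")) {
  by <- match.arg(by)
  if (length(matrices) == 0L) abort_validation("choose_target: no matrices given")
  sizes <- vapply(matrices, function(m) if (by == "samples") ncol(m) else nrow(m), integer(1))
  pick <- which.max(sizes)
  if (!is.null(names(matrices))) names(matrices)[pick] else pick
}

#' One-call multi-source normalization pipeline
#'
#' Pools each source, builds its histogram, fits the requested density family,
#' and maps every non-target source onto the target distribution. The target
#' may be one of the sources (chosen automatically as the largest when
#' `target = "auto"`) or an analytic reference distribution.
#'
#' @param matrices Named list of [expression_matrix()] objects, one per source.
#' @param target `"auto"`, the name of one of `matrices`, or a `density_model`
#'   (e.g. from [make_analytic_model()]).
#' @param family,order,n_bins,n_grid Fitting parameters (see [fit_density()]).
#' @param eps Interior probability clamp (see [dbnorm_map()]).
#' @return List with `normalized` (named list of matrices; the target source,
#'   if any, is passed through unchanged), `models` (fitted per source),
#'   `target_model` and `target_name` (`NA` for an analytic target).
#' @examples
#' sim <- simulate_platforms(100, westmead_like_preset(1)[1:2])
#' res <- dbnorm_normalize(sim$matrices, target = "auto")
#' res$target_name
#' @export
dbnorm_normalize <- function(matrices, target = "auto",
                             family = c("fourier", "polynomial", "gaussian"),
                             order = NULL, n_bins = NULL, n_grid = 8193L, eps = 1e-9) {
  family <- match.arg(family)
  if (length(matrices) == 0L) abort_validation("no input matrices")
  matrices <- lapply(matrices, as_expression_matrix)
  if (is.null(names(matrices))) names(matrices) <- paste0("source", seq_along(matrices))

  models <- lapply(names(matrices), function(nm) {
    pool <- as_value_pool(matrices[[nm]], source_id = nm)
    fit_density(build_histogram(pool, n_bins = n_bins), family = family,
                order = order, n_grid = n_grid)
  })
  names(models) <- names(matrices)

  if (inherits(target, "density_model")) {
    target_model <- target
    target_name <- NA_character_
  } else {
    target_name <- if (identical(target, "auto")) choose_target(matrices) else target
    if (!target_name %in% names(matrices)) {
      abort_validation(sprintf("target '%s' is not among the input sources", target_name))
    }
    target_model <- models[[target_name]]
  }
  dn_log("info", "normalizing %d sources onto target '%s' (family %s)",
         length(matrices), target_name, family)

  normalized <- lapply(names(matrices), function(nm) {
    if (!is.na(target_name) && nm == target_name) return(matrices[[nm]])
    normalize_matrix(matrices[[nm]], models[[nm]], target_model, eps = eps)
  })
  names(normalized) <- names(matrices)
  list(normalized = normalized, models = models,
       target_model = target_model, target_name = target_name)
}
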