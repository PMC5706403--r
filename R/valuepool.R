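#' Pool of intensity values from one data source
#'
#' A value pool is the flattened collection of expression intensities from one
#' platform or data source, the unit on which distribution fitting operates.
#' By default all samples of a source are pooled into a single vector.
#'
#' @param values Numeric vector of intensities (log-like scale).
#' @param source_id Optional identifier of the originating matrix/platform.
#' @param nonfinite One of `"drop"` (default; NA/NaN/Inf entries are removed
#'   and their count logged) or `"reject"` (any non-finite entry is an error).
#' @return An object of class `value_pool`: a numeric vector with a
#'   `source_id` attribute.
#' @examples
#' p <- value_pool(rnorm(100, 6.5, 2), source_id = "U133A")
#' length(p)
#' @export
value_pool <- function(values, source_id = NULL, nonfinite = c("drop", "reject")) {
  nonfinite <- match.arg(nonfinite)
  if (!is.numeric(values)) {
    abort_validation("value pool must be numeric")
  }
  values <- as.numeric(values)
  bad <- !is.finite(values)
  if (any(bad)) {
    if (nonfinite == "reject") {
      abort_validation(sprintf("value pool contains %d non-finite entries and policy is 'reject'",
                               sum(bad)))
    }
    dn_log("debug", "dropped %d non-finite values from pool%s", sum(bad),
           if (is.null(source_id)) "" else paste0(" '", source_id, "'"))
    values <- values[!bad]
  }
  if (length(unique(values)) < 2L) {
    abort_validation("value pool must contain at least 2 distinct finite values")
  }
  structure(values, source_id = source_id, class = c("value_pool", "numeric"))
}

as_value_pool <- function(x, source_id = NULL, nonfinite = "drop") {
  if (inherits(x, "value_pool")) return(x)
  if (inherits(x, "expression_matrix") || is.matrix(x)) {
    if (is.null(source_id)) source_id <- attr(x, "source_id")
    return(value_pool(as.vector(unclass(x)), source_id = source_id, nonfinite = nonfinite))
  }
  value_pool(x, source_id = source_id, nonfinite = nonfinite)
}

#' @export
print.value_pool <- function(x, ...) {
  cat(sprintf("value_pool: %d values%s, range [%.4g, %.4g]\n",
              length(x),
              if (is.null(attr(x, "source_id"))) "" else
                paste0(" from '", attr(x, "source_id"), "'"),
              min(x), max(x)))
  invisible(x)
}
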