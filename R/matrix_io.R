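#' Expression matrix container
#'
#' A probesets x samples numeric matrix with unique row (probe) and column
#' (sample) identifiers, the object every normalizer consumes. Implemented as
#' a plain numeric matrix with a class attribute, so all matrix operations
#' keep working.
#'
#' @param values Numeric matrix, probes in rows, samples in columns.
#' @param probe_ids,sample_ids Identifier vectors; default to existing
#'   dimnames or generated `probe_i` / `sample_j`.
#' @param source_id Optional identifier of the platform/data source.
#' @param nonfinite `"reject"` (default: any non-finite value is an error) or
#'   `"drop"` is not meaningful for matrices, so non-finite entries always
#'   reject.
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_ids = NULL, sample_ids = NULL,
                              source_id = NULL, nonfinite = "reject") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_validation("expression_matrix: values must be a numeric matrix")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    abort_validation("expression_matrix: needs at least one probe and one sample")
  }
  if (any(!is.finite(values))) {
    abort_validation(sprintf("expression_matrix: %d non-finite values present",
                             sum(!is.finite(values))))
  }
  probe_ids <- as.character(probe_ids %||% rownames(values) %||% paste0("probe_", seq_len(nrow(values))))
  sample_ids <- as.character(sample_ids %||% colnames(values) %||% paste0("sample_", seq_len(ncol(values))))
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    abort_validation("expression_matrix: identifier lengths do not match dimensions")
  }
  if (anyDuplicated(probe_ids)) {
    abort_validation(sprintf("duplicate probe id: '%s'", probe_ids[duplicated(probe_ids)][1]))
  }
  if (anyDuplicated(sample_ids)) {
    abort_validation(sprintf("duplicate sample id: '%s'", sample_ids[duplicated(sample_ids)][1]))
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(values, source_id = source_id, class = c("expression_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_expression_matrix <- function(x, source_id = NULL) {
  if (inherits(x, "expression_matrix")) return(x)
  if (!is.matrix(x)) abort_validation("expected an expression matrix")
  expression_matrix(x, source_id = source_id %||% attr(x, "source_id"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples%s\n", nrow(x), ncol(x),
              if (is.null(attr(x, "source_id"))) "" else
                paste0(" from '", attr(x, "source_id"), "'")))
  if (nrow(x) > 6L || ncol(x) > 6L) {
    print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
    cat("...\n")
  } else {
    print(unclass(x))
  }
  invisible(x)
}

#' Read a delimited expression matrix
#'
#' Layout contract: first row holds sample identifiers, first column holds
#' probe identifiers, remaining cells are numeric intensities. Duplicate
#' identifiers and ragged rows are rejected.
#'
#' @param path File path.
#' @param delimiter Field separator (default tab).
#' @param source_id Optional source identifier attached to the result.
#' @param nonfinite `"reject"` (default) errors on non-numeric cells; `"drop"`
#'   is rejected for matrices since entries cannot be removed without breaking
#'   the rectangle.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, delimiter = "\t", source_id = NULL, nonfinite = "reject") {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  fields <- utils::count.fields(path, sep = delimiter, quote = "\"", comment.char = "")
  if (length(fields) < 2L) abort_io(sprintf("parse error in %s: no data rows", path))
  if (length(unique(fields)) != 1L) {
    abort_io(sprintf("parse error in %s: ragged row at line %d (%d fields, expected %d)",
                     path, which(fields != fields[1])[1], fields[fields != fields[1]][1],
                     fields[1]))
  }
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, sep = delimiter, header = TRUE, data.table = FALSE,
                        check.names = FALSE, colClasses = list(character = 1))),
    error = function(e) abort_io(sprintf("parse error in %s: %s", path, conditionMessage(e))))
  if (ncol(dt) < 2L) abort_io(sprintf("parse error in %s: no sample columns", path))
  probe_ids <- dt[[1L]]
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(vals, 2, as.numeric))), arr.ind = TRUE)
    abort_validation(sprintf("non-numeric cell at data row %d, column '%s'",
                             bad[1, 1], colnames(vals)[bad[1, 2]]))
  }
  m <- expression_matrix(vals, probe_ids = probe_ids, sample_ids = colnames(vals),
                         source_id = source_id, nonfinite = nonfinite)
  dn_log("debug", "read %d x %d matrix from %s", nrow(m), ncol(m), path)
  m
}

#' Write an expression matrix as delimited text
#'
#' Values are printed with `%.17g`, which round-trips IEEE doubles exactly:
#' `read_matrix(write_matrix(m, f))` reproduces `m` bit for bit.
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, delimiter = "\t") {
  matrix <- as_expression_matrix(matrix)
  header <- paste(c("probe_id", colnames(matrix)), collapse = delimiter)
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], sprintf("%.17g", unclass(matrix)[i, ])),
          collapse = delimiter)
  }, character(1))
  ok <- tryCatch({ writeLines(c(header, body), path); TRUE },
                 error = function(e) abort_io(sprintf("cannot write %s: %s",
                                                      path, conditionMessage(e))))
  dn_log("debug", "wrote %d x %d matrix to %s", nrow(matrix), ncol(matrix), path)
  invisible(path)
}
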