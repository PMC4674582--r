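# Evaluation statistics over benchmark complex sets: energy ranges,
# Pearson correlations with experiment, and consistency of the binding
# decomposition.

#' Energy range of a set of values
#'
#' The difference between the highest and lowest energies across the
#' complexes of a benchmark set.
#'
#' @param values Numeric vector, kcal/mol, length at least 2.
#' @return `max - min`, kcal/mol.
#' @export
energy_range <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("energy_range needs at least 2 values")
  if (anyNA(values)) stop("missing values in energy_range input")
  max(values) - min(values)
}

#' Pearson correlation between experimental and calculated energies
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   non-zero variance.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("pearson needs at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in pearson input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Summarize a per-complex binding-energy table
#'
#' For every target-function column of the table, computes its energy
#' range over the complexes and its Pearson correlation with the
#' experimental binding energies, i.e. the two summary rows printed at the
#' bottom of a benchmark table.
#'
#' @param records Data frame with one row per complex, a `dG_exp` column,
#'   and one numeric column per target function (any extra `pdb_id` /
#'   `protein` label columns are ignored).
#' @return An object of class `evaluation_summary` with named numeric
#'   vectors `ranges` (including `dG_exp` itself) and `correlations`
#'   (each function column vs `dG_exp`).
#' @export
summarize_binding_table <- function(records) {
  records <- as.data.frame(records)
  if (!"dG_exp" %in% names(records))
    stop("records must contain a 'dG_exp' column")
  num_cols <- names(records)[vapply(records, is.numeric, TRUE)]
  fun_cols <- setdiff(num_cols, "dG_exp")
  if (length(fun_cols) == 0L) stop("no target-function columns found")
  for (cl in c("dG_exp", fun_cols)) {
    if (anyNA(records[[cl]]))
      stop("missing values in column '", cl, "'")
  }
  ranges <- vapply(c("dG_exp", fun_cols),
                   function(cl) energy_range(records[[cl]]), 0)
  correlations <- vapply(fun_cols,
                         function(cl) pearson(records$dG_exp, records[[cl]]),
                         0)
  structure(list(ranges = ranges, correlations = correlations),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("<evaluation_summary>\n  Energy range (kcal/mol):\n")
  print(round(x$ranges, 2))
  cat("  Pearson correlation with dG_exp:\n")
  print(round(x$correlations, 2))
  invisible(x)
}

#' Consistency of binding-energy decompositions
#'
#' Checks the identity `dG_bind = dE + dG_v + dG_t + dG_r + dG_all` on a
#' table of decomposition rows and returns the worst violation.
#'
#' @param rows A data frame with columns `dG_bind`, `dE`, `dG_v`, `dG_t`,
#'   `dG_r`, `dG_all`, or a list of [binding_breakdown()] objects.
#' @return Maximum absolute residual over the rows, kcal/mol.
#' @export
breakdown_consistency <- function(rows) {
  if (is.list(rows) && length(rows) > 0L &&
      inherits(rows[[1L]], "binding_breakdown")) {
    rows <- do.call(rbind, lapply(rows, function(b)
      data.frame(dG_bind = b$dG_bind, dE = b$dE, dG_v = b$dG_v,
                 dG_t = b$dG_t, dG_r = b$dG_r, dG_all = b$dG_all)))
  }
  rows <- as.data.frame(rows)
  need <- c("dG_bind", "dE", "dG_v", "dG_t", "dG_r", "dG_all")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0L)
    stop("missing component column(s): ", paste(miss, collapse = ", "))
  resid <- rows$dG_bind -
    (rows$dE + rows$dG_v + rows$dG_t + rows$dG_r + rows$dG_all)
  max(abs(resid))
}
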