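#' Expression tables
#'
#' Throughout the package an expression table is a wide tibble with one row
#' per probe: a `probe_id` column, a `gene_symbol` column, and one numeric
#' column per sample holding log2-scale intensities. Sample-to-group
#' assignments live in a separate two-column tibble (`sample`, `group`),
#' mirroring the on-disk TSV layout (see [read_expression_tsv()]).
#'
#' @param expr An expression tibble.
#' @return `expr_matrix()` returns the numeric probes-by-samples matrix with
#'   probe ids as row names; `sample_names()` the sample column names.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 1))
#' m <- expr_matrix(sim$expr)
#' dim(m)
#' @export
expr_matrix <- function(expr) {
  check_expression(expr)
  m <- as.matrix(expr[sample_names(expr)])
  rownames(m) <- expr$probe_id
  m
}

#' @rdname expr_matrix
#' @export
sample_names <- function(expr) {
  setdiff(names(expr), c("probe_id", "gene_symbol"))
}

# Validate the expression-table contract: required columns, unique ids,
# numeric sample columns, no missing values.
check_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr)) {
    abort(sprintf("`%s` must be a data frame of probes x samples.", arg))
  }
  if (!all(c("probe_id", "gene_symbol") %in% names(expr))) {
    abort(sprintf("`%s` must have `probe_id` and `gene_symbol` columns.", arg))
  }
  samp <- setdiff(names(expr), c("probe_id", "gene_symbol"))
  if (length(samp) < 1L) {
    abort(sprintf("`%s` has no sample columns.", arg))
  }
  if (anyDuplicated(expr$probe_id)) {
    abort(sprintf("duplicate probe ids in `%s`: %s", arg,
                  paste(head(unique(expr$probe_id[duplicated(expr$probe_id)]), 3L),
                        collapse = ", ")))
  }
  vals <- expr[samp]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort(sprintf("all sample columns of `%s` must be numeric.", arg))
  }
  if (anyNA(vals)) {
    abort(sprintf("`%s` contains missing intensity values; impute or drop before analysis.", arg))
  }
  invisible(expr)
}

# Resolve sample groups against the expression columns. Returns a list with
# the control/treated sample names in expression-column order.
check_groups <- function(expr, groups, control = NULL, treated = NULL) {
  if (!is.data.frame(groups) || !all(c("sample", "group") %in% names(groups))) {
    abort("`groups` must be a data frame with `sample` and `group` columns.")
  }
  samp <- sample_names(expr)
  missing <- setdiff(samp, groups$sample)
  if (length(missing) > 0L) {
    abort(sprintf("samples missing from `groups`: %s", paste(missing, collapse = ", ")))
  }
  grp <- setNames(as.character(groups$group), groups$sample)[samp]
  lev <- unique(grp)
  if (length(lev) != 2L) {
    abort(sprintf("exactly two groups are required, found %d (%s).",
                  length(lev), paste(lev, collapse = ", ")))
  }
  if (is.null(control) && is.null(treated)) {
    # prefer the conventional labels, otherwise first-seen group is control
    if ("control" %in% lev) {
      control <- "control"
    } else {
      control <- lev[1L]
    }
  }
  if (is.null(treated)) treated <- setdiff(lev, control)
  if (is.null(control)) control <- setdiff(lev, treated)
  if (!control %in% lev || !treated %in% lev || control == treated) {
    abort(sprintf("`control`/`treated` must name the two groups (%s).",
                  paste(lev, collapse = ", ")))
  }
  list(
    control = samp[grp == control], treated = samp[grp == treated],
    control_label = control, treated_label = treated
  )
}
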