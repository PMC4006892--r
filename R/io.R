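#' Read and write the pipeline's tab-separated formats
#'
#' The on-disk formats are plain TSV:
#' * expression — `probe_id`, `gene_symbol`, then one numeric column per
#'   sample (header row carries sample names);
#' * groups — two columns `sample`, `group`;
#' * qPCR — four columns `sample_id`, `group`, `target`, `ct`;
#' * gene sets — GMT: per line, set name, description, then member genes,
#'   tab-separated.
#'
#' Readers validate on load: empty files, duplicate probe/sample identifiers,
#' non-numeric or missing intensities, and malformed GMT lines (fewer than
#' three fields) are errors that name the offending line or identifier.
#' `write_*` then `read_*` reproduces the object.
#'
#' @param path File path.
#' @return `read_expression_tsv()` an expression tibble;
#'   `read_groups_tsv()` a sample/group tibble; `read_qpcr_tsv()` a Ct
#'   tibble; `read_gmt()` a long tibble with `set`, `description`, `gene`.
#'   Writers return `path` invisibly.
#' @name pipeline_io
NULL

read_tsv_strict <- function(path, col_types = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) abort(sprintf("empty input file: %s", path))
  x <- readr::read_tsv(path, col_types = col_types, progress = FALSE,
                       show_col_types = FALSE)
  pr <- readr::problems(x)
  if (nrow(pr) > 0L) {
    abort(sprintf("malformed rows in %s (first at line %d: %s)",
                  path, pr$row[1] + 1L, pr$expected[1]))
  }
  if (nrow(x) == 0L) abort(sprintf("no data rows in %s", path))
  x
}

#' @rdname pipeline_io
#' @export
read_expression_tsv <- function(path) {
  x <- read_tsv_strict(path)
  check_expression(x, arg = path)
  if (anyDuplicated(sample_names(x))) {
    abort(sprintf("duplicate sample columns in %s", path))
  }
  x
}

#' @rdname pipeline_io
#' @param expr Expression tibble.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression(expr)
  readr::write_tsv(expr, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_groups_tsv <- function(path) {
  x <- read_tsv_strict(path, col_types = readr::cols(.default = "c"))
  if (!all(c("sample", "group") %in% names(x))) {
    abort(sprintf("%s must have `sample` and `group` columns.", path))
  }
  if (anyDuplicated(x$sample)) abort(sprintf("duplicate samples in %s", path))
  x[c("sample", "group")]
}

#' @rdname pipeline_io
#' @param groups Sample/group tibble.
#' @export
write_groups_tsv <- function(groups, path) {
  readr::write_tsv(groups[c("sample", "group")], path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_qpcr_tsv <- function(path) {
  x <- read_tsv_strict(path, col_types = readr::cols(
    sample_id = "c", group = "c", target = "c", ct = "d"
  ))
  check_qpcr(x)
  x[c("sample_id", "group", "target", "ct")]
}

#' @rdname pipeline_io
#' @param qpcr Ct tibble.
#' @export
write_qpcr_tsv <- function(qpcr, path) {
  if (inherits(qpcr, "mhg_qpcr_sim")) qpcr <- qpcr$qpcr
  check_qpcr(qpcr)
  readr::write_tsv(qpcr[c("sample_id", "group", "target", "ct")], path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort(sprintf("empty GMT file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("GMT line %d of %s has fewer than 3 fields (name, description, members...).",
                  bad[1], path))
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate set name in %s: %s", path, nm[duplicated(nm)][1]))
  }
  desc <- vapply(parts, `[[`, character(1), 2L)
  members <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  tibble(set = rep(nm, lengths(members)),
         description = rep(desc, lengths(members)),
         gene = unlist(members))
}

#' @rdname pipeline_io
#' @param sets Gene sets: long tibble (`set`, `gene`, optional
#'   `description`) or named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  if (is.data.frame(sets)) {
    desc <- if ("description" %in% names(sets)) {
      vapply(split(sets$description, factor(sets$set, unique(sets$set))),
             `[[`, character(1), 1L)
    } else NULL
    lst <- as_gene_sets(sets)
  } else {
    lst <- as_gene_sets(sets)
    desc <- NULL
  }
  if (is.null(desc)) desc <- rep("na", length(lst))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(lst), desc, lst)
  readr::write_lines(lines, path)
  invisible(path)
}
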