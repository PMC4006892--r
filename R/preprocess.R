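#' Quantile-normalize an expression table
#'
#' Forces every sample to share the same intensity distribution: each value is
#' replaced by the across-sample mean of the order statistics at its
#' within-sample rank. After normalization the sorted value vector of every
#' sample is identical (up to ties), which removes sample-to-sample
#' distributional shifts before differential testing.
#'
#' Ties within a sample receive the mean of the normalized values over their
#' tied rank span, the convention that keeps the transform idempotent and
#' rank-preserving.
#'
#' @param expr Expression tibble (see [expr_matrix()]).
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` first for raw-scale
#'   input. Default `FALSE`: values are assumed to be on the log2 scale
#'   already.
#' @return The expression tibble with normalized sample columns; probe and
#'   gene columns untouched.
#' @examples
#' expr <- tibble::tibble(
#'   probe_id = c("p1", "p2"), gene_symbol = c("A", "B"),
#'   s1 = c(1, 3), s2 = c(4, 2)
#' )
#' quantile_normalize(expr) # -> s1 = (1.5, 3.5), s2 = (3.5, 1.5)
#' @export
quantile_normalize <- function(expr, log2_transform = FALSE) {
  m <- expr_matrix(expr)
  if (log2_transform) {
    if (any(m < 0)) abort("negative intensities: cannot apply log2(x + 1).")
    m <- log2(m + 1)
  }
  if (ncol(m) > 1L) {
    target <- rowMeans(apply(m, 2L, sort))
    csum <- c(0, cumsum(target))
    for (j in seq_len(ncol(m))) {
      rmin <- rank(m[, j], ties.method = "min")
      rmax <- rank(m[, j], ties.method = "max")
      # mean of the target order statistics across each tied rank span
      m[, j] <- (csum[rmax + 1L] - csum[rmin]) / (rmax - rmin + 1L)
    }
  }
  expr[sample_names(expr)] <- as.data.frame(m)
  expr
}

#' Call detected probes against an intensity threshold
#'
#' A probe is called detected when its intensity strictly exceeds `threshold`
#' in at least one sample; everything else is treated as background and
#' excluded from downstream testing. Use `threshold = -Inf` to keep all
#' probes.
#'
#' @param expr Expression tibble.
#' @param threshold Log2-scale detection threshold (finite or `-Inf`). See
#'   [suggest_threshold()] for a percentile-based choice.
#' @return An object of class `mhg_detection`: a list with `threshold`, the
#'   per-probe `calls` tibble (`probe_id`, `max_intensity`, `detected`), and
#'   `detected`, the filtered expression tibble in the original probe order.
#'   `tidy()` returns the calls.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 1))
#' det <- detect_probes(sim$expr, threshold = 5)
#' det
#' @export
detect_probes <- function(expr, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold == Inf) {
    abort("`threshold` must be a single finite value or -Inf.")
  }
  m <- expr_matrix(expr)
  mx <- apply(m, 1L, max)
  mask <- mx > threshold
  out <- list(
    threshold = threshold,
    calls = tibble(probe_id = expr$probe_id, max_intensity = unname(mx),
                   detected = unname(mask)),
    detected = expr[mask, , drop = FALSE]
  )
  structure(out, class = "mhg_detection")
}

#' @export
print.mhg_detection <- function(x, ...) {
  cat(sprintf("Detection filter: threshold %.4g (log2)\n", x$threshold))
  cat(sprintf("  %d / %d probes detected\n", sum(x$calls$detected), nrow(x$calls)))
  invisible(x)
}

#' @rdname detect_probes
#' @param x An `mhg_detection` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mhg_detection <- function(x, ...) x$calls

#' Suggest a detection threshold from the intensity distribution
#'
#' Pools all intensities and returns the requested percentile (linear
#' interpolation between order statistics, the spreadsheet/"type 7" rule used
#' throughout the package). A text histogram of the pooled log2 distribution
#' can be printed so the cut can also be judged by eye, the way detection
#' thresholds are classically chosen from distribution plots.
#'
#' @param expr Expression tibble.
#' @param percentile Percentile of the pooled distribution, in \[0, 100\].
#'   Default 20.
#' @param histogram Print the text histogram? Default `TRUE`.
#' @return The threshold (a single log2 value).
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 1))
#' suggest_threshold(sim$expr, percentile = 20, histogram = FALSE)
#' @export
suggest_threshold <- function(expr, percentile = 20, histogram = TRUE) {
  if (!is.numeric(percentile) || length(percentile) != 1L || is.na(percentile) ||
      percentile < 0 || percentile > 100) {
    abort("`percentile` must be a single value in [0, 100].")
  }
  pooled <- as.vector(expr_matrix(expr))
  thr <- unname(quantile(pooled, percentile / 100, type = 7))
  if (histogram) {
    inform(c("Pooled log2 intensity distribution:", text_histogram(pooled, thr)))
  }
  thr
}

# 20-bin text histogram with a marker on the bin holding the threshold
text_histogram <- function(x, threshold, bins = 20L, width = 40L) {
  if (length(unique(x)) == 1L) {
    return(sprintf("all %d values equal %.4g", length(x), x[1]))
  }
  brk <- seq(min(x), max(x), length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE), nbins = bins)
  bar <- vapply(cnt, function(k) {
    strrep("#", max(0L, round(width * k / max(cnt))))
  }, character(1))
  mark <- findInterval(threshold, brk, rightmost.closed = TRUE)
  sprintf("[%8.3f,%8.3f%s %6d %s%s", brk[-length(brk)], brk[-1],
          ifelse(seq_len(bins) == bins, "]", ")"), cnt, bar,
          ifelse(seq_len(bins) == mark, "  <- threshold", ""))
}
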