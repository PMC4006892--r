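#' Exchangeability factor s0 from per-probe scatter
#'
#' The SAM denominator adds a constant s0 to every probe's pooled standard
#' error so that probes with accidentally tiny variance do not dominate the
#' significance ranking. s0 is taken as a percentile of the per-probe scatter
#' values (default the 75th), computed with linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param scatter_values Per-probe pooled standard errors, all non-negative.
#' @param percentile Percentile in \[0, 100\]; default 75.
#' @return The s0 value.
#' @examples
#' compute_s0(c(1, 2, 3, 4), 75) # 3.25
#' @export
compute_s0 <- function(scatter_values, percentile = 75) {
  if (length(scatter_values) == 0L || anyNA(scatter_values)) {
    abort("`scatter_values` must be non-empty and free of missing values.")
  }
  if (any(scatter_values < 0)) abort("scatter values must be >= 0.")
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile < 0 || percentile > 100) {
    abort("`percentile` must be a single value in [0, 100].")
  }
  unname(quantile(scatter_values, percentile / 100, type = 7))
}

# Core two-class unpaired statistic on a plain matrix.
# idx_treated is a logical column selector; returns list(d, s, diff).
#   s = sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))
#   d = (mean_treated - mean_control) / (s + s0)
sam_core <- function(m, idx_treated, s0) {
  n2 <- sum(idx_treated)
  n1 <- ncol(m) - n2
  m1 <- rowMeans(m[, !idx_treated, drop = FALSE])
  m2 <- rowMeans(m[, idx_treated, drop = FALSE])
  ss <- rowSums((m[, !idx_treated, drop = FALSE] - m1)^2) +
    rowSums((m[, idx_treated, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  diff <- m2 - m1
  list(d = diff / (s + s0), s = s, diff = diff)
}

#' SAM moderated difference statistic
#'
#' Computes the two-class unpaired SAM statistic
#' \eqn{d = (\bar{x}_T - \bar{x}_C) / (s + s_0)} for every probe, where `s` is
#' the pooled standard error of the mean difference and `s0` the
#' exchangeability factor (see [compute_s0()]).
#'
#' @param expr Expression tibble (log2 scale).
#' @param groups Sample-to-group tibble (`sample`, `group`); exactly two
#'   groups, each with at least two samples.
#' @param s0 Exchangeability factor; 0 recovers the classical pooled-variance
#'   t statistic (up to the constant factor).
#' @param control,treated Optional group labels; by default the group named
#'   `"control"` (or the first seen) is the baseline.
#' @return A tibble with `probe_id`, `gene_symbol`, `d`, and the per-probe
#'   scatter `s`.
#' @seealso [sam_de()] for the full differential analysis with permutation
#'   p- and q-values.
#' @export
sam_statistic <- function(expr, groups, s0 = 0, control = NULL, treated = NULL) {
  g <- check_groups(expr, groups, control, treated)
  if (length(g$control) < 2L || length(g$treated) < 2L) {
    abort(sprintf("each group needs >= 2 samples (found %d control, %d treated).",
                  length(g$control), length(g$treated)))
  }
  m <- expr_matrix(expr)[, c(g$control, g$treated), drop = FALSE]
  res <- sam_core(m, seq_len(ncol(m)) > length(g$control), s0)
  tibble(probe_id = expr$probe_id, gene_symbol = expr$gene_symbol,
         d = unname(res$d), s = unname(res$s))
}

#' Per-probe fold changes between two groups
#'
#' The fold change is the anti-logged difference of group means on the log2
#' scale, `2^(mean treated - mean control)`, reported as a ratio together
#' with a direction flag (`"down"` when the ratio is below 1).
#'
#' @inheritParams sam_statistic
#' @return Tibble with `probe_id`, `gene_symbol`, `fold_change` (ratio
#'   treated/control) and `direction` (`"up"`/`"down"`).
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 30, seed = 1))
#' fold_changes(sim$expr, sim$groups)
#' @export
fold_changes <- function(expr, groups, control = NULL, treated = NULL) {
  g <- check_groups(expr, groups, control, treated)
  m <- expr_matrix(expr)
  diff <- unname(rowMeans(m[, g$treated, drop = FALSE]) -
                   rowMeans(m[, g$control, drop = FALSE]))
  tibble(probe_id = expr$probe_id, gene_symbol = expr$gene_symbol,
         fold_change = 2^diff,
         direction = ifelse(diff < 0, "down", "up"))
}

# Enumerate or sample group relabelings.
# Returns a logical matrix, samples x permutations: TRUE = relabeled treated.
# When the number of distinct relabelings C(n, n_treated) is at most
# `exhaustive_limit` (or n_permutations == "all"), all are enumerated.
sam_relabelings <- function(n_samples, n_treated, n_permutations,
                            exhaustive_limit = 2000L) {
  total <- choose(n_samples, n_treated)
  exhaustive <- identical(n_permutations, "all") || total <= exhaustive_limit
  if (exhaustive) {
    idx <- combn(n_samples, n_treated)
  } else {
    if (!is.numeric(n_permutations) || n_permutations < 1L) {
      abort("`n_permutations` must be a positive count or \"all\".")
    }
    idx <- replicate(n_permutations, sample.int(n_samples, n_treated))
  }
  lab <- matrix(FALSE, n_samples, ncol(idx))
  lab[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n_treated))] <- TRUE
  attr(lab, "exhaustive") <- exhaustive
  lab
}

# |d*| for every relabeling, fully vectorized across permutations:
# group means and sums of squares come from two matrix products.
sam_permuted_abs_d <- function(m, relabelings, s0) {
  ns <- ncol(m)
  nt <- sum(relabelings[, 1L])
  nc <- ns - nt
  wt <- relabelings / nt            # samples x B
  wc <- (!relabelings) / nc
  mt <- m %*% wt                    # probes x B group means
  mc <- m %*% wc
  m2 <- m^2
  sst <- m2 %*% relabelings - nt * mt^2
  ssc <- m2 %*% (!relabelings) - nc * mc^2
  s <- sqrt((1 / nc + 1 / nt) * pmax(sst + ssc, 0) / (ns - 2))
  abs(mt - mc) / (s + s0)
}

#' SAM differential analysis with permutation FDR
#'
#' The full SAM-style two-class analysis: moderated d statistic with
#' exchangeability factor s0 set to a percentile of the per-probe scatter,
#' fold changes, permutation p-values, and q-values (the smallest false
#' discovery rate at which each probe is called significant).
#'
#' Group labels are permuted (exhaustively when at most 2000 distinct
#' relabelings exist, otherwise `n_permutations` random relabelings seeded by
#' `seed`). For each cutoff delta in `delta_grid`, the FDR is the median
#' across permutations of the number of permuted \eqn{|d^*|} values at or
#' above delta, divided by the number of probes called at that delta; the
#' q-value of a probe is the smallest FDR over the deltas at which it is
#' called. The permutation p-value pools \eqn{|d^*|} across probes and
#' permutations with add-one smoothing, \eqn{(b + 1)/(B + 1)}.
#'
#' @inheritParams sam_statistic
#' @param s0_percentile Percentile of the per-probe scatter used for s0;
#'   default 75.
#' @param n_permutations Number of random relabelings (default 1000), or
#'   `"all"` to force exhaustive enumeration.
#' @param seed Integer seed for the permutation draw.
#' @param delta_grid Non-negative cutoffs for the significance sweep; default
#'   50 evenly spaced values from 0 to max |d|.
#' @return An object of class `sam_fit`. `tidy()` returns the per-probe table
#'   sorted by q ascending (ties: |d| descending, then probe id);
#'   `glance()` a one-row summary; `autoplot()` a volcano plot. The
#'   `delta_table` element holds the FDR sweep.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 60, seed = 1))
#' fit <- sam_de(sim$expr, sim$groups, n_permutations = 100, seed = 1)
#' glance(fit)
#' head(tidy(fit))
#' @export
sam_de <- function(expr, groups, s0_percentile = 75, n_permutations = 1000,
                   seed = 1L, delta_grid = NULL,
                   control = NULL, treated = NULL) {
  g <- check_groups(expr, groups, control, treated)
  n1 <- length(g$control)
  n2 <- length(g$treated)
  if (n1 < 2L || n2 < 2L) {
    abort(sprintf("each group needs >= 2 samples (found %d control, %d treated).",
                  n1, n2))
  }
  if (!identical(n_permutations, "all") &&
      (!is.numeric(n_permutations) || length(n_permutations) != 1L ||
       n_permutations < 1L)) {
    abort("`n_permutations` must be a positive count or \"all\".")
  }
  m <- expr_matrix(expr)[, c(g$control, g$treated), drop = FALSE]
  idx_treated <- seq_len(ncol(m)) > n1

  obs <- sam_core(m, idx_treated, s0 = 0)
  s0 <- compute_s0(obs$s, s0_percentile)
  d <- obs$diff / (obs$s + s0)
  abs_d <- abs(d)

  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs_d), length.out = 50L)
  }
  if (any(delta_grid < 0)) abort("`delta_grid` values must be >= 0.")
  delta_grid <- sort(unique(delta_grid))

  relab <- with_seed(seed, sam_relabelings(ncol(m), n2, n_permutations))
  abs_d_perm <- sam_permuted_abs_d(m, relab, s0)
  B <- ncol(abs_d_perm)

  # per-permutation counts of |d*| >= delta via a sort + binary search
  false_counts <- vapply(seq_len(B), function(b) {
    srt <- sort(abs_d_perm[, b])
    length(srt) - findInterval(delta_grid, srt, left.open = TRUE)
  }, numeric(length(delta_grid)))
  false_median <- apply(false_counts, 1L, median)

  srt_obs <- sort(abs_d)
  n_called <- length(abs_d) - findInterval(delta_grid, srt_obs, left.open = TRUE)
  fdr <- pmin(1, false_median / pmax(1, n_called))

  # q = min FDR over deltas at which the probe is called (delta <= |d|);
  # the running minimum makes q monotone non-decreasing as |d| decreases
  cum_fdr <- cummin(fdr)
  j <- findInterval(abs_d, delta_grid)   # delta_grid[1] == 0 <= |d| always
  q <- cum_fdr[pmax(j, 1L)]

  # pooled permutation p with add-one smoothing
  pooled <- sort(as.vector(abs_d_perm))
  b_ge <- length(pooled) - findInterval(abs_d, pooled, left.open = TRUE)
  p_perm <- (b_ge + 1) / (length(pooled) + 1)

  fc <- 2^obs$diff
  tab <- tibble(
    probe_id = expr$probe_id, gene_symbol = expr$gene_symbol,
    d = unname(d), s = unname(obs$s),
    fold_change = unname(fc),
    direction = ifelse(obs$diff < 0, "down", "up"),
    p_perm = unname(p_perm), q = unname(q)
  )
  tab <- dplyr::arrange(tab, .data$q, dplyr::desc(abs(.data$d)), .data$probe_id)

  structure(list(
    table = tab,
    delta_table = tibble(delta = delta_grid, n_called = n_called,
                         n_false_median = false_median, fdr = fdr),
    s0 = s0, s0_percentile = s0_percentile,
    n_permutations = B, exhaustive = attr(relab, "exhaustive"),
    seed = seed, control = g$control_label, treated = g$treated_label,
    n_control = n1, n_treated = n2
  ), class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat(sprintf("SAM two-class fit: %d probes, %s (n=%d) vs %s (n=%d)\n",
              nrow(x$table), x$treated, x$n_treated, x$control, x$n_control))
  cat(sprintf("  s0 = %.4g (percentile %g); %d %s permutations\n",
              x$s0, x$s0_percentile, x$n_permutations,
              if (x$exhaustive) "exhaustive" else "random"))
  cat(sprintf("  probes at q <= 0.05: %d\n", sum(x$table$q <= 0.05)))
  invisible(x)
}

#' @rdname sam_de
#' @param x A `sam_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sam_fit <- function(x, ...) x$table

#' @rdname sam_de
#' @exportS3Method generics::glance
glance.sam_fit <- function(x, ...) {
  tibble(
    n_probes = nrow(x$table), n_control = x$n_control, n_treated = x$n_treated,
    s0 = x$s0, s0_percentile = x$s0_percentile,
    n_permutations = x$n_permutations, exhaustive = x$exhaustive,
    n_de = nrow(filter_de(x$table))
  )
}

#' Reporting filter on fold change and p-value
#'
#' Keeps probes altered by at least `min_fold` in either direction
#' (`max(ratio, 1/ratio) >= min_fold`) with permutation p-value at most
#' `max_p`. Both boundaries are inclusive. Row order is preserved.
#'
#' @param table A differential table (e.g. `tidy()` of a [sam_de()] fit) with
#'   `fold_change` and `p_perm` columns.
#' @param min_fold Minimum fold change (ratio scale); default 1.2.
#' @param max_p Maximum permutation p-value; default 0.05.
#' @return The filtered tibble.
#' @examples
#' tab <- tibble::tibble(
#'   probe_id = c("a", "b", "c"),
#'   fold_change = c(1.31, 1.15, 2.0), p_perm = c(0.04, 0.01, 0.2)
#' )
#' filter_de(tab) # only probe "a" qualifies
#' @export
filter_de <- function(table, min_fold = 1.2, max_p = 0.05) {
  if (!all(c("fold_change", "p_perm") %in% names(table))) {
    abort("`table` needs `fold_change` and `p_perm` columns.")
  }
  keep <- pmax(table$fold_change, 1 / table$fold_change) >= min_fold &
    table$p_perm <= max_p
  table[keep, , drop = FALSE]
}
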