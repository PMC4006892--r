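# Independent oracles and tiny fixture builders used across the suite.

# Exhaustive oracle for the rank order-statistic tail: enumerate every
# n-subset of {1..N} and count those with at least k elements <= r.
brute_tail <- function(N, n, k, r) {
  subs <- utils::combn(N, n)
  mean(colSums(subs <= r) >= k)
}

# Brute-force p_raw = min_k pk for given member ranks, via the oracle above.
brute_p_raw <- function(N, ranks) {
  ranks <- sort(ranks)
  min(vapply(seq_along(ranks),
             function(k) brute_tail(N, length(ranks), k, ranks[k]),
             numeric(1)))
}

# Small wide expression tibble from a plain matrix.
make_expr <- function(m, probe_ids = sprintf("p%02d", seq_len(nrow(m))),
                      genes = probe_ids,
                      samples = sprintf("s%02d", seq_len(ncol(m)))) {
  expr <- tibble::tibble(probe_id = probe_ids, gene_symbol = genes)
  expr[samples] <- as.data.frame(m)
  expr
}

make_groups <- function(samples, group) {
  tibble::tibble(sample = samples, group = group)
}

# Two-group expression fixture with n samples per group.
two_group_expr <- function(m, n_per_group = ncol(m) / 2) {
  expr <- make_expr(m)
  groups <- make_groups(sample_names(expr),
                        rep(c("control", "treated"), each = n_per_group))
  list(expr = expr, groups = groups)
}
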