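#' Collapse probes to genes, keeping the best-ranked probe
#'
#' A gene measured by several probes keeps only its highest-ranking
#' (most significant) probe; the surviving genes are re-ranked consecutively
#' 1..N with rank 1 the most significant. The input is a differential table
#' already sorted by significance; if a `q` column is present the table is
#' re-sorted by q ascending with ties broken by |d| descending and then
#' probe id, the package's canonical ordering.
#'
#' Probes with a missing or empty gene symbol cannot be ranked and are
#' dropped with an informative message.
#'
#' @param de_table Tibble with `probe_id` and `gene_symbol` columns, e.g.
#'   `tidy()` of a [sam_de()] fit.
#' @param quiet Suppress the dropped-probe message.
#' @return A ranked gene list: tibble with `rank` (1..N), `gene`, and the
#'   surviving `probe_id`.
#' @examples
#' tab <- tibble::tibble(
#'   probe_id = c("p1", "p2", "p3", "p4"),
#'   gene_symbol = c("A", "B", "A", "C")
#' )
#' collapse_probes(tab) # A=1, B=2, C=3
#' @export
collapse_probes <- function(de_table, quiet = FALSE) {
  if (!all(c("probe_id", "gene_symbol") %in% names(de_table))) {
    abort("`de_table` needs `probe_id` and `gene_symbol` columns.")
  }
  tab <- as_tibble(de_table)
  if (all(c("q", "d") %in% names(tab))) {
    tab <- dplyr::arrange(tab, .data$q, dplyr::desc(abs(.data$d)), .data$probe_id)
  }
  bad <- is.na(tab$gene_symbol) | tab$gene_symbol == ""
  if (any(bad)) {
    if (!quiet) {
      inform(sprintf("dropped %d probe(s) without a gene identifier.", sum(bad)))
    }
    tab <- tab[!bad, , drop = FALSE]
  }
  tab <- tab[!duplicated(tab$gene_symbol), , drop = FALSE]
  tibble(rank = seq_len(nrow(tab)), gene = tab$gene_symbol,
         probe_id = tab$probe_id)
}

#' Build a ranked gene list from an ordered gene vector
#'
#' Convenience constructor: genes given in significance order (best first)
#' become a ranked gene list with ranks 1..N, the input expected by the
#' enrichment functions.
#'
#' @param genes Character vector of unique gene identifiers, most significant
#'   first.
#' @return Tibble with `rank` and `gene`.
#' @export
ranked_gene_list <- function(genes) {
  if (anyDuplicated(genes)) abort("`genes` must be unique.")
  tibble(rank = seq_along(genes), gene = as.character(genes))
}

#' Tail probability of a rank order statistic
#'
#' For n ranks drawn uniformly without replacement from \{1..N\}, returns the
#' probability that at least k of them fall within the top r positions —
#' equivalently, that the k-th best drawn rank is at least as good as r. This
#' is the upper tail of a hypergeometric count and is the building block of
#' the rank-order gene-set statistic: small values mean a set's k-th best
#' member sits improbably high in the list.
#'
#' Computed by direct summation of hypergeometric terms in log space
#' (log-gamma binomials, max-shifted summation), exact to near machine
#' precision for any N.
#'
#' @param N Total number of ranked genes.
#' @param n Number of draws (set size), `n <= N`.
#' @param k Order index, `1 <= k <= n`.
#' @param r Rank cutoff, `1 <= r <= N`.
#' @return P(at least k of the n draws lie in the top r), in \[0, 1\].
#' @examples
#' order_statistic_tail(10, 3, 1, 1)  # 3/10
#' order_statistic_tail(10, 3, 2, 4)  # 40/120
#' @export
order_statistic_tail <- function(N, n, k, r) {
  for (v in list(N = N, n = n, k = k, r = r)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v)) {
      abort("`N`, `n`, `k`, `r` must be single integers.")
    }
  }
  if (n < 1L || n > N) abort("need 1 <= n <= N.")
  if (k < 1L || k > n) abort("need 1 <= k <= n.")
  if (r < 1L || r > N) abort("need 1 <= r <= N.")
  j <- seq.int(max(k, n - (N - r)), min(n, r))
  if (length(j) == 0L || j[1L] > min(n, r)) return(0)
  lt <- lchoose(r, j) + lchoose(N - r, n - j) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

#' Rank-order enrichment p-value for one gene set
#'
#' The set's members are located in the ranked gene list; with member ranks
#' \eqn{r_1 < \dots < r_n}, each \eqn{p_k} is the probability that k random
#' ranks out of n land at or above \eqn{r_k} ([order_statistic_tail()]), and
#' the set p-value is \eqn{\min_k p_k}. The minimum over k adapts the
#' statistic to however many of the set's members concentrate at the top of
#' the list; no multiplicity adjustment is applied across k because the n
#' tail tests are highly dependent.
#'
#' @param ranked Ranked gene list (tibble with `rank`, `gene`), e.g. from
#'   [collapse_probes()].
#' @param members Character vector of the set's gene identifiers.
#' @param direction `"top"` (default) tests for overrepresentation at the top
#'   of the list (rank 1 = most significant); `"literal"` applies the
#'   mirrored reading, testing concentration toward the largest rank numbers.
#' @return One-row tibble: effective size `n` (members present in the ranked
#'   list), `k_star` (smallest minimizing k), `p_raw`, `testable`, and
#'   list-columns `member_ranks` and `pk`.
#' @examples
#' ranked <- ranked_gene_list(paste0("G", 1:10))
#' gene_set_pvalue(ranked, c("G1", "G2", "G5"))  # p_raw = 8/120 at k = 2
#' @export
gene_set_pvalue <- function(ranked, members, direction = c("top", "literal")) {
  direction <- match.arg(direction)
  check_ranked(ranked)
  N <- nrow(ranked)
  r <- sort(ranked$rank[ranked$gene %in% members])
  n <- length(r)
  if (n == 0L) {
    return(tibble(n = 0L, k_star = NA_integer_, p_raw = NA_real_,
                  testable = FALSE, member_ranks = list(integer(0)),
                  pk = list(numeric(0))))
  }
  if (direction == "literal") {
    # mirror the list: k-th largest rank >= r becomes k-th best <= N - r + 1
    r <- N - rev(r) + 1L
  }
  pk <- vapply(seq_len(n), function(k) order_statistic_tail(N, n, k, r[k]),
               numeric(1))
  k_star <- which.min(pk)
  tibble(n = n, k_star = as.integer(k_star), p_raw = pk[k_star],
         testable = TRUE, member_ranks = list(r), pk = list(pk))
}

check_ranked <- function(ranked) {
  if (!is.data.frame(ranked) || !all(c("rank", "gene") %in% names(ranked))) {
    abort("`ranked` must be a tibble with `rank` and `gene` columns.")
  }
  if (nrow(ranked) == 0L) abort("`ranked` is empty.")
  if (!identical(sort(as.integer(ranked$rank)), seq_len(nrow(ranked)))) {
    abort("ranks must be a permutation of 1..N.")
  }
  if (anyDuplicated(ranked$gene)) abort("duplicate genes in ranked list.")
  invisible(ranked)
}

#' Test a gene-set collection against a ranked gene list
#'
#' Applies [gene_set_pvalue()] to every set, Bonferroni-adjusts the raw
#' p-values for the number of testable sets (those with at least one member
#' in the ranked list), and flags the sets passing the reporting rule
#' `p_adjusted <= alpha`. Sets with no members in the list are kept in the
#' output flagged non-testable and are excluded from the Bonferroni count.
#'
#' @inheritParams gene_set_pvalue
#' @param sets A gene-set collection: either a long tibble with `set` and
#'   `gene` columns (as returned by [read_gmt()]) or a named list of
#'   character vectors.
#' @param alpha Reporting threshold on the adjusted p-value; default 0.01.
#' @return A tibble of class `mhg_enrichment`, sorted by adjusted p then set
#'   name: `set`, `n`, `k_star`, `p_raw`, `p_adjusted`, `reported`,
#'   `testable`. The Bonferroni count m and alpha are stored as attributes;
#'   `autoplot()` draws the significance bar chart.
#' @examples
#' ranked <- ranked_gene_list(paste0("G", 1:20))
#' sets <- list(top = paste0("G", 1:4), spread = paste0("G", c(2, 9, 17)))
#' enrich_collection(ranked, sets, alpha = 0.05)
#' @export
enrich_collection <- function(ranked, sets, alpha = 0.01,
                              direction = c("top", "literal")) {
  direction <- match.arg(direction)
  sets <- as_gene_sets(sets)
  if (length(sets) == 0L) abort("`sets` contains no gene sets.")
  check_ranked(ranked)
  res <- purrr::map(sets, function(g) gene_set_pvalue(ranked, g, direction))
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(out, set = names(sets), .before = 1L)
  m <- sum(out$testable)
  if (m == 0L) abort("no set overlaps the ranked gene list; nothing testable.")
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out$reported <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  out <- dplyr::arrange(out, .data$p_adjusted, .data$set)
  out <- out[c("set", "n", "k_star", "p_raw", "p_adjusted", "reported",
               "testable", "member_ranks", "pk")]
  structure(out, class = c("mhg_enrichment", class(tibble())),
            alpha = alpha, m = m, n_ranked = nrow(ranked),
            direction = direction)
}

# Accept a long tibble (set, gene) or a named list of character vectors.
as_gene_sets <- function(sets) {
  if (is.data.frame(sets)) {
    if (!all(c("set", "gene") %in% names(sets))) {
      abort("a gene-set data frame needs `set` and `gene` columns.")
    }
    return(split(as.character(sets$gene), factor(sets$set, unique(sets$set))))
  }
  if (is.list(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      abort("gene-set lists must have unique names.")
    }
    return(lapply(sets, as.character))
  }
  abort("`sets` must be a set/gene data frame or a named list.")
}
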