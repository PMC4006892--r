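test_that("probe collapsing keeps the best probe per gene and re-ranks 1..N", {
  tab <- tibble::tibble(probe_id = c("p1", "p2", "p3", "p4"),
                        gene_symbol = c("A", "B", "A", "C"))
  out <- collapse_probes(tab)
  expect_equal(out$gene, c("A", "B", "C"))
  expect_equal(out$rank, 1:3)
  expect_equal(out$probe_id, c("p1", "p2", "p4"))

  # one probe per gene: order preserved as consecutive ranks
  tab1 <- tibble::tibble(probe_id = c("x", "y"), gene_symbol = c("G2", "G1"))
  expect_equal(collapse_probes(tab1)$gene, c("G2", "G1"))
  expect_equal(nrow(collapse_probes(tab1[0, ])), 0)
})

test_that("collapsing re-sorts by q with the canonical tie-break and drops blank genes", {
  tab <- tibble::tibble(
    probe_id = c("p4", "p3", "p2", "p1"),
    gene_symbol = c("A", "B", NA, "A"),
    d = c(-3, 3, 5, 1), q = c(0.2, 0.01, 0.01, 0.01)
  )
  expect_message(out <- collapse_probes(tab), "1 probe")
  # q ties broken by |d| desc then probe_id: p3 (B) before p1 (A); p4 last
  expect_equal(out$gene, c("B", "A"))
  expect_equal(out$probe_id, c("p3", "p1"))
})

test_that("order_statistic_tail matches closed forms and bounds checks", {
  expect_equal(order_statistic_tail(10, 3, 1, 1), 0.3)   # n/N
  expect_equal(order_statistic_tail(10, 3, 1, 10), 1)
  expect_equal(order_statistic_tail(10, 3, 2, 4), 40 / 120)
  expect_error(order_statistic_tail(10, 11, 1, 1), "n <= N")
  expect_error(order_statistic_tail(10, 3, 4, 1), "k <= n")
  expect_error(order_statistic_tail(10, 3, 1, 11), "r <= N")
})

test_that("order_statistic_tail equals the hypergeometric upper tail at scale", {
  set.seed(17)
  for (i in 1:50) {
    N <- sample(5:2000, 1)
    n <- sample(seq_len(min(N, 60)), 1)
    k <- sample(n, 1)
    r <- sample(N, 1)
    expect_equal(order_statistic_tail(N, n, k, r),
                 phyper(k - 1, r, N - r, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("pk is monotone in r and in k", {
  N <- 40; n <- 6
  for (k in 1:n) {
    p_r <- vapply(1:N, function(r) order_statistic_tail(N, n, k, r), numeric(1))
    expect_true(all(diff(p_r) >= -1e-12)) # non-decreasing in r
  }
  for (r in c(3, 10, 25)) {
    p_k <- vapply(1:n, function(k) order_statistic_tail(N, n, k, r), numeric(1))
    expect_true(all(diff(p_k) <= 1e-12)) # non-increasing in k
  }
})

test_that("gene_set_pvalue reproduces the worked examples", {
  ranked <- ranked_gene_list(paste0("G", 1:10))
  res <- gene_set_pvalue(ranked, c("G1", "G2", "G5"))
  expect_equal(res$pk[[1]], c(0.3, 8 / 120, 10 / 120), tolerance = 1e-12)
  expect_equal(res$p_raw, 8 / 120, tolerance = 1e-12)
  expect_equal(res$k_star, 2L)

  top3 <- gene_set_pvalue(ranked, c("G1", "G2", "G3"))
  expect_equal(top3$p_raw, 1 / 120, tolerance = 1e-12)

  whole <- gene_set_pvalue(ranked, paste0("G", 1:10))
  expect_equal(whole$pk[[1]], rep(1, 10))
  expect_equal(whole$p_raw, 1)
})

test_that("an empty intersection is flagged not testable", {
  ranked <- ranked_gene_list(paste0("G", 1:5))
  res <- gene_set_pvalue(ranked, c("X1", "X2"))
  expect_false(res$testable)
  expect_true(is.na(res$p_raw))
})

test_that("p_raw matches the exhaustive min-k oracle on random small cases", {
  set.seed(23)
  for (i in 1:25) {
    N <- sample(6:12, 1)
    n <- sample(2:4, 1)
    ranks <- sort(sample(N, n))
    ranked <- ranked_gene_list(paste0("G", 1:N))
    res <- gene_set_pvalue(ranked, paste0("G", ranks))
    expect_equal(res$p_raw, brute_p_raw(N, ranks), tolerance = 1e-12)
  }
})

test_that("improving a member's rank never increases p_raw", {
  set.seed(29)
  N <- 80
  ranked <- ranked_gene_list(paste0("G", 1:N))
  for (i in 1:20) {
    ranks <- sort(sample(N, 6))
    p0 <- gene_set_pvalue(ranked, paste0("G", ranks))$p_raw
    j <- sample(6, 1)
    better <- setdiff(seq_len(ranks[j] - 1), ranks)
    if (length(better) == 0) next
    ranks2 <- sort(c(ranks[-j], sample(better, 1)))
    p1 <- gene_set_pvalue(ranked, paste0("G", ranks2))$p_raw
    expect_lte(p1, p0 + 1e-12)
  }
})

test_that("the literal direction mirrors the list", {
  ranked <- ranked_gene_list(paste0("G", 1:10))
  bottom <- gene_set_pvalue(ranked, c("G6", "G9", "G10"), direction = "literal")
  top <- gene_set_pvalue(ranked, c("G1", "G2", "G5"), direction = "top")
  # ranks {6,9,10} mirrored are {1,2,5}: identical pk under the literal reading
  expect_equal(bottom$pk[[1]], top$pk[[1]], tolerance = 1e-12)
})

test_that("implementation p_raw equals the oracle on random null draws", {
  # the empirical null of p_raw is whatever min_k pk gives on random ranks;
  # the implementation must coincide draw by draw with an independent
  # hypergeometric-tail oracle (stats::phyper)
  set.seed(31)
  N <- 50; n <- 5
  ranked <- ranked_gene_list(paste0("G", 1:N))
  for (i in 1:200) {
    ranks <- sort(sample(N, n))
    oracle <- min(phyper(seq_len(n) - 1, ranks, N - ranks, n, lower.tail = FALSE))
    expect_equal(gene_set_pvalue(ranked, paste0("G", ranks))$p_raw,
                 oracle, tolerance = 1e-12)
  }
})

test_that("enrich_collection Bonferroni-adjusts over testable sets and sorts", {
  ranked <- ranked_gene_list(paste0("G", 1:100))
  sets <- list(
    hot = paste0("G", 1:5),            # extreme top concentration
    null1 = paste0("G", c(11, 40, 77)),
    null2 = paste0("G", c(25, 60, 90)),
    ghost = c("X1", "X2")              # not on the array
  )
  res <- enrich_collection(ranked, sets, alpha = 0.01)
  expect_equal(attr(res, "m"), 3) # ghost excluded from the Bonferroni count
  testable <- res[res$testable, ]
  expect_equal(testable$p_adjusted, pmin(1, testable$p_raw * 3), tolerance = 1e-12)
  expect_equal(res$set[1], "hot")
  expect_false(res$reported[res$set == "ghost"])
  expect_true(all(diff(testable$p_adjusted) >= -1e-12))
})

test_that("single-set and capped adjustments follow the arithmetic", {
  ranked <- ranked_gene_list(paste0("G", 1:40))
  one <- enrich_collection(ranked, list(s = paste0("G", c(5, 17, 30))), alpha = 0.01)
  expect_equal(one$p_adjusted, one$p_raw) # m = 1
  many <- c(list(top = paste0("G", 1:3)),
            setNames(lapply(1:9, function(i) paste0("G", sample(40, 4))),
                     paste0("n", 1:9)))
  res <- enrich_collection(ranked, many, alpha = 0.01)
  expect_true(all(res$p_adjusted <= 1))
  expect_equal(res$p_adjusted[res$set == "top"],
               min(1, res$p_raw[res$set == "top"] * 10))
})
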