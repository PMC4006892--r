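test_that("compute_s0 is the interpolated percentile of the scatter", {
  expect_equal(compute_s0(c(1, 2, 3, 4), 75), 3.25)
  expect_equal(compute_s0(rep(0.7, 10), 30), 0.7)
  expect_equal(compute_s0(c(5, 1, 9), 0), 1)
  expect_error(compute_s0(numeric(0)), "non-empty")
  expect_error(compute_s0(c(-1, 2)), ">= 0")
})

test_that("sam_statistic evaluates the two-class unpaired formula", {
  fx <- two_group_expr(matrix(c(1, 2, 3, 3, 4, 5), 1))
  out <- sam_statistic(fx$expr, fx$groups, s0 = 0)
  expect_equal(out$s, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(out$d, sqrt(6), tolerance = 1e-12) # 2 / sqrt(2/3)

  # equal group means give d = 0 regardless of s0
  fx0 <- two_group_expr(matrix(c(1, 2, 3, 3, 2, 1), 1))
  expect_equal(sam_statistic(fx0$expr, fx0$groups, s0 = 0.5)$d, 0)
})

test_that("|d| shrinks monotonically toward 0 as s0 grows", {
  set.seed(5)
  fx <- two_group_expr(matrix(rnorm(20 * 6), 20))
  s0s <- c(0, 0.5, 1, 5, 50)
  d <- sapply(s0s, function(s0) abs(sam_statistic(fx$expr, fx$groups, s0)$d))
  expect_true(all(diff(t(d)) <= 0))
  expect_lt(max(d[, length(s0s)]), max(d[, 1]))
})

test_that("with s0 = 0 and equal group sizes d is the classical pooled t", {
  set.seed(9)
  m <- matrix(rnorm(100 * 8, 8, 1), 100)
  fx <- two_group_expr(m)
  d <- sam_statistic(fx$expr, fx$groups, s0 = 0)$d
  tref <- apply(m, 1, function(x) {
    unname(t.test(x[5:8], x[1:4], var.equal = TRUE)$statistic)
  })
  expect_equal(d, tref, tolerance = 1e-10)
})

test_that("groups with fewer than two samples are a design error", {
  expr <- make_expr(matrix(rnorm(9), 3))
  groups <- make_groups(sample_names(expr), c("control", "treated", "treated"))
  expect_error(sam_statistic(expr, groups, 0), ">= 2 samples")
  expect_error(sam_de(expr, groups), ">= 2 samples")
})

test_that("n1 = n2 = 2 enumerates exactly choose(4, 2) = 6 relabelings", {
  set.seed(2)
  fx <- two_group_expr(matrix(rnorm(5 * 4), 5))
  fit <- sam_de(fx$expr, fx$groups, n_permutations = "all", seed = 1)
  expect_true(fit$exhaustive)
  expect_equal(fit$n_permutations, 6)
  # requesting more random permutations than distinct relabelings also
  # falls back to exhaustive enumeration
  fit2 <- sam_de(fx$expr, fx$groups, n_permutations = 1000, seed = 1)
  expect_equal(fit2$n_permutations, 6)
})

test_that("permutation p-values match a direct pooled-count oracle", {
  set.seed(21)
  fx <- two_group_expr(matrix(rnorm(12 * 4, 8, 1), 12))
  fit <- sam_de(fx$expr, fx$groups, n_permutations = "all", seed = 1)
  m <- expr_matrix(fx$expr)
  s0 <- fit$s0
  combs <- combn(4, 2)
  dstar <- apply(combs, 2, function(tr) {
    x <- m[, -tr, drop = FALSE]; y <- m[, tr, drop = FALSE]
    ss <- rowSums((x - rowMeans(x))^2) + rowSums((y - rowMeans(y))^2)
    s <- sqrt((1 / 2 + 1 / 2) * ss / 2)
    abs(rowMeans(y) - rowMeans(x)) / (s + s0)
  })
  tab <- tidy(fit)
  pooled <- as.vector(dstar)
  expected <- vapply(tab$probe_id, function(p) {
    dd <- abs(tab$d[tab$probe_id == p])
    (sum(pooled >= dd) + 1) / (length(pooled) + 1)
  }, numeric(1))
  # the identity relabeling reproduces |d| only to machine precision, so
  # boundary equalities may count differently by a permutation or two
  expect_true(all(abs(unname(expected) - tab$p_perm) <= 2.5 / (length(pooled) + 1)))
})

test_that("q-values are monotone in |d|, capped at 1, and 0 for a clear outlier", {
  set.seed(13)
  m <- matrix(rnorm(50 * 6, 8, 0.5), 50)
  m[1, 4:6] <- m[1, 4:6] + 50 # unmissable shift
  fx <- two_group_expr(m)
  fit <- sam_de(fx$expr, fx$groups, n_permutations = "all", seed = 1)
  tab <- tidy(fit) # sorted by q ascending
  ord <- order(abs(tab$d), decreasing = TRUE)
  expect_true(all(diff(tab$q[ord]) >= -1e-12))
  expect_true(all(tab$q <= 1))
  expect_equal(tab$q[tab$probe_id == "p01"], 0)
})

test_that("zero permutations is a configuration error", {
  fx <- two_group_expr(matrix(rnorm(8), 2))
  expect_error(sam_de(fx$expr, fx$groups, n_permutations = 0), "positive count")
})

test_that("fold changes anti-log the group-mean difference", {
  m <- rbind(c(5, 5, 5, 5), c(5, 5, 6, 6), c(8, 8, 8.39, 8.39))
  fx <- two_group_expr(m)
  fc <- fold_changes(fx$expr, fx$groups)
  expect_equal(fc$fold_change[1], 1)
  expect_equal(fc$fold_change[2], 2)
  expect_equal(round(fc$fold_change[3], 2), 1.31) # a 0.39 log2 shift
  expect_equal(fc$direction, c("up", "up", "up"))
  fx_down <- two_group_expr(rbind(c(6, 6, 5, 5)))
  expect_equal(fold_changes(fx_down$expr, fx_down$groups)$direction, "down")
})

test_that("the reporting filter keeps >=1.2-fold, p<=0.05, boundaries inclusive", {
  tab <- tibble::tibble(
    probe_id = c("a", "b", "c", "d", "e"),
    fold_change = c(1.31, 1.15, 2.0, 1.2, 1 / 1.2),
    p_perm = c(0.04, 0.01, 0.2, 0.05, 0.05)
  )
  out <- filter_de(tab)
  expect_equal(out$probe_id, c("a", "d", "e")) # order preserved; d,e at both boundaries
  expect_equal(nrow(filter_de(tab[0, ])), 0)
})

test_that("sam_de output is deterministic under a fixed seed", {
  set.seed(33)
  # 7 + 7 samples: choose(14, 7) > 2000 distinct relabelings, so the
  # permutations are genuinely random draws governed by `seed`
  fx <- two_group_expr(matrix(rnorm(30 * 14, 8, 1), 30), 7)
  f1 <- sam_de(fx$expr, fx$groups, n_permutations = 50, seed = 4)
  f2 <- sam_de(fx$expr, fx$groups, n_permutations = 50, seed = 4)
  expect_equal(tidy(f1), tidy(f2))
  expect_false(isTRUE(all.equal(tidy(f1)$q,
                                tidy(sam_de(fx$expr, fx$groups,
                                            n_permutations = 50, seed = 5))$q)))
})
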