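test_that("identical configurations give identical output", {
  cfg <- sim_config(n_genes = 60, seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  ga <- simulate_gene_sets(cfg, a$truth)
  gb <- simulate_gene_sets(cfg, b$truth)
  expect_identical(ga$sets, gb$sets)
  qa <- simulate_qpcr("ALPL", 2, n = 3, ct_sd = 0.2, seed = 5)
  qb <- simulate_qpcr("ALPL", 2, n = 3, ct_sd = 0.2, seed = 5)
  expect_identical(qa$qpcr, qb$qpcr)
  expect_false(identical(a$expr,
                         simulate_expression(sim_config(n_genes = 60, seed = 12))$expr))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  x <- rnorm(1)
  set.seed(99)
  invisible(simulate_expression(sim_config(n_genes = 50, seed = 1)))
  expect_identical(rnorm(1), x)
})

test_that("de_fraction = 0 yields a pure null with all true folds 1", {
  sim <- simulate_expression(sim_config(n_genes = 50, de_fraction = 0, seed = 2))
  expect_true(all(sim$truth$true_fold == 1))
  expect_false(any(sim$truth$is_de))
})

test_that("every probe has exactly one truth record and groups are balanced", {
  cfg <- sim_config(n_genes = 40, n_per_group = 4, seed = 6)
  sim <- simulate_expression(cfg)
  expect_identical(sim$truth$probe_id, sim$expr$probe_id)
  expect_equal(anyDuplicated(sim$truth$probe_id), 0L)
  expect_equal(table(sim$groups$group), table(rep(c("control", "treated"), 4)),
               ignore_attr = TRUE)
  expect_identical(sim$groups$sample, sample_names(sim$expr))
})

test_that("realized DE log2 differences centre on log2(fold)", {
  cfg <- sim_config(n_genes = 1000, probes_per_gene = 1, n_per_group = 4,
                    de_fraction = 0.2, de_fold_changes = 2,
                    de_direction = "up", noise_sd = 0.3,
                    undetected_fraction = 0, seed = 8)
  sim <- simulate_expression(cfg)
  g <- sim$groups
  m <- expr_matrix(sim$expr)
  diff <- rowMeans(m[, g$sample[g$group == "treated"]]) -
    rowMeans(m[, g$sample[g$group == "control"]])
  de <- sim$truth$is_de
  expect_equal(sum(de), 200)
  # standard error of the mean realized difference under the noise model
  se <- 0.3 * sqrt(2 / 4) / sqrt(sum(de))
  expect_lt(abs(mean(diff[de]) - 1), 3 * se)
})

test_that("the configured fraction of probes sits entirely below the floor", {
  cfg <- sim_config(n_genes = 200, probes_per_gene = 1, detection_floor = 5,
                    undetected_fraction = 0.15, seed = 4)
  sim <- simulate_expression(cfg)
  below <- sim$truth$below_floor
  expect_equal(sum(below), 30)
  m <- expr_matrix(sim$expr)
  expect_true(all(m[below, ] < 5))
  det <- detect_probes(sim$expr, 5)
  expect_true(all(det$calls$detected[!below] | apply(m[!below, ], 1, max) <= 5))
})

test_that("n_probes pins the exact probe total", {
  cfg <- sim_config(n_genes = 100, n_probes = 160, seed = 3)
  sim <- simulate_expression(cfg)
  expect_equal(nrow(sim$expr), 160)
  expect_equal(length(unique(sim$expr$gene_symbol)), 100)
})

test_that("gene sets respect sizes, enrichment flags, and truth completeness", {
  cfg <- sim_config(n_genes = 200, n_gene_sets = 10, set_size_range = c(5, 5),
                    enriched_set_ids = character(0), seed = 5)
  sim <- simulate_expression(cfg)
  gs <- simulate_gene_sets(cfg, sim$truth)
  expect_equal(unname(table(gs$sets$set)), rep(5L, 10), ignore_attr = TRUE)
  expect_false(any(gs$set_truth$is_enriched))
  expect_equal(nrow(gs$set_truth), 10)

  cfg2 <- sim_config(n_genes = 200, n_gene_sets = 6, set_size_range = c(10, 30),
                     de_fraction = 0.3, enriched_set_ids = c("SET02", "SET05"),
                     enriched_de_fraction = 0.8, seed = 5)
  sim2 <- simulate_expression(cfg2)
  gs2 <- simulate_gene_sets(cfg2, sim2$truth)
  sizes <- table(gs2$sets$set)
  expect_true(all(sizes >= 10 & sizes <= 30))
  de_genes <- unique(sim2$truth$gene_symbol[sim2$truth$is_de])
  hit <- gs2$sets[gs2$sets$set == "SET02", ]
  expect_gte(mean(hit$gene %in% de_genes), 0.7) # ~80% by construction
  expect_equal(gs2$set_truth$is_enriched,
               sprintf("SET%02d", 1:6) %in% c("SET02", "SET05"))
})

test_that("configuration errors name the offending field", {
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(de_fold_changes = c(1.5, -2)), "de_fold_changes")
  expect_error(sim_config(n_genes = 10, set_size_range = c(5, 20)), "set_size_range")
  expect_error(sim_config(enriched_set_ids = "SET99"), "enriched_set_ids")
  expect_error(sim_config(n_genes = 10, n_probes = 5), "n_probes")
  expect_error(simulate_qpcr("A", true_rq = -1, n = 3), "positive")
  expect_error(simulate_qpcr("A", true_rq = 1, n = 1), ">= 2")
})

test_that("noise-free reference Ct is identical across qPCR groups", {
  sim <- simulate_qpcr("ALPL", true_rq = 2, n = 3, ct_sd = 0, seed = 1)
  ref <- sim$qpcr[sim$qpcr$target == "GAPDH", ]
  expect_equal(length(unique(ref$ct)), 1L)
  tgt <- sim$qpcr[sim$qpcr$target == "ALPL", ]
  expect_equal(unique(tgt$ct[tgt$group == "control"]) -
                 unique(tgt$ct[tgt$group == "treated"]), log2(2))
})
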