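#' Configuration for the synthetic expression experiment
#'
#' Bundles and validates the parameters of the two-condition (treated vs
#' control) synthetic microarray experiment used to exercise every pipeline
#' stage against known ground truth. Defaults emulate a small siRNA-style
#' Illumina experiment: log2-scale intensities, triplicate arrays per
#' condition, a detection floor under which a fraction of probes sit, a
#' modest fraction of differential genes at fold changes in the 1.2-2x
#' range, and gene sets of which a chosen few are enriched for differential
#' genes.
#'
#' @param n_genes Number of genes on the array.
#' @param probes_per_gene Either a single positive integer (every gene gets
#'   exactly that many probes) or a probability weight vector over 1, 2, ...
#'   probes per gene. Default `c(0.6, 0.3, 0.1)`: most genes measured by one
#'   probe, some by two or three, so probe collapsing is exercised.
#' @param n_probes Optional exact total probe count; per-gene counts are
#'   adjusted to hit it (requires `n_genes <= n_probes`). Default `NULL`
#'   (total follows from `probes_per_gene`).
#' @param n_per_group Arrays per condition (>= 2); default 3, the replicate
#'   scale typical of these experiments.
#' @param baseline_mean,baseline_sd Mean and SD of per-probe baseline log2
#'   intensity; defaults 8 and 1.5.
#' @param noise_sd SD of the additive Gaussian measurement noise, log2
#'   scale; default 0.3.
#' @param de_fraction Fraction of genes that are truly differential, in
#'   \[0, 1\]; default 0.1.
#' @param de_fold_changes Menu of fold changes (> 0, ratio scale) sampled for
#'   differential genes; default `c(1.2, 1.4, 1.6, 1.8, 2.0)`.
#' @param de_direction `"both"` (default; up or down at random), `"up"`, or
#'   `"down"`.
#' @param detection_floor Log2 value below which undetected probes sit;
#'   default 5.
#' @param undetected_fraction Fraction of probes shifted entirely below the
#'   detection floor; default 0.1.
#' @param n_gene_sets Number of gene sets to simulate; default 20.
#' @param set_size_range Inclusive (min, max) set sizes; default c(10, 40).
#' @param enriched_set_ids Names of the sets to enrich with differential
#'   genes (must be among `SET01..SETxx`); default none.
#' @param enriched_de_fraction Fraction of an enriched set's members drawn
#'   from truly differential genes; default 0.8.
#' @param seed Integer root seed; identical configurations produce identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 100, enriched_set_ids = "SET01", seed = 7)
#' cfg$n_per_group
#' @export
sim_config <- function(n_genes = 800, probes_per_gene = c(0.6, 0.3, 0.1),
                       n_probes = NULL, n_per_group = 3,
                       baseline_mean = 8, baseline_sd = 1.5, noise_sd = 0.3,
                       de_fraction = 0.1,
                       de_fold_changes = c(1.2, 1.4, 1.6, 1.8, 2.0),
                       de_direction = c("both", "up", "down"),
                       detection_floor = 5, undetected_fraction = 0.1,
                       n_gene_sets = 20, set_size_range = c(10, 40),
                       enriched_set_ids = character(0),
                       enriched_de_fraction = 0.8, seed = 1L) {
  cfg <- list(
    n_genes = n_genes, probes_per_gene = probes_per_gene, n_probes = n_probes,
    n_per_group = n_per_group, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, noise_sd = noise_sd, de_fraction = de_fraction,
    de_fold_changes = de_fold_changes,
    de_direction = match.arg(de_direction),
    detection_floor = detection_floor,
    undetected_fraction = undetected_fraction,
    n_gene_sets = n_gene_sets, set_size_range = set_size_range,
    enriched_set_ids = as.character(enriched_set_ids),
    enriched_de_fraction = enriched_de_fraction, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    abort(sprintf("invalid `%s`: %s", field, why))
  }
  count1 <- function(field, min) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v) || v < min) {
      fail(field, sprintf("must be a single integer >= %d", min))
    }
  }
  count1("n_genes", 2L)
  count1("n_per_group", 2L)
  count1("n_gene_sets", 0L)
  count1("seed", -.Machine$integer.max)
  p <- cfg$probes_per_gene
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(p < 0) || sum(p) <= 0) {
    fail("probes_per_gene", "must be a count or non-negative weights")
  }
  if (length(p) == 1L && (p < 1 || p != round(p))) {
    fail("probes_per_gene", "a scalar value must be a positive integer")
  }
  if (!is.null(cfg$n_probes)) {
    count1("n_probes", 2L)
    if (cfg$n_probes < cfg$n_genes) fail("n_probes", "must be >= n_genes")
  }
  for (f in c("baseline_sd", "noise_sd")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0) {
      fail(f, "must be a single value >= 0")
    }
  }
  if (!is.numeric(cfg$de_fraction) || cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    fail("de_fraction", "must lie in [0, 1]")
  }
  if (!is.numeric(cfg$undetected_fraction) || cfg$undetected_fraction < 0 ||
      cfg$undetected_fraction >= 1) {
    fail("undetected_fraction", "must lie in [0, 1)")
  }
  if (!is.numeric(cfg$de_fold_changes) || length(cfg$de_fold_changes) < 1L ||
      any(cfg$de_fold_changes <= 0)) {
    fail("de_fold_changes", "all fold ratios must be > 0")
  }
  ssr <- cfg$set_size_range
  if (!is.numeric(ssr) || length(ssr) != 2L || any(ssr != round(ssr)) ||
      ssr[1] < 1L || ssr[1] > ssr[2]) {
    fail("set_size_range", "must be an increasing pair of positive counts")
  }
  if (ssr[2] > cfg$n_genes) {
    fail("set_size_range", "maximum set size exceeds n_genes")
  }
  if (!is.numeric(cfg$enriched_de_fraction) || cfg$enriched_de_fraction < 0 ||
      cfg$enriched_de_fraction > 1) {
    fail("enriched_de_fraction", "must lie in [0, 1]")
  }
  set_names <- sprintf("SET%02d", seq_len(cfg$n_gene_sets))
  if (!all(cfg$enriched_set_ids %in% set_names)) {
    fail("enriched_set_ids", sprintf("must be a subset of %s..%s",
                                     set_names[1] %||% "SET01",
                                     set_names[length(set_names)] %||% "SET00"))
  }
  invisible(cfg)
}

#' Simulate a two-condition expression experiment with known truth
#'
#' Draws a probes-by-samples log2 intensity matrix under the configured
#' design: per-probe Gaussian baselines, a true log2 shift of `log2(fold)`
#' added to the treated group's mean for probes of differential genes,
#' additive Gaussian noise per measurement, and a configured fraction of
#' (non-differential) probes shifted so all their values sit strictly below
#' the detection floor.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `mhg_sim`: `expr` (wide expression tibble),
#'   `groups` (sample/group tibble; groups are `"control"` and `"treated"`),
#'   and `truth` (per-probe tibble with `probe_id`, `gene_symbol`,
#'   `true_fold`, `is_de`, `below_floor`).
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 1))
#' sim$truth
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, 1L), simulate_expression_impl(config))
}

simulate_expression_impl <- function(cfg) {
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))

  ppg <- cfg$probes_per_gene
  if (length(ppg) == 1L) {
    counts <- rep.int(as.integer(ppg), cfg$n_genes)
  } else {
    counts <- sample.int(length(ppg), cfg$n_genes, replace = TRUE, prob = ppg)
  }
  if (!is.null(cfg$n_probes)) {
    counts <- fit_probe_total(counts, cfg$n_probes)
  }
  gene_of_probe <- rep(genes, counts)
  n_probes <- length(gene_of_probe)
  probe_ids <- sprintf("P%06d", seq_len(n_probes))

  # gene-level differential truth
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  de_genes <- resample(genes, n_de)
  fold_gene <- setNames(rep(1, cfg$n_genes), genes)
  if (n_de > 0L) {
    f <- resample(cfg$de_fold_changes, n_de, replace = TRUE)
    sign_down <- switch(cfg$de_direction,
      both = sample(c(TRUE, FALSE), n_de, replace = TRUE),
      up = rep(FALSE, n_de),
      down = rep(TRUE, n_de)
    )
    fold_gene[de_genes] <- ifelse(sign_down, 1 / f, f)
  }
  fold_probe <- fold_gene[gene_of_probe]
  is_de_probe <- gene_of_probe %in% de_genes

  np <- cfg$n_per_group
  samples <- c(sprintf("ctrl_%02d", seq_len(np)), sprintf("trt_%02d", seq_len(np)))
  groups <- tibble(sample = samples,
                   group = rep(c("control", "treated"), each = np))

  base <- rnorm(n_probes, cfg$baseline_mean, cfg$baseline_sd)
  mu <- cbind(matrix(base, n_probes, np),
              matrix(base + log2(fold_probe), n_probes, np))
  vals <- mu + matrix(rnorm(n_probes * 2 * np, 0, cfg$noise_sd), n_probes)

  # push a fraction of non-differential probes entirely below the floor
  n_under <- round(cfg$undetected_fraction * n_probes)
  under <- integer(0)
  if (n_under > 0L) {
    pool <- which(!is_de_probe)
    if (length(pool) < n_under) pool <- seq_len(n_probes)
    under <- resample(pool, min(n_under, length(pool)))
    shift <- apply(vals[under, , drop = FALSE], 1L, max) -
      (cfg$detection_floor - 0.1)
    vals[under, ] <- vals[under, ] - shift
  }
  below <- logical(n_probes)
  below[under] <- TRUE

  expr <- tibble(probe_id = probe_ids, gene_symbol = gene_of_probe)
  expr[samples] <- as.data.frame(vals)
  truth <- tibble(probe_id = probe_ids, gene_symbol = gene_of_probe,
                  true_fold = unname(fold_probe), is_de = is_de_probe,
                  below_floor = below)
  structure(list(expr = expr, groups = groups, truth = truth,
                 config = cfg), class = "mhg_sim")
}

# Nudge per-gene probe counts until they sum to the requested total.
fit_probe_total <- function(counts, total) {
  excess <- sum(counts) - total
  while (excess > 0L) {
    i <- which(counts > 1L)
    take <- head(i, excess)
    counts[take] <- counts[take] - 1L
    excess <- sum(counts) - total
    if (length(i) == 0L) abort("cannot reach `n_probes`: too few probes to trim.")
  }
  while (excess < 0L) {
    i <- head(seq_along(counts), -excess)
    counts[i] <- counts[i] + 1L
    excess <- sum(counts) - total
  }
  counts
}

#' @export
print.mhg_sim <- function(x, ...) {
  cat(sprintf("Synthetic expression experiment: %d probes / %d genes, %d + %d samples\n",
              nrow(x$expr), length(unique(x$expr$gene_symbol)),
              sum(x$groups$group == "control"), sum(x$groups$group == "treated")))
  cat(sprintf("  %d truly differential probes; %d below the detection floor\n",
              sum(x$truth$is_de), sum(x$truth$below_floor)))
  invisible(x)
}

#' Simulate gene sets over the genes of a synthetic experiment
#'
#' Null sets draw members uniformly from all genes; sets named in
#' `config$enriched_set_ids` draw a fraction `enriched_de_fraction` of their
#' members from the truly differential genes (the rest uniformly from the
#' others), so they concentrate near the top of the downstream significance
#' ranking. Set sizes are uniform over `set_size_range`.
#'
#' @param config A [sim_config()] object.
#' @param truth Per-probe truth tibble from [simulate_expression()] (gene
#'   flags are derived from it).
#' @return List with `sets` (long tibble: `set`, `gene`) and `set_truth`
#'   (tibble: `set`, `is_enriched`).
#'
#' @examples
#' cfg <- sim_config(n_genes = 100, n_gene_sets = 5,
#'                   enriched_set_ids = "SET01", seed = 2)
#' sim <- simulate_expression(cfg)
#' gs <- simulate_gene_sets(cfg, sim$truth)
#' table(gs$set_truth$is_enriched)
#' @export
simulate_gene_sets <- function(config, truth) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  if (!is.data.frame(truth) || !all(c("gene_symbol", "is_de") %in% names(truth))) {
    abort("`truth` must carry `gene_symbol` and `is_de` columns.")
  }
  with_seed(stage_seed(config$seed, 2L), {
    gene_truth <- dplyr::distinct(truth[c("gene_symbol", "is_de")])
    genes <- gene_truth$gene_symbol
    de_genes <- genes[gene_truth$is_de]
    if (max(config$set_size_range) > length(genes)) {
      abort("requested set size exceeds the number of simulated genes.")
    }
    set_names <- sprintf("SET%02d", seq_len(config$n_gene_sets))
    sets <- purrr::map(set_names, function(nm) {
      size <- resample(seq(config$set_size_range[1], config$set_size_range[2]), 1L)
      if (nm %in% config$enriched_set_ids && length(de_genes) > 0L) {
        n_hit <- min(round(config$enriched_de_fraction * size), length(de_genes))
        c(resample(de_genes, n_hit),
          resample(setdiff(genes, de_genes), size - n_hit))
      } else {
        resample(genes, size)
      }
    })
    list(
      sets = tibble(set = rep(set_names, lengths(sets)),
                    gene = unlist(sets)),
      set_truth = tibble(set = set_names,
                         is_enriched = set_names %in% config$enriched_set_ids)
    )
  })
}

#' Simulate a qPCR Ct table with known relative quantities
#'
#' Reference-gene Ct values are drawn identically in both groups; each
#' target's treated-group Ct is offset by `-log2(true_rq)` so that
#' delta-delta-Ct quantification recovers `true_rq`. Gaussian noise of SD
#' `ct_sd` cycles is added to every well.
#'
#' @param targets Character vector of target gene names.
#' @param true_rq True relative quantities (treated/control), recycled over
#'   targets; all > 0.
#' @param n Samples per group (>= 2); default 3.
#' @param ct_sd Per-well noise SD in cycles; default 0.2. Zero gives exact
#'   recovery.
#' @param seed Integer seed.
#' @param reference Endogenous control gene name; default `"GAPDH"`.
#' @param base_ct_target,base_ct_reference Control-group mean Ct for targets
#'   and reference; defaults 24 and 18 cycles.
#' @return A list of class `mhg_qpcr_sim` with `qpcr` (tibble: `sample_id`,
#'   `group`, `target`, `ct`) and `truth` (tibble: `target`, `true_rq`).
#'   [relative_quantity()] accepts either the list or the `qpcr` tibble.
#' @examples
#' simulate_qpcr(c("ALPL", "BMP2"), true_rq = c(6.06, 1.66), n = 3,
#'               ct_sd = 0, seed = 1)$truth
#' @export
simulate_qpcr <- function(targets, true_rq, n = 3, ct_sd = 0.2, seed = 1L,
                          reference = "GAPDH", base_ct_target = 24,
                          base_ct_reference = 18) {
  if (length(targets) < 1L) abort("need at least one target.")
  if (!is.numeric(true_rq) || any(true_rq <= 0)) {
    abort("`true_rq` must be positive (ratio scale).")
  }
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2L) {
    abort("`n` must be an integer >= 2.")
  }
  if (!is.numeric(ct_sd) || ct_sd < 0) abort("`ct_sd` must be >= 0.")
  true_rq <- rep_len(true_rq, length(targets))
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      group = c("control", "treated"), rep = seq_len(n),
      target = c(reference, targets)
    )
    grid$sample_id <- sprintf("%s_%02d", ifelse(grid$group == "control", "C", "T"),
                              grid$rep)
    offset <- setNames(c(0, -log2(true_rq)), c(reference, targets))
    base <- setNames(c(base_ct_reference, rep(base_ct_target, length(targets))),
                     c(reference, targets))
    grid$ct <- base[grid$target] +
      ifelse(grid$group == "treated", offset[grid$target], 0) +
      rnorm(nrow(grid), 0, ct_sd)
    structure(list(
      qpcr = tibble(sample_id = grid$sample_id, group = grid$group,
                    target = grid$target, ct = unname(grid$ct)),
      truth = tibble(target = targets, true_rq = true_rq)
    ), class = "mhg_qpcr_sim")
  })
}
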