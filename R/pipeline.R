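#' Run the full expression analysis pipeline
#'
#' Chains the stages end to end: (optionally) simulate an experiment, then
#' quantile-normalize, call detected probes, fit the SAM differential model
#' with permutation q-values, apply the fold-change/p reporting filter,
#' collapse probes to a ranked gene list, and test the gene-set collection
#' with the rank-order enrichment statistic. Stage defaults are the
#' pipeline's canonical settings: s0 percentile 75, minimum fold 1.2,
#' p <= 0.05, enrichment reporting at Bonferroni-adjusted p <= 0.01.
#'
#' Either supply `config` to run on simulated data (gene sets simulated from
#' the same configuration), or supply `expr`, `groups`, and `sets` for real
#' inputs. All randomness (simulation and permutations) descends from one
#' root seed, so identical inputs give identical outputs.
#'
#' @param config A [sim_config()]; ignored when `expr` is given.
#' @param expr,groups,sets Real inputs: expression tibble, sample/group
#'   tibble, gene sets (long tibble or named list).
#' @param threshold Detection threshold (log2), or `"auto"` (default) to use
#'   [suggest_threshold()] at `threshold_percentile`.
#' @param threshold_percentile Percentile for the automatic threshold;
#'   default 20.
#' @param filter_before_normalize Apply the detection filter before rather
#'   than after normalization; default `FALSE` (normalize first).
#' @param s0_percentile,n_permutations Passed to [sam_de()].
#' @param min_fold,max_p Passed to [filter_de()].
#' @param alpha,direction Passed to [enrich_collection()].
#' @param seed Root seed; defaults to `config$seed` when simulating, else 1.
#' @return A list of class `mhg_pipeline`: `expr` (normalized, detected
#'   probes), `detection`, `fit` (the `sam_fit`), `de_table`, `de_filtered`,
#'   `ranked`, `enrichment`, `truth`/`set_truth` (simulated runs only), and
#'   `manifest` — every stage parameter actually used plus stage row counts.
#' @examples
#' cfg <- sim_config(n_genes = 120, n_gene_sets = 5,
#'                   enriched_set_ids = "SET01", seed = 3)
#' res <- run_pipeline(cfg, n_permutations = 100)
#' res$enrichment
#' @export
run_pipeline <- function(config = NULL, expr = NULL, groups = NULL,
                         sets = NULL, threshold = "auto",
                         threshold_percentile = 20,
                         filter_before_normalize = FALSE,
                         s0_percentile = 75, n_permutations = 1000,
                         min_fold = 1.2, max_p = 0.05, alpha = 0.01,
                         direction = c("top", "literal"), seed = NULL) {
  direction <- match.arg(direction)
  simulated <- is.null(expr)
  if (simulated) {
    if (is.null(config)) abort("supply either `config` or `expr`+`groups`+`sets`.")
    if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
    seed <- seed %||% config$seed
    sim <- simulate_expression(config)
    gs <- simulate_gene_sets(config, sim$truth)
    expr <- sim$expr
    groups <- sim$groups
    sets <- gs$sets
  } else {
    if (is.null(groups) || is.null(sets)) {
      abort("`groups` and `sets` are required with `expr`.")
    }
    seed <- seed %||% 1L
  }

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }

  n_in <- nrow(expr)
  if (filter_before_normalize) {
    thr <- stage("detect", resolve_threshold(expr, threshold, threshold_percentile))
    detection <- stage("detect", detect_probes(expr, thr))
    norm <- stage("normalize", quantile_normalize(detection$detected))
  } else {
    norm <- stage("normalize", quantile_normalize(expr))
    thr <- stage("detect", resolve_threshold(norm, threshold, threshold_percentile))
    detection <- stage("detect", detect_probes(norm, thr))
    norm <- detection$detected
  }

  fit <- stage("differential",
               sam_de(norm, groups, s0_percentile = s0_percentile,
                      n_permutations = n_permutations,
                      seed = stage_seed(seed, 3L)))
  de_table <- tidy(fit)
  de_filtered <- stage("filter", filter_de(de_table, min_fold, max_p))
  ranked <- stage("collapse", collapse_probes(de_table, quiet = TRUE))
  enrichment <- stage("enrichment",
                      enrich_collection(ranked, sets, alpha = alpha,
                                        direction = direction))

  manifest <- list(
    package = "mhgsea",
    version = as.character(utils::packageVersion("mhgsea")),
    seed = seed, simulated = simulated,
    parameters = list(
      threshold = thr, threshold_requested = threshold,
      threshold_percentile = threshold_percentile,
      filter_before_normalize = filter_before_normalize,
      s0_percentile = s0_percentile, s0 = fit$s0,
      n_permutations = fit$n_permutations, exhaustive = fit$exhaustive,
      min_fold = min_fold, max_p = max_p, alpha = alpha,
      direction = direction
    ),
    counts = list(
      probes_in = n_in, probes_detected = sum(detection$calls$detected),
      probes_tested = nrow(de_table), probes_pass_filter = nrow(de_filtered),
      genes_ranked = nrow(ranked), sets_tested = attr(enrichment, "m"),
      sets_reported = sum(enrichment$reported)
    )
  )
  if (simulated) manifest$config <- unclass(config)

  out <- list(expr = norm, detection = detection, fit = fit,
              de_table = de_table, de_filtered = de_filtered,
              ranked = ranked, enrichment = enrichment, manifest = manifest)
  if (simulated) {
    out$truth <- sim$truth
    out$set_truth <- gs$set_truth
  }
  structure(out, class = "mhg_pipeline")
}

resolve_threshold <- function(expr, threshold, percentile) {
  if (identical(threshold, "auto")) {
    suggest_threshold(expr, percentile, histogram = FALSE)
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    threshold
  } else {
    abort("`threshold` must be a single number or \"auto\".")
  }
}

#' @export
print.mhg_pipeline <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("Expression analysis pipeline run\n")
  cat(sprintf("  probes: %d in, %d detected (threshold %.4g), %d pass the %.3g-fold / p<=%.3g filter\n",
              cnt$probes_in, cnt$probes_detected, x$manifest$parameters$threshold,
              cnt$probes_pass_filter, x$manifest$parameters$min_fold,
              x$manifest$parameters$max_p))
  cat(sprintf("  genes ranked: %d; gene sets tested: %d, reported at adjusted p<=%.3g: %d\n",
              cnt$genes_ranked, cnt$sets_tested, x$manifest$parameters$alpha,
              cnt$sets_reported))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Writes the normalized detected expression table, the differential table,
#' the filtered table, the ranked gene list, the enrichment table (TSVs) and
#' the JSON run manifest. Output is deterministic for a fixed configuration
#' and seed.
#'
#' @param result An `mhg_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  if (!inherits(result, "mhg_pipeline")) abort("`result` must come from run_pipeline().")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_tsv(result$expr, p("expression_normalized.tsv"))
  readr::write_tsv(result$de_table, p("differential.tsv"))
  readr::write_tsv(result$de_filtered, p("differential_filtered.tsv"))
  readr::write_tsv(result$ranked, p("ranked_genes.tsv"))
  enr <- result$enrichment
  readr::write_tsv(enr[setdiff(names(enr), c("member_ranks", "pk"))],
                   p("enrichment.tsv"))
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
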