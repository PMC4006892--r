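#' Volcano plot of a SAM fit
#'
#' Log2 fold change against -log10 permutation p-value, with probes passing
#' the fold/p reporting filter highlighted.
#'
#' @param object A [sam_de()] fit.
#' @param min_fold,max_p Reporting filter bounds used for the highlight;
#'   defaults 1.2 and 0.05.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sam_fit <- function(object, min_fold = 1.2, max_p = 0.05, ...) {
  tab <- object$table
  tab$significant <- pmax(tab$fold_change, 1 / tab$fold_change) >= min_fold &
    tab$p_perm <= max_p
  ggplot2::ggplot(tab, ggplot2::aes(x = log2(.data$fold_change),
                                    y = -log10(.data$p_perm),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-log2(min_fold), log2(min_fold)),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(max_p), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = sprintf(">=%.3g-fold, p<=%.3g",
                                                min_fold, max_p)) +
    ggplot2::labs(x = "log2 fold change (treated / control)",
                  y = "-log10 permutation p") +
    ggplot2::theme_minimal()
}

#' Bar chart of gene-set enrichment results
#'
#' -log10 Bonferroni-adjusted p-value per set, reported sets filled.
#'
#' @param object An [enrich_collection()] result.
#' @param top Show at most this many sets (by adjusted p); default 20.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mhg_enrichment <- function(object, top = 20, ...) {
  tab <- as_tibble(object)[seq_len(min(top, nrow(object))), ]
  tab <- tab[tab$testable, , drop = FALSE]
  tab$set <- factor(tab$set, rev(tab$set))
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(tab, ggplot2::aes(x = -log10(.data$p_adjusted), y = .data$set,
                                    fill = .data$reported)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "steelblue"),
                               name = sprintf("adjusted p <= %.3g", alpha)) +
    ggplot2::labs(x = "-log10 Bonferroni-adjusted p", y = NULL) +
    ggplot2::theme_minimal()
}

#' Relative-quantity bar chart with SEM error bars
#'
#' One bar per target at its relative quantity (treated vs control,
#' RQ = 2^-ddCt), with the treated-group standard error of the mean as the
#' error bar and the control baseline RQ = 1 as a dashed line.
#'
#' @param object A [relative_quantity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qpcr_result <- function(object, ...) {
  tab <- as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$target, y = .data$rq)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rq - .data$sem_treated,
                                        ymax = .data$rq + .data$sem_treated),
                           width = 0.15) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = sprintf("relative quantity (2^-ddCt vs %s)",
                                        attr(object, "reference") %||% "reference")) +
    ggplot2::theme_minimal()
}
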