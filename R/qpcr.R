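#' Delta-delta-Ct relative quantification
#'
#' Livak-style relative quantification against an endogenous control gene.
#' For each sample, \eqn{\Delta CT = CT_{target} - CT_{reference}} (replicate
#' wells averaged); per target, \eqn{\Delta\Delta CT} is the difference of
#' treated and control group means of \eqn{\Delta CT}, and the relative
#' quantity is \eqn{RQ = 2^{-\Delta\Delta CT}} (perfect doubling assumed).
#' Significance is a two-sided unpaired Student t-test (equal variances) on
#' the per-sample \eqn{\Delta CT} values. Error bars are standard errors of
#' the mean of the per-sample relative quantities \eqn{2^{-(\Delta CT_i -
#' \overline{\Delta CT}_{control})}}, i.e. on the RQ scale (recorded in the
#' output as `sem_scale`).
#'
#' @param qpcr Long Ct table: tibble with `sample_id`, `group`, `target`,
#'   `ct` (cycles), e.g. from [simulate_qpcr()] or [read_qpcr_tsv()].
#' @param targets Targets to quantify; default all non-reference targets in
#'   the table.
#' @param reference Endogenous control gene; default `"GAPDH"`.
#' @param control,treated Group labels; by default `"control"` (or the first
#'   group seen) is the baseline.
#' @return A tibble of class `qpcr_result`, one row per target: `target`,
#'   `n_control`, `n_treated`, `ddct`, `rq`, `change` (the human-readable
#'   report, see [report_change()]), `sem_control`, `sem_treated`,
#'   `statistic`, `p_value`. `autoplot()` draws RQ bars with SEM error bars.
#' @examples
#' qt <- simulate_qpcr("ALPL", true_rq = 0.5, n = 3, ct_sd = 0, seed = 1)
#' relative_quantity(qt) # ddct = 1, rq = 0.5
#' @export
relative_quantity <- function(qpcr, targets = NULL, reference = "GAPDH",
                              control = NULL, treated = NULL) {
  if (inherits(qpcr, "mhg_qpcr_sim")) qpcr <- qpcr$qpcr
  check_qpcr(qpcr)
  if (!reference %in% qpcr$target) {
    abort(sprintf("reference gene \"%s\" has no wells in the table.", reference))
  }
  lev <- unique(as.character(qpcr$group))
  if (length(lev) != 2L) {
    abort(sprintf("exactly two groups are required, found: %s.",
                  paste(lev, collapse = ", ")))
  }
  if (is.null(control)) control <- if ("control" %in% lev) "control" else lev[1L]
  if (is.null(treated)) treated <- setdiff(lev, control)
  if (!all(c(control, treated) %in% lev)) {
    abort("`control`/`treated` must name groups present in the table.")
  }
  if (is.null(targets)) targets <- setdiff(unique(qpcr$target), reference)
  if (length(targets) == 0L) abort("no target genes to quantify.")

  # mean Ct per (sample, target) so replicate wells collapse first
  ct <- dplyr::summarise(
    dplyr::group_by(qpcr, .data$sample_id, .data$group, .data$target),
    ct = mean(.data$ct), .groups = "drop"
  )
  ref <- ct[ct$target == reference, c("sample_id", "ct")]
  names(ref)[2L] <- "ct_ref"

  out <- purrr::map(targets, function(tg) {
    tw <- ct[ct$target == tg, , drop = FALSE]
    if (nrow(tw) == 0L) abort(sprintf("target \"%s\" has no wells.", tg))
    noref <- setdiff(tw$sample_id, ref$sample_id)
    if (length(noref) > 0L) {
      abort(sprintf("samples lack reference (%s) wells: %s",
                    reference, paste(noref, collapse = ", ")))
    }
    tw <- dplyr::left_join(tw, ref, by = "sample_id")
    dct <- tw$ct - tw$ct_ref
    dct_c <- dct[tw$group == control]
    dct_t <- dct[tw$group == treated]
    if (length(dct_c) < 2L || length(dct_t) < 2L) {
      abort(sprintf("target \"%s\": need >= 2 samples per group (found %d control, %d treated).",
                    tg, length(dct_c), length(dct_t)))
    }
    ddct <- mean(dct_t) - mean(dct_c)
    # RQ-scale per-sample quantities, each group relative to the control mean
    rq_c <- 2^(-(dct_c - mean(dct_c)))
    rq_t <- 2^(-(dct_t - mean(dct_c)))
    if (sd(dct_c) == 0 && sd(dct_t) == 0) {
      stat <- if (ddct == 0) 0 else Inf * sign(ddct)
      p <- if (ddct == 0) 1 else 0
    } else {
      tt <- t.test(dct_t, dct_c, var.equal = TRUE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    tibble(
      target = tg, n_control = length(dct_c), n_treated = length(dct_t),
      ddct = ddct, rq = 2^(-ddct), change = report_change(2^(-ddct)),
      sem_control = sd(rq_c) / sqrt(length(rq_c)),
      sem_treated = sd(rq_t) / sqrt(length(rq_t)),
      statistic = stat, p_value = p
    )
  })
  out <- dplyr::bind_rows(out)
  structure(out, class = c("qpcr_result", class(tibble())),
            reference = reference, control = control, treated = treated,
            sem_scale = "RQ")
}

check_qpcr <- function(qpcr) {
  need <- c("sample_id", "group", "target", "ct")
  if (!is.data.frame(qpcr) || !all(need %in% names(qpcr))) {
    abort(sprintf("`qpcr` must have columns %s.", paste(need, collapse = ", ")))
  }
  if (nrow(qpcr) == 0L) abort("`qpcr` table is empty.")
  if (!is.numeric(qpcr$ct) || anyNA(qpcr$ct)) {
    abort("`ct` must be numeric with no missing values.")
  }
  invisible(qpcr)
}

#' Report a relative quantity the way figure legends do
#'
#' Mirrors the mixed reporting convention of expression figure legends:
#' ratios below 1 are percent decreases (`(1 - RQ) x 100`), ratios between 1
#' and 2 are percent increases (`(RQ - 1) x 100`), and ratios of 2 or more
#' are reported as fold increases.
#'
#' @param rq Relative quantity (ratio), strictly positive. Vectorized.
#' @return Character vector, e.g. `"69.3% decrease"`, `"66% increase"`,
#'   `"6.06 fold increase"`.
#' @examples
#' report_change(c(0.307, 1.0, 1.66, 6.06))
#' @export
report_change <- function(rq) {
  if (!is.numeric(rq) || length(rq) == 0L || anyNA(rq) || any(rq <= 0)) {
    abort("`rq` must be positive.")
  }
  fmt <- function(x) {
    vapply(x, function(v) format(signif(v, 3), trim = TRUE, scientific = FALSE),
           character(1))
  }
  dplyr::case_when(
    rq == 1 ~ "0% change",
    rq < 1  ~ paste0(fmt((1 - rq) * 100), "% decrease"),
    rq < 2  ~ paste0(fmt((rq - 1) * 100), "% increase"),
    TRUE    ~ paste0(fmt(rq), " fold increase")
  )
}
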