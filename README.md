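# mhgsea

Rank-order gene-set enrichment and SAM-style differential analysis for
two-condition expression arrays, with ΔΔCT qPCR quantification and a
synthetic-data generator with known ground truth.

## The problem

Small two-condition expression experiments — an siRNA knockdown versus a
scramble control on a bead array, a stretched versus static cell culture —
need a compact analysis chain: put samples on a common intensity scale,
discard probes that never rise above background, rank probes by a
variance-moderated differential statistic, and then ask which *gene sets*
concentrate at the top of that ranking. `mhgsea` implements that chain as a
pipeable, tibble-first R package, every stage testable against simulated
data where the truth is known.

## The statistics

**SAM differential statistic.** For probe *i* with group means
$\bar{x}_T, \bar{x}_C$ and pooled standard error $s_i$,

$$d_i = \frac{\bar{x}_T - \bar{x}_C}{s_i + s_0}, \qquad
s_i = \sqrt{\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)
\frac{\sum_C (x-\bar{x}_C)^2 + \sum_T (x-\bar{x}_T)^2}{n_1+n_2-2}}$$

where the exchangeability factor $s_0$ is the 75th percentile of the $s_i$,
guarding against probes with accidentally tiny variance. Group labels are
permuted (exhaustively when few enough relabelings exist) to get per-probe
permutation p-values and q-values — the smallest false discovery rate at
which a probe is called significant, with the FDR at a cutoff estimated as
the median permuted exceedance count over the observed call count.

**Minimum-hypergeometric (min-k) enrichment.** Probes are collapsed to
genes (best probe per gene) and ranked $1..N$ by q. For a set whose members
sit at ranks $r_1 < \dots < r_n$, each

$$p_k = P(\text{at least } k \text{ of } n \text{ random ranks fall within the top } r_k)$$

is a hypergeometric upper tail, and the set's p-value is $\min_k p_k$ —
sensitive to overrepresentation anywhere near the top of the list. Raw set
p-values are Bonferroni-adjusted over the number of testable sets and sets
with adjusted $p \le 0.01$ are flagged as reported.

**ΔΔCT quantification.** Per sample, $\Delta CT = CT_{target} -
CT_{reference}$ (GAPDH by default); per target, $\Delta\Delta CT$ is the
difference of group means and $RQ = 2^{-\Delta\Delta CT}$, with a Student
t-test on the per-sample $\Delta CT$ and SEM error bars on the RQ scale.

## Worked example

```r
library(mhgsea)

cfg <- sim_config(n_genes = 500, de_fraction = 0.1, de_fold_changes = 2,
                  n_gene_sets = 10, enriched_set_ids = "SET01", seed = 42)
res <- run_pipeline(cfg)
res
#> Expression analysis pipeline run
#>   probes: 767 in, 644 detected (threshold 6.069), 98 pass the 1.2-fold / p<=0.05 filter
#>   genes ranked: 449; gene sets tested: 10, reported at adjusted p<=0.01: 1

head(as.data.frame(res$enrichment[, 1:6]), 2)
#>     set  n k_star        p_raw   p_adjusted reported
#> 1 SET01 37     29 1.325924e-26 1.325924e-25     TRUE
#> 2 SET06 24     10 1.472324e-02 1.472324e-01    FALSE
```

The 500 simulated genes include 50 truly differential at 2-fold; `SET01`
was built with 80% of its members drawn from those genes. The pipeline
quantile-normalizes, drops probes never exceeding the 20th-percentile
intensity threshold (6.07 log2 units here), fits the SAM model with
s0 at the 75th percentile of per-probe scatter, and the spiked set is the
only one surviving the Bonferroni-adjusted 0.01 reporting rule — at
adjusted p ≈ 1.3 × 10⁻²⁵, 24 orders of magnitude clear of the nearest
null set. `tidy(res$fit)` exposes the per-probe table (d, fold change,
permutation p, q), `autoplot(res$fit)` the volcano plot, and
`autoplot(res$enrichment)` the enrichment bars.

qPCR quantification works from a long Ct table:

```r
qt <- simulate_qpcr(c("ALPL", "BMP2"), true_rq = c(6.06, 1.66),
                    n = 3, ct_sd = 0.15, seed = 42)
relative_quantity(qt)[, c("target", "rq", "change", "p_value")]
#>   target       rq             change      p_value
#> 1   ALPL 5.038253 5.04 fold increase 6.370169e-05
#> 2   BMP2 1.573048     57.3% increase 7.158745e-02
```

With triplicates and 0.15-cycle noise the true ratios (6.06 and 1.66) are
recovered as 5.04 and 1.57; ratios ≥ 2 are reported as fold increases and
smaller ones as percent changes, the usual figure-legend convention.

## Layout

- `R/` — simulation (`sim_config`, `simulate_*`), preprocessing
  (`quantile_normalize`, `detect_probes`, `suggest_threshold`),
  differential analysis (`sam_de`, `compute_s0`, `filter_de`), enrichment
  (`collapse_probes`, `order_statistic_tail`, `gene_set_pvalue`,
  `enrich_collection`), qPCR (`relative_quantity`, `report_change`), IO
  (`read_/write_` TSV and GMT), and the `run_pipeline` orchestrator.
- `vignettes/mhgsea-methods.Rmd` — the model, its assumptions, parameter
  choices, and known limitations.
- `tests/testthat/` — unit, property, and end-to-end calibration tests.
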