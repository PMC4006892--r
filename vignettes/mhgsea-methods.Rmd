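---
title: "Methods: rank-order enrichment for two-condition arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-order enrichment for two-condition arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhgsea)
```

`mhgsea` analyzes small two-condition expression experiments end to end:
normalization, detection filtering, moderated differential statistics with
permutation-based error control, probe-to-gene collapsing, and a rank-order
gene-set enrichment statistic from the minimum-hypergeometric family,
together with ΔΔCT qPCR quantification. This vignette explains each model,
the tunable parameters and their defaults, the synthetic-data generator the
test suite relies on, and the numerical and design choices that were
genuinely open.

## Quantile normalization

All samples are forced onto one intensity distribution: the value at
within-sample rank $j$ is replaced by the mean across samples of the $j$-th
order statistics. The transform assumes samples are technically comparable
and that distributional differences are artefactual — reasonable for
replicate bead arrays of the same tissue, wrong if conditions genuinely
shift the whole expression distribution.

*Ties.* Tied values within a sample receive the mean of the target order
statistics over their tied rank span. This keeps the transform
rank-preserving and exactly idempotent on tie-free data. One subtlety
follows: with ties, a column containing a tie collapses part of the target
distribution to its mean, so the "all columns share one sorted vector"
property holds exactly only for tie-free data; continuous intensities make
ties measure-zero in practice. The test suite asserts the shared-multiset
and idempotence properties on tie-free matrices and the tie convention on a
dedicated tied fixture.

Inputs are assumed to be log2-scale; `log2_transform = TRUE` applies
$\log_2(x+1)$ for raw intensities.

## Detection filtering

A probe is *detected* if its intensity strictly exceeds a threshold in at
least one sample. "Exceeds" is read as a strict inequality, and the
boundary behaviour is tested. Thresholds for bead arrays are classically
picked by eye from the pooled log-intensity histogram; `suggest_threshold()`
makes that reproducible by returning a percentile (default the 20th) of the
pooled distribution — type 7 interpolation, the same convention used for
s0 — while still printing a text histogram for visual inspection. Whether
filtering precedes or follows normalization is a config flag
(`filter_before_normalize`, default `FALSE`: normalize first, so the
threshold refers to the common normalized scale).

## SAM differential statistic and permutation FDR

The two-class unpaired statistic is $d_i = (\bar{x}_{T,i} - \bar{x}_{C,i}) /
(s_i + s_0)$ with $s_i$ the pooled standard error. At $s_0 = 0$ and equal
group sizes this is exactly the classical pooled-variance t statistic
(asserted numerically in the tests). $s_0$, the exchangeability factor, is a
percentile — default the 75th — of the per-probe $s_i$ values, applied to
the quantity the denominator actually uses; it damps the statistic of
probes whose variance is accidentally tiny.

Error control is permutation-based. Group labels are relabeled exhaustively
whenever at most 2000 distinct relabelings exist (at the default 3 + 3
design that is all $\binom{6}{3} = 20$), otherwise by `n_permutations`
(default 1000) seeded random draws. Two quantities come out:

* **q-values**: for each cutoff $\delta$ in a grid of 50 evenly spaced
  values from 0 to $\max|d|$, the estimated FDR is the median over
  relabelings of the count of $|d^*| \ge \delta$, divided by the observed
  call count; a probe's q is the minimum FDR over the cutoffs at which it
  is called. The min-over-cutoffs construction makes q monotone in $|d|$ by
  design.
* **permutation p-values**: the fraction of $|d^*|$, pooled across probes
  and relabelings, at or above the observed $|d|$, with add-one smoothing
  $(b+1)/(B+1)$ so no p is exactly zero. Pooling assumes probes share a
  common null scale — true in the generator (equal noise for all probes)
  and approximately true after $s_0$ moderation on real arrays.

The reporting filter keeps probes altered at least 1.2-fold in either
direction with $p \le 0.05$, both boundaries inclusive.

## Probe collapsing and the min-k enrichment statistic

Probes are sorted by q (ties: $|d|$ descending, then probe id — a
deterministic total order), each gene keeps its best probe, and the
surviving genes are re-ranked $1..N$. Probes without a gene identifier
cannot be ranked and are dropped with a logged count.

For a set with member ranks $r_1 < \dots < r_n$ in that list, $p_k$ is the
probability that at least $k$ of $n$ uniformly drawn ranks (without
replacement) land within the top $r_k$ — the upper tail of a
hypergeometric count — and the set p-value is $p_{raw} = \min_k p_k$. The
minimum adapts to however many members concentrate at the top; no
correction is applied across $k$ because the $n$ tail tests are strongly
dependent. Raw p-values are Bonferroni-adjusted over the number $m$ of
*testable* sets (non-empty intersection with the ranked list; empty sets
are flagged and excluded from $m$), and sets with adjusted $p \le 0.01$ are
flagged `reported`.

*Direction of the inequality.* The statistic is stated in terms of the
"k-th highest" rank; with ranks running 1 = most significant, a literal
lowest-tail reading would reward sets at the *bottom* of the list, the
opposite of the statistic's purpose of detecting overrepresentation at the
top. The default (`direction = "top"`) therefore tests concentration at the
top; the mirrored literal reading is available as `direction = "literal"`
for comparison. This was a genuinely open choice and the package picks the
purpose-consistent reading.

*Null behaviour — an important caveat.* $p_{raw}$ is a minimum of dependent
tails and is **not** uniform under the null: near its lower tail it is
roughly an order of magnitude smaller than uniform at typical set sizes
(10–40). Bonferroni adjustment therefore bounds the expected number of
false reports only up to that inflation factor; across 100 simulated null
pipelines with 20 null sets each, roughly one run in ten reports a single
set at adjusted $p \le 0.01$. The adjusted value is a ranking and reporting
device, not an exact family-wise error guarantee. Users who need strict
null calibration should recalibrate $p_{raw}$ against its simulated null
(the generator makes this cheap).

*Numerics.* $p_k$ is computed by summing hypergeometric terms in log space
(log-gamma binomial coefficients, max-shifted exponentiation), exact to
near machine precision; the tests verify equality with exhaustive
enumeration for all $N \le 12, n \le 4$ and with the hypergeometric tail
function at $N$ up to 2000. Ties for the minimizing $k$ break toward the
smallest $k$; output ordering is by (adjusted p, set name).

## ΔΔCT quantification

Per sample, $\Delta CT = CT_{target} - CT_{reference}$ (replicate wells
averaged first; GAPDH is the default endogenous control). Per target,
$\Delta\Delta CT$ is the treated-minus-control difference of group means of
$\Delta CT$ and $RQ = 2^{-\Delta\Delta CT}$, assuming perfect doubling per
cycle — no efficiency correction. Significance is a two-sided unpaired
Student t-test (equal variances) on per-sample $\Delta CT$; with zero
variance in both groups the statistic is defined as 0 (equal means) to keep
the degenerate noise-free case exact. Error bars could be computed on the
$\Delta CT$, $\Delta\Delta CT$ or RQ scale; the package reports SEM of
per-sample quantities on the **RQ scale** (each sample anti-logged relative
to the control mean), records the choice in the result's `sem_scale`
attribute, and leaves the other scales one line of arithmetic away.
`report_change()` renders ratios the way expression figure legends usually
do: percent decrease below 1, percent increase up to 2-fold, "x.xx fold"
beyond.

## The synthetic-data generator

`simulate_expression()` emulates a small two-condition bead-array
experiment; it is the package's test bed, not a bead-level simulator.

| parameter | default | why |
|---|---|---|
| `n_per_group` | 3 | triplicate arrays, the replicate scale typical of these designs |
| `baseline_mean`, `baseline_sd` | 8, 1.5 log2 units | plausible normalized bead-array intensity spread |
| `noise_sd` | 0.3 log2 units | additive Gaussian measurement noise on the log scale, standard for normalized intensities |
| `de_fraction` | 0.1 | a modest knockdown footprint |
| `de_fold_changes` | 1.2–2.0 | the fold-change range typical of reported hits in such experiments |
| `probes_per_gene` | weights (0.6, 0.3, 0.1) on 1–3 | exercises the collapsing rule without dominating it |
| `detection_floor` / `undetected_fraction` | 5 / 0.1 | a tenth of probes shifted *entirely* below the floor, making the detection filter deterministic and testable |

Differential genes get a true log2 shift of $\log_2(\text{fold})$ added to
the treated group mean before noise; undetected probes are drawn from the
non-differential pool and hard-shifted so their maximum sits just below the
floor. Gene sets are uniform draws, except sets named in
`enriched_set_ids`, which draw 80% of members (configurable) from the truly
differential genes. qPCR simulation offsets the treated target Ct by
$-\log_2(RQ_{true})$ with group-independent reference Ct.

What the generator does *not* model — probe-specific variances, intensity-
dependent noise, batch and chip effects, correlated genes, qPCR efficiency
below 2 — bounds what passing tests show: they certify the statistics and
their calibration under a clean null, not robustness to real-array
artefacts.

All randomness descends from one root seed, split per stage, so identical
configurations are byte-identical; simulation restores the caller's RNG
state.

## Problem sizes used in the checks

The calibration and recovery checks run at the scale the methods are meant
for: 1000-probe null experiments (3 + 3 samples, exhaustive relabelings)
for permutation-p calibration across 5 seeds, 100 seeded null pipelines for
the reporting-rule null rate, and 100 seeded spiked pipelines (500 genes,
10% differential at 2-fold, one set with 80% differential members) for
recovery — the spiked set attains the smallest adjusted p in every run.

## Known limitations

* The Bonferroni-on-$\min_k p_k$ reporting rule is mildly anti-conservative
  under the null (see above); the package reports it as specified but the
  caveat stands.
* Only two-class unpaired designs: no paired, multi-class, or survival
  modes, and no variance shrinkage beyond $s_0$.
* No background correction, batch correction, or bead-level summarization;
  inputs are assumed probe-summarized and on a comparable scale.
* Gene identifiers are matched as plain strings; no identifier-mapping
  service is consulted.
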