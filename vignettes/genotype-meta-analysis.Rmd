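---
title: "Pooling case-control genotype counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling case-control genotype counts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The problem

A single case-control study of a candidate single-nucleotide polymorphism
reports three genotype counts per arm: common homozygotes (AA),
heterozygotes (Aa) and variant homozygotes (aa). Individual studies are
usually underpowered, so evidence is combined across studies by
meta-analysis of odds ratios. snpmeta implements that pipeline end to end:
genotype collapse under the five standard genetic contrasts, per-study
odds-ratio estimation, fixed- and random-effects pooling with a
heterogeneity-guided choice between them, cancer-type (or any other label)
subgroup analysis, leave-one-out sensitivity analysis, and a rank-correlation
check for publication bias. A bundled corpus of published studies of the
CRP promoter/intronic variants rs2808630 and rs1417938 exercises the whole
chain, and a genotype-count simulator with known truth validates it.

## Genetic contrasts

Because the mode of inheritance is unknown a priori, the three genotype
classes are dichotomized five ways, each giving a 2x2 table of
exposed/unexposed by case/control ($a, b$ exposed/unexposed cases; $c, d$
exposed/unexposed controls):

| contrast     | exposed        | unexposed      |
|--------------|----------------|----------------|
| `recessive`  | aa             | Aa + AA        |
| `dominant`   | aa + Aa        | AA             |
| `codom_hom`  | aa             | AA             |
| `codom_het`  | Aa             | AA             |
| `allele`     | a (2·aa + Aa)  | A (2·AA + Aa)  |

The allele contrast counts two alleles per subject as independent
observations, the usual additive-model convention; its margins are twice the
subject totals. The codominant contrasts drop the omitted genotype class
entirely. All five derive from one stored record — counts are never
pre-collapsed, so a corpus supports every contrast without re-extraction.

The variant allele is always treated as the exposure, exactly as the counts
are recorded. No minor-allele re-orientation is attempted: in two bundled
rs1417938 studies the variant allele is in fact the majority allele, and
re-orienting would silently invert those odds ratios.

## Per-study estimation

For each 2x2 table the crude odds ratio is the cross-product $ad/bc$; its
log has the Woolf (delta-method) variance

$$v = \frac1a + \frac1b + \frac1c + \frac1d .$$

Confidence intervals are computed on the log scale,
$\hat\theta \pm z_{1-\alpha/2}\sqrt{v}$ (with $z = 1.959964$ at the default
95% level), then exponentiated — they are asymmetric around the odds ratio,
never around it symmetric on the ratio scale.

**Zero cells.** A table containing a zero has an undefined log odds ratio or
variance. `apply_continuity()` adds the Haldane–Anscombe increment (default
0.5) to *all four cells* of any table containing a zero; tables without
zeros are untouched, and the correction is per table, not corpus-wide. A
study with an empty case or control margin under a contrast (for example,
no variant homozygotes in either arm) carries no information about that
contrast and is rejected with an error rather than corrected.

## Pooling

With per-study log odds ratios $\hat\theta_i$ and variances $v_i$:

* **Fixed effect, inverse variance** (`pool_fixed()`): weights $w_i = 1/v_i$,
  $\hat\theta = \sum w_i \hat\theta_i / \sum w_i$,
  $\mathrm{se} = 1/\sqrt{\sum w_i}$.
* **Heterogeneity** (`heterogeneity()`): Cochran's
  $Q = \sum w_i (\hat\theta_i - \hat\theta)^2$, referred to
  $\chi^2_{k-1}$ for $P_h$ (undefined at $k = 1$);
  $I^2 = \max(0, (Q - df)/Q)$; DerSimonian–Laird moment estimate
  $\hat\tau^2 = \max\!\big(0, (Q - df)\,/\,(\textstyle\sum w_i - \sum
  w_i^2/\sum w_i)\big)$. Q is always computed with fixed-effect weights
  around the fixed-effect pooled value, also when the random-effects model
  is ultimately reported.
* **Random effects, DerSimonian–Laird** (`pool_random()`): starred weights
  $w_i^* = 1/(v_i + \hat\tau^2)$, otherwise as above. When $\hat\tau^2 = 0$
  it coincides with the fixed-effect result in every number.
* **Mantel–Haenszel** (`pool_mh()`): pools the tables directly,
  $\hat\theta = \log\big(\sum a_i d_i/N_i \,/\, \sum b_i c_i/N_i\big)$, with
  the Robins–Breslow–Greenland variance.

**Model selection** (`pool_auto()`, used by `run_meta()` for every cell):
random effects if $P_h < \alpha_h$ (default 0.05), fixed effect otherwise;
a single study is always reported as fixed. $I^2$ and $\tau^2$ are reported
but play no role in the choice.

**Which fixed-effect engine?** The default is inverse variance. But the
analysis that motivated the bundled corpus was run in Stata, whose `metan`
command pools count data by Mantel–Haenszel, applying the 0.5 correction to
zero-cell studies and using the corrected counts throughout.
`run_meta(fixed_method = "mh")` mirrors that convention and reproduces the
published pooled table to its printed two decimals; the inverse-variance
default agrees with it to about 1% (the engines differ only in the second
decimal on these data, e.g. 0.865 vs 0.859 for the overall rs2808630
recessive pool). `pool_mh(correct = FALSE)` gives the classical raw-count
Mantel–Haenszel estimate, which needs no zero-cell correction for its point
estimate (0.850 on the same cell).

On two subgroup cells the recomputed heterogeneity $P_h$ lands 0.005–0.01
from the published value under every engine combination we examined
(0.815 vs 0.82; 0.785 vs 0.79) — a last-digit disagreement in the published
table itself, documented here rather than chased.

## Subgroups, sensitivity, publication bias

`run_meta()` evaluates every contrast in every stratum of a grouping
variable (default `cancer_type`) plus an all-studies Total; strata are taken
from the data, not a fixed list. `leave_one_out()` re-pools $k$ times,
omitting one study each time, re-applying the full fixed/random rule after
each exclusion (the choice may flip). Stability is judged by confidence
intervals: no leave-one-out interval should fail to overlap the full-corpus
interval.

`begg_test()` quantifies funnel asymmetry: each effect is standardized
against the fixed-effect pool,
$t_i = (\hat\theta_i - \hat\theta_F)/\sqrt{v_i - 1/\sum w}$, and Kendall's
rank correlation between $t_i$ and $v_i$ is tested with the
continuity-corrected normal deviate
$z = (|S| - 1)/\sqrt{k(k-1)(2k+5)/18}$ (two-sided). Tau uses tau-b tie
handling; the variance term keeps the untied formula, adequate because ties
in continuous variances are rare. If all variances are tied the test is
degenerate and reported as $\tau = 0$, $p = 1$ with a warning. With fewer
than three studies the test runs but is flagged as having very low power.
`funnel_data()` emits the plot-ready points (log odds ratio vs standard
error) with the pooled centre and pseudo-95% limit curves.

## The simulator

`simulate_corpus()` generates corpora whose truth is known exactly:

* Controls are multinomial draws from Hardy–Weinberg proportions
  $((1-p)^2,\, 2p(1-p),\, p^2)$ at variant-allele frequency $p$.
* Cases are multinomial draws from the control distribution tilted by
  genotype odds ratios: probabilities proportional to
  $(P_{AA},\, P_{Aa}\psi_{het},\, P_{aa}\psi_{hom})$. Tilting is the
  retrospective equivalent of a prospective logistic model, so collapsed
  population odds ratios are controlled exactly — in particular the
  recessive odds ratio equals $\psi_{hom}$ exactly when $\psi_{het} = 1$.
* Between-study heterogeneity of standard deviation $\tau$ perturbs the
  variant-homozygote log odds ratio, so with $\psi_{het} = 1$ the true
  recessive log odds ratio of study $i$ is exactly
  $N(\log\psi_{hom}, \tau^2)$. Other contrasts inherit attenuated
  heterogeneity; a study design needing exact heterogeneity on, say, the
  dominant scale is out of scope.
* An optional selection rule publishes a small study (case arm at most
  `max_n`) only if its crude continuity-corrected recessive odds ratio
  exceeds `or_threshold` — the minimal mechanism that produces funnel
  asymmetry and gives the rank-correlation test something to detect.
* `seed` is a required argument; generation is a pure function of the
  configuration and seed, and the caller's RNG stream is saved and restored.

Arm sizes and allele frequency accept either a fixed value or a
`c(lo, hi)` range drawn independently per study.

What the simulator deliberately omits: Hardy–Weinberg violations in
controls, linkage disequilibrium between variants, covariates and
gene–environment interaction, population stratification, and genotyping
error. Passing calibration tests on simulated corpora therefore validates
the estimators and the pipeline plumbing, not robustness to those
real-data complications.

## Calibration choices

The validation suite checks, among other properties:

* parameter recovery — over 500 replicate corpora of $k = 20$ studies with
  2000 subjects per arm, $p = 0.3$, true recessive odds ratio 1.5, the mean
  pooled log odds ratio sits within three Monte-Carlo standard errors of
  $\log 1.5$;
* null calibration — on 500 null corpora (odds ratio 1, $\tau = 0$) the
  Q test rejects at close to its nominal 5% and the rank-correlation test's
  type-I error stays near nominal at $k = 20$;
* $\tau^2$ recovery at $k = 50$ studies of 5000 per arm;
* Mantel–Haenszel and inverse-variance pooled log odds ratios agreeing to
  within 0.01 on corpora of $10^5$ subjects per arm.

These problem sizes were chosen as the smallest at which the asymptotic
behaviour being checked is visibly established; they run in well under a
minute.

## Numerical and degenerate-input conventions

* Normal quantile at 95%: 1.959964 (from `qnorm`, never hard-coded 1.96).
* Continuity increment 0.5, per table with any zero cell; configurable.
* Display rounding in `format_report()` is half-even at two decimals;
  all computations and tests use unrounded values.
* A single-study pool reports its study verbatim, with $P_h$ undefined
  (rendered `NA`).
* Validation is strict: counts must be non-negative integers, both arms
  must genotype at least one subject, study identifiers must be unique, and
  ethnicity labels come from the closed set Caucasian/African/Asian/Mixed
  (title-cased on load, as are cancer-type labels).

## Known limitations

Estimates are crude (unadjusted) odds ratios from published counts;
individual-level confounder adjustment is impossible in this design. No
Hardy–Weinberg equilibrium test is applied to control arms, and no study is
excluded on that basis. Intervals are asymptotic — no exact conditional or
mid-p intervals, which matters for very sparse tables beyond what the 0.5
correction handles. Heterogeneity estimation uses only the
DerSimonian–Laird moment estimator (no REML or Paule–Mandel) and no
Hartung–Knapp small-$k$ adjustment, matching the conventions of the
analyses this package reproduces. Publication-bias assessment is limited to
the Begg–Mazumdar test and funnel data; Egger-type regressions and
trim-and-fill are out of scope. In the bundled rs2808630 corpus the
published subgroup table prints the lung and colorectal rows against each
other's studies; `run_meta()` reports strata by the study-level labels, so
its lung row is the pooled lung studies.
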