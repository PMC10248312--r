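---
title: "Validating an actuarial violence-risk instrument: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an actuarial violence-risk instrument: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskcalib)
```

## The problem

Actuarial violence-risk instruments such as the Violence Risk Appraisal
Guide-Revised (VRAG-R) sum weighted static items into a total score and map
it to one of nine ordered risk bins, each carrying a normative expected
recidivism rate. Before such a tool is used in a new population — here, a
forensic population found Not Criminally Responsible on account of Mental
Disorder (NCRMD) — two distinct psychometric questions must be answered:

* **Discrimination**: do recidivists outscore nonrecidivists? Quantified by
  the AUC, the probability that a randomly chosen recidivist scores above a
  randomly chosen nonrecidivist.
* **Calibration**: do the normative expected rates match the rates actually
  observed? Quantified by logistic score-to-rate models with
  Hosmer-Lemeshow fit tests, and by the expected/observed (E/O) index per
  bin and in total.

A tool can discriminate well and still be badly calibrated — typically when
the validation population's base rate differs from the normative sample's —
and that combination has direct consequences for how its bin estimates may
be communicated in reports. `riskcalib` implements the full validation
battery plus a synthetic-cohort generator, because the subject-level data
behind such studies are restricted: every stage of the pipeline is testable
against simulated cohorts with the published structure.

## Scoring and binning

The default instrument has 12 items whose published weight ranges sum to a
total score in $[-34, +46]$. Only the ranges are public; the shipped
default therefore allows every integer in each range, and a sparser allowed
set from a scoring manual can be supplied as JSON config.

**Proration.** Up to four omitted items may be prorated. The published
description ("a weighted average for missing values ... added to the
existing unprorated total") does not print a formula; we implement the most
direct reading: with $m$ missing items the adjustment is $m$ times the mean
weight of the scored items, i.e. omitted items are imputed at the
scored-item average. This is flagged as an interpretation; it is identity
at $m = 0$ and its sign equals the sign of the scored-item mean.

**Bin edges.** Two published layouts disagree about whether $-25$ belongs
to bin 1 or bin 2. The default follows the layout printed with the
normative expected-rate table (bin 1 is $\le -25$), because calibration
against the norms must use the norms' own bins; the descriptive layout is
available via `default_instrument_spec("descriptive")`, and edges are fully
config-overridable. Fractional prorated totals are rounded
half-away-from-zero before lookup, since bins are defined on integers; the
unrounded value is kept for continuous-score analyses.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws, per subject: sex (Bernoulli, 83.1% male); an
integer total score; a follow-up length; diagnoses; and per-outcome
recidivism events with conviction times. Defaults are the published cohort
structure, fixed once:

| Parameter | Default | Basis |
|---|---|---|
| male / female score mean (SD) | -4.81 (19.1) / -16.61 (14.9) | published descriptives |
| 5-yr violence logit | $B_0 = -2.856$, $B_1 = 0.040$ | published regression |
| 10-yr violence logit | $B_0 = -2.471$, $B_1 = 0.041$ | published regression |
| 5-/10-yr general logit | $-2.110/0.033$, $-1.656/0.033$ | calibrated to the published 8.8% / 13.2% base rates at the cohort mean; slope set for moderate discrimination (no coefficients are published for general recidivism) |
| diagnosis prevalence | psychotic .845, SUD .562, mood .387, ASPD .245 | published prevalences |
| comorbidity | ASPD-SUD odds ratio 3.6 | the only published pairing clearly departing from independence (77.8% SUD given ASPD vs 56.2% marginal) |
| follow-up mixture | 15% U(0.5,5), 1% U(5,10), 84% U(10,40) years | reproduces denominators that shrink markedly at the 5-year window but barely between 5 and 10 years |

Design notes on the pieces that were genuinely open:

* **Truncated-normal scores, moment-matched.** Only means and SDs are
  published, so scores are drawn from a normal truncated to the instrument
  range and rounded to integers. Crucially, the published moments describe
  the *observed* (range-limited) scores: naively using them as latent
  parameters yields an observed mean of about $-2.6$ rather than $-4.81$.
  The generator therefore solves for latent $(\mu, \sigma)$ such that the
  truncated distribution attains the printed moments (analytic truncated
  moments, Nelder-Mead). A pleasant consequence is that the female
  distribution concentrates its mode in bin 1, as the published frequency
  table shows. What the generator does **not** reproduce is the true
  shape of the score distribution beyond two moments — the published
  per-bin frequencies are multimodal in ways a normal cannot match — so a
  green test establishes correct behaviour *under the stated moments*, not
  distributional fidelity.
* **Event times.** The published analyses are fixed-window binary outcomes,
  so the time law matters only for window truncation. Times follow the
  piecewise-linear CDF interpolating the configured per-horizon logistic
  probabilities; the probability of an event within each configured window
  is then exactly $\mathrm{logit}^{-1}(B_0^{(h)} + B_1^{(h)} s)$. Events
  whose latent time exceeds the subject's follow-up are censored.
* **Comorbidity.** The design sketch called for a rejection adjustment
  tilting the joint by $\mathrm{OR}^{x_j x_k}$, but such a tilt distorts
  the marginal prevalences badly (ASPD would drift from .245 to ~.41 at
  OR 3.6). Instead, each configured pair's two indicators are redrawn
  jointly from the bivariate Bernoulli with the original margins and the
  configured odds ratio (closed-form $p_{11}$): margins stay exact and the
  odds ratio is hit exactly for disjoint pairs. Pairwise published rates
  remain *targets, not guarantees* when pairs share a diagnosis.
* **Seeding.** One master seed; each component (sex, scores, follow-up,
  outcomes, diagnoses, sheets, rater) derives a documented sub-seed, so
  adding a component never shifts another's stream and identical seeds
  give byte-identical fixtures.

Item-level sheets are produced by decomposing each total into a random
feasible per-item weight vector (sheet totals equal cohort totals by
construction), then injecting per-item omissions at the configured rate,
capped at the proration limit. A second rater re-scores each item with a
configured disagreement probability and perturbation magnitude; at full
disagreement with maximal magnitude the re-draw is uniform over the item's
allowed set, which is the independence stress case used in tests.

## Discrimination

AUC is computed as the Mann-Whitney probability with midrank ties — stated
explicitly because bin-level AUCs are tie-heavy. The default CI is Hanley &
McNeil's SE with a normal interval clipped to $[0,1]$ (the convention of
the validation literature this package mirrors; the published CI method is
unstated and printed intervals cannot adjudicate). A stratified bootstrap
CI is available by flag. Effect labels use the conventional thresholds
.556/.639/.714 (small/medium/large). Subgroups with a single outcome class
are skipped with a logged reason; subgroups with fewer than five subjects
in either class are flagged unstable rather than suppressed.

## Calibration

The logistic score-to-rate model is fit in-package by IRLS (convergence:
relative log-likelihood change $< 10^{-10}$ or 100 iterations; complete
separation detected and reported; constant scores fall back to the
closed-form intercept-only fit). SEs come from the information matrix at
the optimum; the Wald statistic, p, and $e^{B_1}$ with Wald CI mirror the
conventional reporting block. Tests verify the fit against both
`stats::glm` and an independent coarse-to-fine grid search of the
log-likelihood.

Hosmer-Lemeshow groups subjects by deciles of fitted probability; tied
fitted probabilities always share a group, collapsing the group count when
necessary, with $df = g - 2$.

The E/O index is $E/O$ with multiplicative CI
$(E/O)\,e^{\pm 1.96\sqrt{1/O}}$ (Rockhill's formulation — the published
formula is typographically garbled, and this reading reproduces the printed
total CI lower bound 3.04 from $E = 101.4$, $O = 22$). Per-bin expected
counts are `rate * n`, held unrounded internally so totals do not compound
rounding. Published tables occasionally print an expected-count column
inconsistent with `rate * n` in a single bin while their totals follow the
printed column; `eo_table()` therefore accepts an externally supplied
expected column so either arithmetic can be reproduced exactly. Bins with
zero observed events get no CI (the index is undefined) but still
contribute to totals, so total $E/\sum O$ always matches the column sums.

## Reliability

The interrater battery mirrors the conventional reporting paragraph:
one-way random-effects single-measure ICC (with the two-way consistency
and absolute-agreement variants also exposed — under a one-way model the
absolute/consistency distinction is degenerate, and both are reported
because published values quote both), unweighted and weighted Cohen's
kappa, Gwet's AC1 and its weighted counterpart AC2, binary and weighted
percent agreement, and Cronbach's alpha. The weighted-kappa scheme is not
stated in the literature this mirrors; the default is quadratic, which is
the common convention for many-category ordinal scales — and the published
weighted percent agreement of .992 is arithmetically consistent with the
quadratic kernel on nine categories
($(17 + 12(1-(1/8)^2) + 1(1-(2/8)^2))/30 = .9917$), which corroborates the
choice. AC2 uses the same kernel for comparability. Gwet variance is the
two-rater linearized estimator with a $t_{n-1}$ interval; tests check it
against a leave-one-out jackknife. ICC CIs are exact F bounds for the
one-way and consistency models and Satterthwaite for absolute agreement.

## Cohort statistics

Welch's $t$ works from raw vectors or published summaries. Cohen's $d$ is
reported under both the pooled-SD and mean-of-SDs standardisers, always
tagged: published $d$s in this literature are frequently the mean-SD
variant (the bundled reference summaries give $d = .69$ under mean-SD and
$.64$ pooled). Chi-square is Pearson without continuity correction with
Cramér's V ($=\phi$ for two groups).

**Fixed windows.** A subject enters a horizon's denominator iff their
follow-up covers the window *or* they recidivated inside it; short-followed
nonrecidivists are excluded. This rule is inferred — it is the only policy
that reproduces published denominators shrinking from the overall sample to
the fixed windows while early recidivists are retained — and it is the
default, config-overridable.

## Numerical choices and degenerate inputs

* Proration over the cap (> 4 omissions) is an error, not a silent skip.
* Half-away-from-zero rounding (not banker's) before bin lookup.
* AUC with a single outcome class is an error ("AUC undefined").
* Kappa with one category used by both raters is undefined (`NA` with
  warning); ICC with zero between-subject variance returns 0 with warning;
  alpha with zero total variance is `NA` with warning.
* Hosmer-Lemeshow with all fitted probabilities equal is an error
  (degenerate grouping).
* E/O with $O = 0$: flagged row, no CI, still in totals.

## What the tests establish — and what they cannot

The restricted subject-level data mean the published AUCs, ICCs, alpha and
fitted coefficients are *not* reproducible; they are covered by
property-based tests instead: AUC against exhaustive pair counting,
logistic recovery of the generator's coefficients within 3 SE at
$n = 10{,}000$, Hosmer-Lemeshow type-I error within $[.03, .08]$ over
1,000 well-specified replicates, and the agreement battery pinned at 1
under perfect agreement and near 0 under independence. The quantities that
*are* reproducible from published summary tables — total and per-bin E/O
indices with their CIs, the gender Welch $t$ and bin-by-gender chi-square,
and the instrument minimum — are recomputed from the bundled tables by the
test suite and by `scripts/acceptance.R`. A green suite therefore
establishes internal correctness and desk-scale reproduction, not
re-analysis of the clinical records.

## Known limitations

* The score generator matches two moments per sex; real score
  distributions in such cohorts are skewed and multimodal.
* Diagnoses and scores are generated independently (the joint distribution
  is unpublished), so diagnostic-subgroup simulations share one score law.
* General-recidivism coefficients are package defaults calibrated to base
  rates, not published estimates.
* Only two raters are supported in the agreement battery (the design being
  mirrored is paired), and survival-style time-to-event modelling is out of
  scope by design.
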