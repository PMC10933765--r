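---
title: "Sudden-gains methodology: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sudden-gains methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gainstudy)
```

This vignette is the package's own account of the science it implements:
the detection rule and its boundary behaviour, the statistical models
around it, what the synthetic cohort generator does and does not
emulate, and the decisions taken where the methodology left genuine
choices open.

## The three-criterion detection rule

Sudden gains are large, stable between-session symptom decreases. On a
weekly series $x_1, \dots, x_T$, the interval between sessions $n$
(pregain) and $n+1$ (postgain) is a gain when:

* **Criterion one (absolute):** $x_n - x_{n+1} \ge c$, where $c$ is the
  reliable change index of the scale, $c = 1.96\sqrt{2\,(SD
  \sqrt{1-\alpha})^2}$, rounded *up* to a whole point. `compute_rci_cutoff()`
  exposes both the raw and the rounded value; the ceiling rule is the
  default because fractional score points do not exist on summed
  questionnaires. With the package defaults (baseline SD 18.0, $\alpha =
  0.95$, an LSAS-like 0–144 scale) the cutoff is 12.
* **Criterion two (relative):** $x_n - x_{n+1} \ge 0.25\,x_n$. Both
  magnitude criteria use $\ge$ at the boundary: a drop exactly at the
  cutoff counts.
* **Criterion three (stability):** $\bar{x}_{pre} - \bar{x}_{post} >
  m \cdot s_{pooled}$ over the windows $\{x_{n-2}, x_{n-1}, x_n\}$ and
  $\{x_{n+1}, x_{n+2}, x_{n+3}\}$, strict because the rule demands the
  difference be *greater than* the threshold. The multiplier $m$ is 2.78
  with all six window points and 3.18 with exactly five; these are the
  97.5th percentiles of the $t$ distribution at 4 and 3 degrees of
  freedom, rounded to two decimals (`qt(0.975, 4)` = 2.776,
  `qt(0.975, 3)` = 3.182).

### Evaluability, not failure

Intervals at $n = 1$ or $n = T-1$, intervals with a missing endpoint,
and intervals whose criterion-three window retains fewer than five
points (or fewer than two per side) are reported as **not evaluable**.
This state is deliberately distinct from "evaluated and failed": the
count of evaluable intervals is the denominator of interval-level gain
rates, so conflating the two would bias every frequency statistic. A
complete 14-week series has 11 evaluable intervals ($n = 2..12$).

The five-point multiplier applies in two situations treated identically:
a window truncated by the series boundary ($n = 2$ or $n = T-2$) and a
window with exactly one missing interior value.

### Pooled SD convention

`pooled_sd()` defaults to the df-weighted two-sample form
$\sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}$. Whether historical
analyses weighted by degrees of freedom or simply averaged the two
variances is not always reported; the unweighted variant
(`pooled_sd_method = "simple_average"`) is provided for sensitivity
analysis. With complete windows ($n_1 = n_2 = 3$) the two coincide.

### Multiple gains

`detect_gains()` reports every passing interval, including overlapping
ones; de-duplication is the job of `select_primary_gain()`. Two rules
exist because two downstream analyses need different behaviour:
`"largest"` (maximum magnitude, ties broken by the earliest index —
deterministic and documented) for the around-gain analyses, and
`"tape_study"`, which first discards the later member of any pair of
gains at consecutive pregain indices — that gain has no usable control
session one week before it — and then takes the largest survivor.

## Missing data

Item-level missingness is handled by prorating
(`prorate_total()`): the mean of completed items scaled to the full item
count, provided at least half the items were completed (the
conventional half-scale rule; the threshold is an explicit argument
because no standard value is universal). A fully missed questionnaire
yields a missing weekly total — totals are never imputed, because an
interpolated total could manufacture or destroy a gain. Downstream
mixed models retain participants with missing rows via maximum
likelihood rather than dropping cases.

## The synthetic cohort generator

No participant-level trial data are deposited with the analyses this
package operationalises, so `generate_cohort()` produces cohorts with
the statistical structure those analyses assume. The defaults *are* the
study conditions: two arms of 50 and 49 participants, 14 weekly
assessments, baseline mean 85 and SD 18 on a 0–144 scale, per-arm
gainer probabilities 0.64/0.51, injected gain magnitudes
$N(23.0, 9.0^2)$ and $N(20.8, 7.3^2)$ floored at zero, second-gain
probabilities 11/32 and 9/25 among gainers, and adjusted outcome
differences 16.40/14.70/10.20 points at posttreatment and the 3- and
12-month follow-ups.

A trajectory is baseline + cumulative weekly drift + injected persistent
step drops + weekly noise, truncated to the score range. Values the
data do not pin down were chosen once as field-realistic and are
configurable, not revisited:

* **Drift** −2 points/week: combined with a typical ~23-point gain this
  puts the gain at roughly half of a gainer's total improvement, the
  proportion sudden-gains studies typically report.
* **Noise SD** 2 points i.i.d. Gaussian: small relative to the 12-point
  cutoff, so spontaneous false positives are rare (the tests verify
  < 1% of intervals under a no-gain null). An AR(1) option (`ar1_rho`)
  exists because autocorrelated noise is the natural stress test for
  false-positive studies; no weekly autocorrelation estimate exists to
  calibrate it against, so it defaults off.
* **Process measures.** Five weekly process series (cognition frequency
  and belief, general and difficult-situation self-focused attention,
  and a nine-item depression measure) are generated with their own
  baselines, drifts and noise, plus gain-locked step drops aligned to
  the participant's largest injected gain: a *pre-gain* drop over
  $n-1 \to n$ for the cognition and attention measures, and a
  *concurrent* drop over $n \to n+1$ for all five. The depression
  measure's pre-gain drop — and its background drift — are zero, so its
  pre-gain interval shows no change at any sample size; this encodes
  the qualitative specificity pattern (cognitive/attentional change
  precedes the gain, mood change does not) rather than any particular
  published effect estimate. The expected value of a consecutive
  contrast is therefore `weekly_change + drop` on intervals carrying a
  drop and `weekly_change` elsewhere.
* **Outcomes** are arm-free means per timepoint minus the configured
  gain-status effect for gainers, plus a baseline slope (0.5 per
  centred baseline point), a participant random effect (SD 10) and
  residual noise (SD 8) — a generating process congruent with the
  outcome model fitted downstream, so recovery is a fair test of the
  fitting code.

### Detectability versus magnitude realism

Injected magnitudes drawn from the configured normal are *not* all
detectable: a 15-point drop from a pregain score of 80 fails the 25%
criterion. This is faithful to how the magnitude distribution behaves
around the criteria — observed gain magnitudes are a selected,
upward-biased subset of underlying changes. Two regimes are therefore
offered:

* **Default** (`ensure_detectable = FALSE`): magnitudes keep the
  configured distribution; detection on such cohorts exhibits the
  realistic attenuation.
* **Recovery regime** (`ensure_detectable = TRUE`): magnitudes are
  floored at $\max(c,\ 0.25 \cdot \text{pregain level})$, multi-gain
  positions are spaced at least four weeks apart so neither gain's
  criterion-three window is contaminated by the other's step, and
  injections without headroom above the scale floor are skipped. Under
  this regime plus zero noise, detection provably recovers the ground
  truth exactly, and the test suite asserts it. The spacing and
  headroom rules exist because a step inside a neighbouring window, or
  one clipped by the scale floor, is not recoverable by *any* detector
  honouring the criteria — without them "perfect recovery" would be an
  impossible standard rather than a property of the engine.

What passing these tests shows about real data is deliberately limited:
the generator produces clean step changes with stationary Gaussian
noise and no dropout process, session non-attendance, floor-seeking
response styles, or treatment-phase heteroscedasticity. Results on
synthetic cohorts validate the *machinery*, not any clinical claim.

## Around-gain contrasts

`fit_consecutive_contrasts()` fits `value ~ timepoint` with a random
participant intercept by maximum likelihood (nlme), timepoint being the
categorical offset $n-2..n+3$ around the selected largest gain, and
reports the five consecutive-timepoint contrasts as unstandardised mean
differences (later minus earlier). Treatment condition is deliberately
omitted as a factor, keeping the model minimal. Missing offsets (window
truncation at series edges, missed questionnaires) are omitted via the
likelihood; contrasts are formed from fitted level means, not raw
means, so unbalanced missingness is handled consistently. p-values use
the large-sample normal approximation of the contrast $z$; with only a
handful of participants a Satterthwaite correction would differ, but
the analyses this serves operate on dozens of windows where the
approximation is standard practice.

Degenerate inputs (zero residual variance: constant or noiseless data)
make a mixed model unidentifiable; the function then falls back to a
within-participant fixed-effects regression, records
`attr(res, "method") = "fixed_effects"`, and treats a numerically zero
SE as an exact fit (p of 1 for a zero contrast, 0 otherwise).

## Outcome model

`fit_outcome_model()` fits the repeated outcome assessments
(posttreatment, 3- and 12-month follow-up) with fixed factors timepoint,
treatment condition and gain status plus the timepoint×status
interaction, the baseline score as covariate, a random participant
intercept, ML estimation, and an unstructured residual covariance over
the three timepoints (corSymm with per-timepoint variances). When that
general structure fails to converge the model refits with the
random-intercept-only covariance and records the fallback in
`meta$notes` — degraded covariance modelling should be visible, not
silent. Adjusted differences are non-gainer minus gainer estimated
marginal means at each timepoint (emmeans), so a benefit of having had
a gain is positive.

The effect size $d$ divides the adjusted difference by
$\sqrt{\sigma^2_{intercept} + \sigma^2_{residual}}$, the model's total
SD. Standardisation conventions for adjusted mixed-model differences
vary across reports and are rarely stated; this one is explicit,
computable from the fitted model alone, and documented as a convention
— comparisons with externally reported $d$ values should mind the
denominator. A difference is flagged clinically meaningful when it
reaches the reliable-change cutoff (12 by default). No multiplicity
adjustment is applied across the three timepoints by default, matching
the plain-pairwise reporting convention; `adjust = "holm"` is available.

## Tape study

`select_tape_pairs()` assembles the blinded rating design: per gainer,
the consecutive-gain rule, then largest-gain selection, then exclusion
if the pregain tape is unavailable, then control selection at $n-1$
with fallback to $n-2$. Foil pairs — two consecutive sessions from
participants who never gained, at session numbers drawn to match the
gain pairs' empirical distribution — are added at one per `ratio` gain
pairs (rounded up, so 25 gain pairs at ratio 2 yield 13 foils). A foil
pair mirrors a gain pair's internal structure (sessions $m-1, m$ from
one participant); the composition of foils is rarely specified in
published designs, and this choice maximises indistinguishability.
Viewing order is counterbalanced 50/50 with an odd leftover ordered by
the seeded RNG, and pair order is randomised so position carries no
information about pair kind. The whole design is deterministic given
its seed.

The four rating scales are two therapist-question scales (0–2) and two
client-statement scales (0–6); `validate_ratings()` enforces the
ranges. Reliability uses ICC(2,1) — two-way random effects, absolute
agreement, single rater — computed from the Shrout–Fleiss mean squares;
no installed package provides it, and the closed form is ten lines
cross-checked in the tests against an independent ANOVA computation.
Constant matrices and non-positive denominators return an explicit
degenerate flag rather than a number. Within-pair comparisons are
paired t tests with paired Cohen's $d$ (mean difference over the SD of
differences); between-group comparisons are pooled-variance independent
t tests. Zero-spread degeneracies are flagged infinite rather than
erroring, because a blinded-rating simulation can legitimately produce
them.

## Numerical and scale choices in the test suite

The simulation-scale tests run at sizes chosen to hold Monte-Carlo
error meaningfully below the effects being recovered: 2,000
participants for outcome-model recovery (difference SE ≈ 0.6 against
effects of 10–16 points), ~1,900 gain windows for contrast recovery,
5,000 trajectories for the null false-positive bound, and 1,000 random
short series for oracle equivalence of the detection engine. The
brute-force oracle is an independent, loop-based restatement of the
criteria kept free of package internals.

## Known limitations

* Gains are injected as instantaneous persistent steps; partial rebound
  ("sudden losses", reversal criteria) is out of scope.
* The generator has no dropout or attendance process — missingness is
  independent at a flat rate, and never at baseline.
* No pretreatment-variability screen is applied to flag possible
  false-positive gains; the criteria are implemented as classically
  stated.
* The tape-study ratings here are simulated; the package models the
  numeric scales and the blinded design around them, not the content of
  therapy sessions.
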