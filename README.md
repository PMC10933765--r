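# gainstudy

Detection and analysis of **sudden gains** — large, stable decreases in
clinical symptoms between consecutive therapy sessions — in weekly
symptom trajectories from two-arm treatment trials, together with the
downstream analyses such gains feed: outcome models by gain status,
process-measure change around the gain, and the blinded session-tape
rating design used to study what happens in the session before a gain.

The package is aimed at psychotherapy-process researchers who collect
weekly questionnaire totals (e.g. the Liebowitz Social Anxiety Scale,
0–144) across a course of treatment and want a tested, reproducible
implementation of the standard sudden-gains machinery, plus a simulator
for planning and validating such analyses when trial data cannot be
shared.

## The detection rule

A between-session interval with pregain score `x_n` and postgain score
`x_{n+1}` is a sudden gain when all three classical criteria hold:

1. **Absolute magnitude** — `x_n − x_{n+1} ≥ RCI`, where the reliable
   change index is `RCI = 1.96 · √(2 · (SD · √(1 − α))²)`, computed from
   the baseline standard deviation of the scale and its internal
   consistency α, rounded up to a whole score point. For SD = 18.0 and
   α = 0.95 this gives `⌈11.16⌉ = 12` points.
2. **Relative magnitude** — `x_n − x_{n+1} ≥ 0.25 · x_n`.
3. **Stability against local fluctuation** — the mean of up to three
   pregain scores `{x_{n−2}, x_{n−1}, x_n}` must exceed the mean of up
   to three postgain scores `{x_{n+1}, x_{n+2}, x_{n+3}}` by more than
   2.78 times their pooled standard deviation (the 97.5th t percentile
   at 4 df); with only five of the six window points available — at the
   series boundaries or with one missing value — the adjusted multiplier
   3.18 (3 df) is used. Fewer than five points, or a missing endpoint,
   makes the interval *not evaluable*, a state kept distinct from
   criterion failure.

Gains following the first or penultimate session are not evaluable, so a
complete 14-week trajectory contributes 11 evaluable intervals.

## Worked example

```r
library(gainstudy)

lsas <- c(80, 78, 76, 75, 50, 49, 51, 48, 47, 45, 44, 44, 43, 42)
res <- detect_gains(lsas, gain_criteria())
res$gains[, c("n", "pregain", "postgain", "magnitude")]
#>   n pregain postgain magnitude
#> 1 4      75       50        25
res$n_evaluable
#> [1] 11
```

The 25-point drop between weeks 4 and 5 passes all three criteria:
25 ≥ 12 (criterion one), 25/75 = 33% ≥ 25% (criterion two), and the
window means differ by 26.33 while the pooled SD is 1.29, so
26.33 > 2.78 × 1.29 (criterion three). The other ten evaluable intervals
fail criterion one.

A full simulated-trial analysis, end to end:

```r
b <- run_pipeline(simulation_config(), seed = 1)
b
#> 99 participants; 59 of 1089 intervals were sudden gains (5.4%)
#>   ct: 30/50 gainers (60%), 33 gains, magnitude M = 30.8 (SD 7.8)
#>   ict: 22/49 gainers (45%), 26 gains, magnitude M = 28.0 (SD 6.8)
#>   gainer proportion by arm: chi2(1) = 2.263, p = 0.132
#>   magnitude by arm: t(57) = 1.421, p = 0.161
```

Here `run_pipeline` simulated a 99-participant two-arm cohort, scanned
all 1089 evaluable intervals, and found no significant arm difference in
gainer proportion (Pearson chi-square without continuity correction) or
gain magnitude (pooled-variance t). The bundle also carries the
around-gain consecutive contrasts per process measure
(`b$contrasts`), the outcome-by-gain-status mixed model
(`b$outcome_model`), and the blinded tape-pair design
(`b$tape_design`).

## The analysis workflow

The numbered drivers under `analysis/` run the full study pipeline on a
simulated trial-sized cohort and write their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | generates the two-arm cohort (50/49 × 14 weeks) with injected gains, linked process measures, outcomes |
| `02_detect_gains.R` | detects gains, per-arm frequency/magnitude/timing tables |
| `03_around_gain.R` | mixed-model consecutive contrasts of the five process measures around the largest gain |
| `04_outcomes.R` | baseline equivalence; outcome model with adjusted gain-status differences and effect sizes |
| `05_tape_study.R` | blinded tape-pair design, simulated ratings, paired/independent comparisons, ICC(2,1) |

Run them in order from the repository root:
`Rscript analysis/01_simulate.R`, etc.

## Scope notes

Participant-level results of any particular trial (gainer percentages,
contrast estimates, adjusted outcome differences) depend on data that
are not publicly deposited; the simulator emulates their statistical
structure so that every analysis stage is testable, but its outputs are
synthetic and are labelled as such throughout. See the methods vignette
(`vignettes/sudden-gains-methods.Rmd`) for the model assumptions,
parameter defaults and design decisions.
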