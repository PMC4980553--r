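---
title: "Methods: validating momentary eating and activity reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating momentary eating and activity reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emavalid)
```

## The validation problem

A prompt-based mobile survey (mEMA) asks a participant, several times a
day, what they were doing right before the text arrived: whether they were
eating (and which of six broad food groups), and at what intensity they
were physically active. Two reference instruments run in parallel: a
24-hour dietary recall yielding time-stamped eating instances coded to the
same six food groups, and a hip-worn accelerometer summing movement counts
into 60-second epochs. The package quantifies agreement between the
momentary reports and each reference, separately for the diet arm and the
activity arm, while respecting the repeated-measures structure (many
occasions per participant).

The two arms are deliberately asymmetric. Recall-derived eating times are
known to be unreliable, so the diet arm works at the day level and with
widening time windows rather than at the moment of the report. The
accelerometer, by contrast, measures continuously, so the activity arm
compares at the moment of each prompt.

## Study design assumed by the defaults

The default configuration mirrors a four-day monitoring design: two
prompts drawn uniformly at random within each of four daily blocks
(09:00–12:00, 12:00–15:00, 15:00–19:00, 19:00–22:00), of which seven per
day are real-time and one is a retrospective past-3-hours prompt; the
survey can be completed from 5 minutes before to 30 minutes after the
text, and the completion time is the analysis timestamp. Participants
complete one to three recall days of the four. Retrospective prompts are
generated and flagged but **excluded from the validation analyses by
default**: a momentary-versus-reference comparison is only meaningful for
real-time reports. A flag (`include_retrospective`) allows the
alternative. Since each day's schedule draws two prompts per block, the
day's final prompt is designated the retrospective one, so it can cover
the day it summarises.

## Diet arm

### Day-level matching

For food group $g$ on participant-day $(i,d)$, with $m_{id}$ momentary
endorsements and $r_{id}$ recall instances, the day contributes
$\min(m_{id}, r_{id})$ matches to a denominator of $m_{id}$. Matching is
presence-based and per-count, never a one-to-one assignment of specific
instances. A group never endorsed has an undefined match rate, reported
as missing rather than zero. The "other" food group is carried through
ingest but excluded from match statistics by default, since it is a
catch-all whose agreement is not interpretable.

Days enter this analysis only if they have at least one momentary food
entry and a biologically plausible recall day. Plausibility is a
**closed** interval, 500–5000 kcal: the wording "between 500 and 5000"
leaves the boundary open, and we keep boundary days because the screen is
meant to remove impossible values, not borderline ones. Both bounds are
configurable (`filter_thresholds()`).

### Window matching

For half-widths $w$ from 6 minutes to 8 hours in 6-minute steps (the
"either side" reading: $w = 480$ spans 16 hours total), an endorsement at
time $t$ is matched if any same-group recall instance falls in the closed
interval $[t-w, t+w]$. Closed on both ends so that an instance exactly
$w$ minutes away counts; with minute-resolution data the choice moves
individual events at exact boundaries only. The PPV curve is monotone
non-decreasing in $w$ by construction (fixed denominator, growing
numerator), and the package asserts this invariant in its tests.

For sensitivity and specificity, a negatives pool is required, which the
day-level definitions do not supply. The occasion set is **all completed
real-time prompts** — eating or not — with reference condition "recall
instance of $g$ within the window" and test condition "this report
endorses $g$". This is the only choice that yields a full 2×2 table at
every $w$; an `occasions = "eating_only"` switch restricts the pool to
prompts with at least one food entry. We note that narrative summaries of
such curves can disagree on the direction of the sensitivity trend; the
package computes and reports both statistics at every $w$ and asserts
only the conservation and monotonicity properties that hold by
construction.

### Subgroup and model-based comparisons

Chi-square tests on the 2×2 (matched × group) collapse per food group use
no continuity correction — tallies are large and the uncorrected statistic
matches the closed form $N(ad-bc)^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ used
as the test oracle. Tables with any expected cell below 1 are flagged
unreliable rather than suppressed.

The mixed logistic model works at the prompt × food-group level:
$\operatorname{logit} P(\text{endorse}_g) = \beta_0 + \beta_1\,
\text{recall-day}_g + u_i$, $u_i \sim N(0, \sigma_u^2)$, fitted by
maximum likelihood (lme4), odds ratio $e^{\beta_1}$ with a 95% Wald
interval. Separation and non-convergence produce flagged `NA` rows, never
a crash: with few participants and rare groups these models legitimately
fail, and silent point estimates would be worse than an honest flag.

## Activity arm

Epochs are classified with the Freedson cut points; bands are left-closed
(100 CPM is light, 1952 moderate, 5725 vigorous) so they partition the
nonnegative integers. The derived measure at a prompt is the arithmetic
mean of counts over the **half-open** window $[t-5, t)$ minutes by epoch
start — half-open so the epoch containing the response itself, which
mixes the behaviour with the act of answering, is excluded. Occasions are
dropped (with a ledger reason) when either 30-minute flank of counts is
entirely zero — the wording "zero for the 30 minutes before or after" is
ambiguous between *either* and *both*; we exclude on *either*, because a
fully zero flank indicates the device was off at the moment of report —
or when daily wear is under 5 hours. Wear time uses the standard
≥60-minute consecutive-zero-run non-wear convention, since no wear
algorithm is otherwise specified. The instrument label "strenuous" is
accepted as a synonym of "vigorous" throughout.

The 4×4 reported-by-derived table is summarised per level by:

* match rate — diagonal over row (reported) total;
* sensitivity and specificity — conditioned on the **derived** (column)
  level: positives at level $L$ are occasions the accelerometer placed at
  $L$; this orientation reproduces every derived statistic of the
  reference cross-tabulation used in the acceptance tests;
* $LR^+ = \text{sens}/(1-\text{spec})$, undefined at specificity 1;
  $LR^- = (1-\text{sens})/\text{spec}$, undefined at specificity 0;
* a mixed logistic odds ratio per level (outcome: derived $= L$;
  predictor: reported $= L$; participant random intercepts), declared
  undefined when fewer than two participants contribute concordant
  occasions at $L$ — a single participant cannot support a random-intercept
  contrast, the situation that arises for vigorous activity in small
  cohorts.

Kolmogorov–Smirnov comparisons of the derived-count distributions between
reported levels use the asymptotic p-value (ties in minute-resolution
count data make the exact computation inapplicable; the D statistic is
unaffected and is oracle-checked against a brute-force maximum ECDF gap).

The mixed linear model uses $\ln(\text{CPM} + 1)$: the log transform is
conventional for right-skewed counts and the $+1$ offset handles the
zero 5-minute means that survive the flank filter. Fitting is by maximum
likelihood with Wald intervals; all six pairwise level contrasts are
reported, and each contrast is back-transformed to a raw-count difference
relative to the model's sedentary mean,
$\exp(\beta_0 + \delta_b) - \exp(\beta_0 + \delta_a)$, which is how a
reader of the log-scale estimates recovers counts-per-minute differences.
The per-participant mean-by-level summary (`participant_level_means()`)
reports ordering inversions — participants whose average counts are lower
when they report the higher level — because population-level monotonicity
routinely coexists with inverted within-person orderings, and a validation
analysis should surface that.

## The synthetic cohort generator

The generator exists so that every downstream statistic has a testbed
with known truth. Per participant-day it draws Poisson(3.7) true eating
occasions uniformly over 08:00–22:00 with a recall-frequency-weighted
food-group multinomial, and a piecewise-constant activity track with
geometric bout durations (mean 30 min) over intensity distribution
(0.55, 0.40, 0.045, 0.005). Epoch counts are per-level lognormals
truncated to the level's cut-point band, with a configurable `spill`
mass (default 5%) drawn untruncated to create controlled
misclassification. Recall applies independent omission (default 0.2) and
centred Gaussian clock-time displacement (default SD 60 min — recall
times are known to be badly misplaced, and a displacement of this order
is what makes short-window match rates collapse while day-level rates
stay high). Daily energy is uniform on 1400–3000 kcal, so default days
pass the plausibility screen; tests plant violations explicitly.

Two generator choices deserve emphasis:

* **Occasion-level activity truth.** The "true" level at a prompt is
  defined as the cut-point classification of the mean simulated counts
  over the 5-minute pre-window, and the misreport matrix
  $P(\text{reported} \mid \text{true})$ is applied to that level. Defining
  truth at the occasion summary (rather than per minute) guarantees that
  an identity misreport matrix with zero spill yields an exactly diagonal
  cross-tabulation regardless of where activity bouts fall relative to
  prompts — the round-trip identity the tests rely on. The per-minute
  track remains available as ground truth.
* **Eating endorsements.** A prompt endorses the food groups of any
  not-yet-reported true occasion in the preceding 45 minutes
  (`eat_window_min`), and each occasion is endorsed at most once, so a
  day's endorsement count never exceeds its true occasion count and
  zero-noise day-level match rates are exactly 100%. The 45-minute
  default reflects the response window plus typical completion latency.

The default misreport matrix reproduces the qualitative signature of
momentary activity self-report — faithful sedentary reporting, heavy
misreporting of light and moderate activity toward sedentary — estimated
from the reported-given-derived frequencies of the reference
cross-tabulation design.

What the generator does **not** emulate: diurnal activity structure
(bouts are exchangeable across the day), non-response (every prompt is
completed; analyses operate on completed prompts, so response bias is out
of scope), wear-time gaps (tests plant non-wear explicitly), energy
misreporting correlated with intake, within-day eating clustering, and
any dependence between the diet and activity error processes. Passing
tests therefore demonstrate the statistical machinery is correct under a
faithful-but-idealised data-generating process, not that any particular
instrument is valid.

## Numerical and engineering choices

* Timestamps are minute-resolution POSIXct in a fixed DST-free calendar
  (UTC), since all instruments share the participant's clock; day
  boundaries are local calendar midnights, and prompts live in
  09:00–22:00 so no cross-midnight ambiguity arises.
* `recall_days_range` (1–3 of the monitoring days) and `eat_window_min`
  extend the configuration surface beyond the core noise parameters
  because the recall-day structure and the prompt–occasion link are both
  needed for any end-to-end run.
* Full precision is kept everywhere internally; rounding to conventional
  printed precision (one decimal for match rates, integer percent for
  sensitivity/specificity, two decimals for likelihood and odds ratios)
  happens only in the report-writing layer.
* A recall day on which every occasion was omitted does not appear in
  the recall table at all and is indistinguishable from a non-recalled
  day — a deliberate simplification matching how absent recalls present
  in real exports.
* Mixed models: `glmer`/`lmer`, maximum likelihood, lme4 default
  optimisers and convergence tolerances; Wald 95% intervals throughout.
  Boundary (singular) fits are legitimate results, and in the
  zero-variance limit the estimates provably coincide with
  `glm`/ordinary least squares, which the tests assert.
* Test and simulation problem sizes: oracle-equivalence suites use 200
  random tables/sample pairs; monotonicity runs 50 small cohorts (2
  participants × 1 day); parameter-recovery uses 5,000 singleton days for
  the omission rate, 50 replicates of 200 × 20 occasions for the
  logistic odds ratio, and 50 replicates of 41 × 17 occasions (the
  reference design size) for the log-count contrasts.

## Known limitations

* The ingest layer reads the documented delimited-text schema only; no
  native ActiGraph AGD containers or vendor recall export dialects.
* Wear-time detection is the plain zero-run rule, without the
  interruption tolerances of more elaborate algorithms.
* The sensitivity/specificity occasion-set choice (all real-time prompts)
  is a modelling decision; with very sparse endorsements the specificity
  estimates are dominated by true negatives and should be read
  accordingly.
* Energy intake, portion size and nutrient composition are out of scope:
  the diet arm validates food-group choices, not intake quantity.
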