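---
title: "Emotion-dynamics indices and symptom models for EMA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotion-dynamics indices and symptom models for EMA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectdyn)
```

# Scope and data model

`affectdyn` analyses ecological momentary assessment (EMA) affect
protocols in which participants rate seven momentary emotions on a
0–6 scale at 5 scheduled prompts a day for 7 days. Two items
(joy/excitement, satisfaction/relaxation) form the positive-affect (PA)
composite and four (worry/anxiety, sadness/disappointment,
irritation/anger, tension/stress) the negative-affect (NA) composite;
the tiredness/listlessness item is carried through I/O but enters no
index. Data travel as long-format CSV — one row per answered prompt —
because that is the simplest lossless representation of the design;
wide formats are out of scope. Ratings are stored as integers, so PA
and NA prompt means (denominators 2 and 4) are exact in floating point
and day-level means introduce no hidden rounding. Timestamps are
optional metadata: prompts are slot-scheduled, so ordering within a day
always uses the slot index, and timestamps are consulted only to break
double-completion ties.

# Data selection

The selection cascade mirrors standard EMA compliance practice:

1. remove prompts with any missing PA/NA emotion item (a missing
   tiredness rating does not make a prompt incomplete);
2. resolve double completions of the same (participant, day, slot) key
   to the earliest completion (timestamp order, then file order);
3. drop participants with fewer than 10 answered prompts (30% of 35);
4. drop person-days with fewer than 3 prompts;
5. drop participants left with fewer than 3 valid days;
6. drop participants without usable symptom data.

The stage ordering is semantically load-bearing and pinned by tests: a
participant with day pattern (3, 3, 3, 1) has 10 prompts at stage 3 and
is retained even though only 9 prompts survive the day filter. A
consequence worth knowing is that the cascade is *not* idempotent at
this boundary — re-running it from scratch on its own output would drop
such a participant at the total-prompt stage. The procedure is defined
as a single pass; `apply_compliance_filters()` documents this and the
test suite asserts both the single-pass outcome and the boundary
behaviour. Every stage is logged with prompts, participants and
person-days remaining.

Participants missing one subscale but not the other stay in the
analysis set; each model then deletes listwise over exactly its own
variables. This is why the depression and anxiety models can have
slightly different n.

# The indices

All indices are computed per participant from the selection-filtered
records; `compute_profiles()` is a vectorized cohort-level
implementation proven equal (by test) to the per-person functions
`rmssd()`, `lag1_autocor()`, `pa_differentiation()` and
`na_differentiation()`.

**Intensity** is the mean over days of the daily mean of prompt-level
composites — deliberately *not* the grand mean over prompts, so that
days with unequal prompt counts weigh equally. A fixture with uneven
days (day means 1, 4, 2 giving 7/3 rather than the grand mean 18/7)
pins this convention.

**Instability** is the daily root mean squared successive difference
(RMSSD), averaged over days. Successive pairs are consecutive
*answered* prompts within a day: a skipped middle slot does not split
the day, because the daily series is short and slot gaps are frequent;
`strict_adjacent = TRUE` restricts pairs to adjacent scheduled slots
for sensitivity analyses. Days with fewer than two answered prompts
contribute no RMSSD and are skipped in the average (after the ≥3
prompts/day filter such days cannot occur, but the rule matters if the
thresholds are reconfigured).

**Inertia** is a lag-1 autocorrelation that respects day boundaries: a
break is inserted after the last observation of each day, so lagged
pairs never straddle midnight, and a single Pearson correlation is
computed over the pooled within-day pairs — an average autocorrelation
across the week. On a gap-free single day this reduces exactly to the
textbook `cor(x[-n], x[-1])`, which the suite verifies against a
brute-force pair-enumerating oracle. The estimator is pairwise-Pearson
(separate means and variances for the lead and lag columns) rather
than autocovariance-over-variance; the two differ at these series
lengths, and pairwise-Pearson is the choice because it remains
well-defined under the day-break construction. At least 3 lagged pairs
are required (a correlation on fewer points is degenerate); the
threshold is exposed as `min_lag_pairs`.

**Differentiation** is the average Fisher-z pairwise Pearson
correlation among same-valence item series over all answered prompts —
1 pair for PA, 6 for NA; higher values mean poorer differentiation.
Pairs involving a (near-)zero-variance series are skipped, and each
correlation needs at least 3 paired observations, the same floor as
inertia, because a 2-point correlation is always ±1.

Numerical choices: correlations are clamped to ±(1 − 1e−7) before
`atanh`, keeping perfectly coupled items finite while preserving order;
zero variance is detected at a 1e−10 tolerance on the centred sum of
squares (ratings are bounded, so scale is not an issue); zero-variance
and too-short series yield `NA` — never 0 and never an error — and
participants with missing indices are removed per model by listwise
deletion.

# Screening

Subscale totals are plain sums of 8 (depression) or 6 (anxiety) items,
each 0–4; elevated status is total **strictly** greater than 11 (a
total of 11 is normal). The cutoff is a parameter. Missing items are
never imputed: any missing item makes the subscale total `NA`.
`prevalence_and_overlap()` computes prevalence over participants with
known status per subscale and the both/only-one breakdown among the
union of elevated participants with both subscales known — the
denominators can legitimately differ, which is exactly what reproduces
published margins in which the two subscales have different ns.

# Models

Group comparisons use Welch's unequal-variance t with
Welch–Satterthwaite degrees of freedom, computable directly from group
summaries so printed descriptive tables can be re-tested. The
unequal-variance form matters: with group SDs differing by nearly a
factor of two, the pooled-variance statistic would differ visibly.

Logistic models are maximum-likelihood `stats::glm` fits. For every
model, rows are selected by listwise deletion over that model's
variables; emotion-dynamics predictors are then standardized *on those
rows* (mean 0, SD 1, n−1 denominator), while age stays in years and
gender is an indicator with female = 1 — so the age odds ratio is "per
year" and index ORs are "per SD". Wald 99% CIs use z = 2.5758 on the
log-odds scale. The individual-predictor stage fits
`outcome ~ index + age + gender` for each of the 8 indices × 2
outcomes. The joint stage fits the initial model
{PA intensity, NA intensity, age, gender} and a final model adding the
promoted index (NA instability by default; `promote = "auto"` promotes
every index individually significant at `alpha`). Both joint models
are fitted on the final model's complete rows — the nested
likelihood-ratio test is otherwise invalid — and compared by
χ² = 2(LL_final − LL_initial), AIC, and adjusted McFadden pseudo-R²,
`1 − (LL − k)/LL₀` with k the number of non-intercept parameters
(plain McFadden is reported alongside, since "adjusted" pseudo-R²
admits several formulas and results should be comparable under
either). Possible separation (non-convergence, |B| > 15, or SE > 50)
is flagged with a warning on the fit object, never silently. All fits
are deterministic given the input rows.

Parallel linear models re-use the same term sets with the continuous
subscale totals as outcomes and report fully standardized betas
(`B·sd(x)/sd(y)`), which are invariant to affine rescaling of either
side.

The significance threshold is 0.01 with 99% intervals everywhere, a
family-wise guard appropriate to the number of indices tested.

# The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage is testable
with known truth. The generative family is deliberately minimal —
latent AR(1) plus item noise — because it is the smallest model in
which all four index families are independently dial-able:

* per valence, a latent series over the 35 scheduled prompts follows
  `x_t = mu + phi (x_{t-1} − mu) + e_t`, `e_t ~ N(0, sigma²)`,
  initialized at the stationary distribution; `mu` controls intensity,
  `sigma` (with `phi`) instability, `phi` inertia;
* each item rating is `clip(round(x_t + item noise), 0, 6)`; the item
  noise SD controls how tightly same-valence items couple, i.e.
  differentiation, and round-then-clip reproduces the floor effects
  typical of NA items when `mu_na` is low;
* prompts are dropped independently with probability `missing_rate`
  (missingness completely at random — no mechanism was available to
  emulate, and MCAR is the testable default).

Person-level parameters are truncated-normal draws. Defaults describe
the reference conditions the package is validated under: 221
participants, 20% missingness, mean age 46 (SD 15), 73% women, low
mean NA. They were fixed once, from the descriptive shape of the
motivating study design, and are not tuned per analysis.

The symptom layer draws elevated status from a logistic model on raw
age, gender (female = 1) and the within-cohort z-scores of the
person's **realized** PA intensity, NA intensity and NA instability —
realized meaning computed by `compute_profiles()` on the complete,
pre-missingness emitted ratings. An analytic "expected index" does not
survive rounding and clipping in closed form, and defining truth on
the realized full-design indices keeps the recovery target exact:
the fitted coefficients estimate precisely the generator's
coefficients, attenuated only by the missingness the analyst actually
faces. Subscale totals are then drawn on the correct side of the
cutoff with a severity that increases with the linear predictor, and
item vectors distribute each total multinomially under the 0–4 item
cap (only totals and cutoffs matter downstream). Ground truth records
every latent parameter, realized index, z-score and probability.

What the generator does **not** emulate: time-of-day and weekday
structure, autocorrelated or state-dependent missingness, response
styles and reactive measurement, item-specific factor structure beyond
shared-valence coupling, and selection effects linking compliance to
symptoms. Passing recovery tests therefore show the estimators are
correct under the stated model, not that real EMA data satisfy it.

# Validation strategy and problem sizes

The test suite works at three levels. Exact fixtures pin arithmetic
conventions (day-first averaging, stage ordering, strict cutoff).
Brute-force oracles — naive re-implementations written only from the
definitions, including a Newton-iteration likelihood maximizer
independent of `glm` — are compared against the implementations on
1,000 random series fixtures and 200 random logistic datasets
(coefficients to 1e−6). Monte-Carlo suites check calibration:
coefficient recovery and 99%-CI coverage on 50 replicate cohorts of
n = 2000 under the reference conditions, and the likelihood-ratio
test's type-I error over 500 null cohorts of n = 200, expected in
[0.2%, 2.5%] at the 0.01 level. These replicate counts keep the full
suite around two minutes on one core while leaving the binomial
tolerances comfortably wide; they are the package's chosen trade-off
between runtime and Monte-Carlo resolution.

One systematic effect is worth stating: because truth is defined on
the complete-design indices while fits see 20% missingness, the
instability coefficient is attenuated by measurement error — about
0.05 on a true log-odds of 0.7 at these settings, under one standard
error. Recovery assertions are made against the per-fit sampling
error (3 SE) and pooled CI coverage, where this bias is immaterial;
it would matter for meta-analytic averaging across many replicates,
which is not a supported use.

# Known limitations

* Inertia and differentiation are undefined for participants with
  (near-)constant series — common when NA is at floor — and such
  participants drop out of the corresponding models listwise; the
  individual-model ns make this visible.
* The inertia estimator is one defensible choice among near-neighbours
  (pairwise-Pearson vs. autocovariance ratios); at 35-prompt weeks the
  difference is small but not zero, and conclusions about inertia
  should not hinge on the estimator.
* No multilevel treatment of prompts (no DSEM, no within-day
  detrending); indices are summary statistics, inheriting their known
  biases at short series lengths.
* The pipeline models two subscales with one cutoff each; other
  subscales, continuous-severity cutpoints, or imputation of missing
  prompts are out of scope.
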