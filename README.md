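# affectdyn

Emotion-dynamics indices and symptom models for ecological momentary
assessment (EMA) data.

## The problem

Depression and generalized anxiety are characterized not only by how
much positive affect (PA) and negative affect (NA) people experience,
but by how affect *unfolds over time*. Intensive longitudinal designs
prompt participants several times a day for a week to rate momentary
emotions, and a small family of person-level indices summarizes the
resulting short, gappy time series. `affectdyn` implements the complete
analysis chain for such studies — compliance-based data selection,
index computation, symptom screening, and staged covariate-adjusted
regression — plus a synthetic cohort generator with known ground truth
so that every stage can be validated end to end.

It is aimed at researchers analysing EMA affect protocols (here: 5
prompts/day × 7 days, seven emotion items rated 0–6, with 2 PA and 4
NA items) against questionnaire-screened symptom outcomes.

## The indices

For person *i*, with prompt-level PA/NA means `x_t` (mean of the 2 PA
items, or of the 4 NA items), computed per valence:

- **Intensity** — the mean of daily means:
  `mean_d( mean_{t in day d}(x_t) )`, so days with unequal prompt
  counts carry equal weight.
- **Instability (RMSSD)** — the root mean squared successive
  difference within each day, `sqrt(mean((x_{t+1} - x_t)^2))` over
  successive answered prompts, averaged over days.
- **Inertia** — the lag-1 autocorrelation with *day breaks*: lagged
  pairs are formed only within a day (a break is inserted after each
  day's last observation), and a single Pearson correlation is taken
  over all pairs; Fisher z-transformed (`atanh r`) for analysis.
- **Differentiation** — the mean Fisher-z pairwise Pearson correlation
  among same-valence item series (1 pair for PA, 6 pairs for NA);
  *higher* values mean *poorer* differentiation.

Elevated depressive / generalized-anxiety status is a subscale total
strictly greater than 11 (8 depression items, 6 anxiety items, each
0–4). The modelling layer fits per-index logistic regressions
(standardized index + age + gender), then an initial joint model
{PA intensity, NA intensity, age, gender} against a final model adding
NA instability, compared by likelihood-ratio test, AIC, and adjusted
McFadden pseudo-R², with odds ratios and 99% Wald CIs throughout.

## Worked example

```r
library(affectdyn)

co  <- simulate_cohort(sim_config(seed = 1))   # 221 participants, 7x5 design
res <- run_pipeline(co$prompts, co$participants)
print(res)
```

```
EMA affect-dynamics analysis
               stage n_prompts n_participants n_days
                 raw      6150            221   1547
    complete_prompts      6150            221   1547
        deduplicated      6150            221   1547
   min_total_prompts      6150            221   1547
 min_prompts_per_day      5966            221   1448
      min_valid_days      5966            221   1448
       with_outcomes      5966            221   1448
elevated depression 32.1%, elevated anxiety 29.4%
initial vs final model comparisons:
      outcome  chi2 df      p aic_initial aic_final pseudo_r2_adj_initial
 dep_elevated 14.69  1 0.0001      241.04    228.35                  0.14
 anx_elevated  6.33  1 0.0119      215.41    211.09                  0.20
 pseudo_r2_adj_final
                0.18
                0.22
```

The retention log traces the selection cascade (complete prompts →
dedup → ≥10 prompts → ≥3 prompts/day → ≥3 valid days → symptom data
present). With 20% random missingness almost no simulated participant
falls below the compliance thresholds; the day filter trims 184
prompts on low-coverage days. The comparison table shows that adding
NA instability improves fit for both outcomes (for depression:
χ² = 14.69 on 1 df, AIC drops from 241.0 to 228.4).

```r
print(res$joint$dep_elevated$final)
```

```
Logistic model for dep_elevated  (n = 221 )
           term      b    se      z     p    or ci_lo  ci_hi
    (Intercept)  0.865 0.643  1.345 0.178 2.375 0.453 12.443
   pa_intensity -0.452 0.180 -2.509 0.012 0.637 0.400  1.012
   na_intensity  0.527 0.182  2.898 0.004 1.694 1.060  2.707
 na_instability  0.704 0.193  3.651 0.000 2.022 1.230  3.323
            age -0.053 0.013 -3.934 0.000 0.949 0.917  0.982
  gender_female  0.728 0.396  1.837 0.066 2.070 0.747  5.740
logLik = -108.18, AIC = 228.35, pseudo-R2 = 0.220 (adjusted 0.184)
```

Each standardized-index OR is the multiplicative change in the odds of
elevated status per SD of the index: here one SD of NA instability
roughly doubles the odds (OR 2.02, 99% CI 1.23–3.32) with PA/NA
intensity, age and gender controlled — close to the generator's true
coefficient of 0.7 on the log-odds scale. `render_tables(res, dir)`
writes the retention log, per-person index profiles and the four
rendered result tables as CSV.

A small deterministic cohort exercising every selection branch ships
as `demo_cohort()` (also as CSVs under `inst/extdata/`).

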