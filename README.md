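# icap — intrinsic capacity scoring and pre/post analysis

`icap` is an R package for gerontology and rehabilitation researchers who
assess older adults with routine functional tests and need (a) a
reproducible composite **intrinsic capacity** (IC) score and (b) a sound
statistical comparison of two assessment timepoints in a single-arm
(pre/post) design with dropout.

Intrinsic capacity is the WHO's composite of physical and mental capacities
across five domains. The package scores each domain on 0–2 points from raw
assessments and sums them without weighting:

    IC = D_locomotion + D_vitality + D_cognition + D_psychological + D_sensory,

with IC ∈ [0, 10] on a half-point grid, classified *low* (0–4), *moderate*
(5–8) or *high* (9–10). Domain rules: vitality (handgrip ≥ 27/16 kgf for
men/women, BMI in 22–27 kg/m², 3-month weight loss < 3 kg, no appetite
loss; 0.5 each); sensory (vision and hearing: 1 point each only with no
difficulty and no corrective device); locomotion (TUG < 10 s, sit-to-stand
at or above the age/sex norm, sit-and-reach in the age/sex range, one-leg
stand > 20 s; 0.5 each); psychological (GDS-15: 0–5 → 2, 6–10 → 1,
11–15 → 0); cognition (MoCA at or above the education-adjusted cutoff → 2).

The analysis stage compares baseline and follow-up with **generalized
estimating equations** (participant as cluster, exchangeable working
correlation, robust sandwich variance; families per variable type: linear,
log-linear, binary-logistic, ordinal-logistic) under intention-to-treat,
and reports a **standardized effect size** — mean within-participant change
divided by the baseline SD — with a participant-level bootstrap 95% CI and
Cohen banding (< 0.5 small, 0.5–0.8 moderate, > 0.8 large). A synthetic
cohort generator with configurable true effects, within-subject correlation
and dropout makes the whole pipeline testable without participant data.

## Worked example

Score one assessment and analyse a simulated cohort of the default study
size (43 enrolled, 3 dropouts):

```r
library(icap)
th <- example_thresholds()   # fixed cutoffs + example norm tables

rec <- list(age = 67, sex = "F", education = "medium", hgs = 18, bmi = 28.4,
            weight_loss_3mo = 0, appetite_loss = FALSE,
            wears_glasses = TRUE, vision_difficulty = FALSE,
            uses_hearing_aid = FALSE, hearing_difficulty = FALSE,
            tug = 9.1, chair_stand = 12, sit_reach = 1.5, balance = 18,
            gds15 = 3, moca = 25)
score_record(rec, th)
#> $domains
#>       sensory psychological     cognitive      vitality    locomotion
#>           1.0           2.0           2.0           1.5           1.5
#> $score
#> [1] 8
#> $category
#> [1] moderate
```

This participant loses the vision point (wears glasses), the BMI half-point
(28.4 kg/m² is above the 22–27 band; her 18 kgf handgrip passes the 16 kgf
female cutoff) and the balance half-point (18 s is not over 20 s), landing
at 8 = moderate capacity.

```r
coh <- generate_cohort(cohort_config(seed = 42))
scored <- ic_score(coh, th)

prepost_gee("body_fat", scored, family = "linear")
#> Pre/post GEE (linear, exchangeable working correlation)
#>   outcome: body_fat;  83 observations, 43 participants
#>   time effect: -1.829  (robust SE 1.013, p = 0.07085)
#>   working correlation alpha = 0.7783

res <- analyze_cohort(scored, default_plan(c("body_fat", "sf6d")),
                      seed = 7, R = 500)
res[, c("variable", "p_value", "effect_size", "es_band")]
#>        variable p_value effect_size es_band
#> 1       sensory   0.757       0.045   small
#> 2 psychological   0.941       0.000   small
#> ...
#> 8      body_fat   0.071      -0.190   small
```

This is a *null* cohort (no configured effects), so the time effect on body
fat (−1.8 percentage points, p = 0.071) is sampling noise and every effect
size sits in the small band — which is exactly what the type-I-error and
null-coverage tests verify systematically.

A command-line pipeline wraps the same functions
(`inst/cli/icap.R simulate | score | analyze`), writing a JSON run manifest
beside every output.

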