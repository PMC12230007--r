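---
title: "Scoring intrinsic capacity and analysing pre/post change"
author: "icap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring intrinsic capacity and analysing pre/post change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icap)
```

## The model

Intrinsic capacity (IC) is the WHO's composite of an older adult's physical
and mental capacities, partitioned into five domains: **vitality**,
**sensory**, **locomotion**, **psychological** and **cognition**. `icap`
implements a composite score in which each domain contributes 0–2 points and
the composite is their unweighted sum,

$$\mathrm{IC} = D_{loc} + D_{vit} + D_{cog} + D_{psy} + D_{sen}
\in [0, 10],$$

classified as *low* (0–4), *moderate* (5–8) or *high* (9–10) capacity.

The domain scores are deterministic functions of routine geriatric
assessments:

* **Vitality** — four pass/fail sub-rules worth 0.5 each: handgrip strength
  at or above the sex-specific cutoff (27 kgf men / 16 kgf women); BMI in
  the closed band 22–27 kg/m²; unintentional 3-month weight loss under
  3 kg; no reported appetite loss.
* **Sensory** — vision and hearing each score 1 only when the participant
  reports neither difficulty nor a corrective device (glasses / hearing
  aid); otherwise 0.
* **Locomotion** — four pass/fail sub-rules worth 0.5 each: Timed Up and Go
  strictly under 10 s; sit-to-stand repetitions at or above the age- and
  sex-specific norm; sit-and-reach inside the recommended range (closed
  interval); one-leg stand held strictly longer than 20 s.
* **Psychological** — GDS-15 total banded 0–5 → 2, 6–10 → 1, 11–15 → 0.
* **Cognition** — MoCA at or above the education-adjusted cutoff → 2,
  below → 0.

## Tie-breaking conventions

Screening rule tables are usually printed for integer measurements, which
leaves gaps once measurements are continuous. The package resolves them
once, consistently, and tests the resulting partition exhaustively:

* **TUG exactly 10 s** fails (scores 0). The pass rule is strict
  (`tug < 10`), the conservative tie-to-fail reading.
* **One-leg stand in (20, 21) s**: the printed rules are "≤ 20 s → 0" and
  "≥ 21 s → 0.5". The package passes iff `balance > 20`, which reproduces
  both printed integer rules and is total over continuous times.
* **Handgrip and MoCA exactly at their cutoffs** pass. Each rule is a
  single step function with its discontinuity at the cutoff.
* **Composite half-points 4.5 and 8.5** (reachable on the 0.5 grid but
  absent from the integer band definitions) resolve downwards: low < 5 ≤
  moderate < 9 ≤ high, so 4.5 is *low* and 8.5 *moderate*. The classifier
  therefore partitions the entire 21-point half-point grid with no gaps or
  overlaps, monotonically in the score.
* **Mixed sensory states** (a device without reported difficulty, or
  difficulty without a device) score 0: any impairment indicator forfeits
  the point.

All sub-scores are exact multiples of 0.5, which is a negative power of two
and hence exactly representable in binary floating point; sums over the
grid are exact and grid-equality tests are safe without integer
bookkeeping.

## Thresholds: what is fixed and what is configuration

The fixed cutoffs above ship as defaults in `ic_thresholds()`. Two inputs
are deliberately *not* fixed, because they are population norms rather than
part of the scoring system:

* the sit-to-stand repetition threshold and the sit-and-reach recommended
  range, by sex and (closed) age band, in the style of senior fitness test
  reference tables;
* the education-adjusted MoCA cutoffs, with free-form education band
  labels matched exactly.

`example_thresholds()` loads a complete configuration whose norm blocks are
**synthetic illustrative stand-ins** (plausible magnitudes, full coverage of
ages 60–99 for both sexes). They keep the scorer executable and testable;
they are not published norms and should be replaced for real analyses.
Age-band matching uses closed integer intervals `[age_min, age_max]` with a
non-overlap invariant enforced at load time, so a boundary age always
resolves to exactly one band.

## The pre/post analysis stage

The study design is a single-arm pre/post comparison with two timepoints
and dropout. `prepost_gee()` fits a marginal model of each outcome on the
timepoint indicator with the participant as the cluster, by generalized
estimating equations:

* families by variable type — identity-link gaussian (`linear`), gaussian on
  the log scale (`log-linear`, for strictly positive skewed outcomes),
  logit-link binomial (`binary-logistic`), and a proportional-odds
  cumulative-logit model (`ordinal-logistic`);
* exchangeable working correlation for the gaussian and binomial families;
* robust (sandwich) variance clustered on the participant, always, so the
  reported standard errors are valid whatever the working structure;
* intention-to-treat: every available row contributes, so a participant
  without a follow-up still informs the baseline mean.

The estimating-equation solver is implemented in the package and validated
in the test suite against an independent reference implementation on a
frozen dataset (point estimates at 1e-8 relative tolerance, robust
standard errors at 1e-6). On complete balanced data the two-timepoint linear GEE has a
closed form — the time effect equals the mean within-participant change —
which the tests verify to high precision across hundreds of simulated
cohorts.

The **ordinal family** is fit as a proportional-odds model under working
independence with a cluster-robust covariance, which is itself a valid
estimating-equation estimator: point estimates are consistent under any
working correlation, and with only two timepoints the efficiency cost of
working independence is second-order. A two-level ordinal outcome is
algebraically a binary-logistic model and is automatically fit as such.

Degenerate inputs (a constant outcome, a binary outcome with an empty cell
at a timepoint) are refused with errors naming the condition;
`analyze_cohort()` captures such per-variable failures in its `error`
column and continues the batch. Significance (5% two-sided Wald) is
reported, never used to filter rows.

## Standardized effect size

The published magnitude bands (below 0.5 small, 0.5–0.8 moderate, above
0.8 large, on the absolute value) presuppose a standardized change score,
but leave its exact construction open. The package's default is

$$\mathrm{SES} = \frac{\overline{\Delta}}{s_{\text{baseline}}},$$

the mean within-participant change over complete pairs divided by the
baseline standard deviation over all participants with a baseline
observation. Alternatives (`pooled-sd`, `change-sd`) are available because
the choice of standardizer is a genuine degree of freedom; the baseline SD
is the default because it keeps the denominator free of the intervention's
own effect. Ordinal variables enter through their integer level codes.

The 95% CI is a participant-level nonparametric percentile bootstrap
(default 2000 resamples, seeded): participants are resampled with
replacement and the whole pre/post pair travels together, which respects
the within-participant dependence. The percentile interval was chosen as
the standard default for this sample-size regime; the test suite checks
its empirical coverage on null cohorts at the study's size (n = 43) across
500 replicates.

## The synthetic cohort generator

`cohort_config()` defaults encode the study conditions: 43 enrolled
participants, 86% women, age 67.7 (SD 4.3) years truncated at 60, 3
dropouts (completely at random, since only the count is reported), and
baseline moments for the secondary outcomes (body fat 37.5 ± 9.5 %, muscle
mass 26.6 ± 4.5 %, abdominal circumference 93.1 ± 10.9 cm, SF-6D
0.84 ± 0.08, heart rate 73.2 ± 12.4 bpm). Raw-measure baselines without
published descriptives (handgrip by sex, TUG, chair stands, sit-and-reach,
balance, GDS-15, MoCA, sensory and appetite flags) use values typical of
community-dwelling Brazilian older adults in exercise programs, chosen once
and kept; they produce scored cohorts concentrated in the moderate band
with occasional low and high classifications, matching the shape of the
published classification table.

Each variable uses a bivariate-normal latent construction: with
$z_1, z_2 \sim N(0,1)$,
$$x_{pre} = f(z_1), \qquad
  x_{post} = f(\rho z_1 + \sqrt{1-\rho^2}\, z_2 + \delta),$$
where $\rho$ (default 0.7) is the latent within-participant correlation and
$\delta$ the configured true effect (natural units for continuous measures,
latent SD units for flags, which are thresholded at the quantile matching
their prevalence). Generated values are rounded to instrument precision and
clipped to their admissible ranges (GDS-15 to 0–15, repetitions to
non-negative integers, and so on), which also makes the CSV round trip
byte-losslessly. True pre/post correlations are unreported in the study, so
`rho` is a free parameter, not an estimate.

What the generator does **not** emulate: the joint correlation structure
*across* variables (each measure has its own independent latent pair),
informative dropout, adherence or session-attendance processes, and any
intervention mechanism. Passing tests on synthetic cohorts therefore
demonstrate the pipeline's statistical correctness under the design's
assumptions, not the study's substantive findings, whose participant-level
data are external.

## Numerical and validation choices

* GEE convergence: Fisher-scoring updates to a relative step tolerance of
  1e-12 (maximum 100 iterations); the exchangeable correlation is
  moment-estimated each iteration and clamped to [-0.99, 0.99].
* Quantiles everywhere use R's default type 7; `descriptive_summary()` of
  `c(1, 2, 3, 4)` gives P25 = 1.75, P75 = 3.25.
* Test problem sizes: the scoring rules are checked against a literal
  decision-table oracle on an exhaustive boundary grid of ~14,000 cells;
  the balanced-cohort closed form on 200 simulated cohorts of the study's
  size; type-I error on 500 null cohorts; effect-size recovery on 100
  cohorts of n = 500 with 2000-resample bootstraps; null CI coverage on
  500 cohorts of n = 43. These sizes are the package's own validation
  choices, balancing Monte-Carlo error against runtime.
* End-to-end determinism: `cmd_simulate()` → `cmd_score()` →
  `cmd_analyze()` under fixed seeds is byte-identical across runs; data
  files carry no timestamps (run metadata lives in the JSON manifests).

## Known limitations

* The norm tables shipped are stand-ins; conclusions about real cohorts
  require the norms actually used in the field.
* The SES definition is one defensible choice among several; published
  effect sizes computed with an unstated formula are not reproduction
  targets.
* The ordinal family reports the time effect as a cumulative log odds
  ratio; with sparse category cells at n ≈ 43 its Wald inference is
  approximate.
* Partial scoring is refused by design (missing raw fields are an error);
  imputation is out of scope.
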