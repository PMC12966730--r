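---
title: "Benchmarking dementia risk scores against cognitive decline: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking dementia risk scores against cognitive decline: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Composite dementia risk indices — ANU-ADRI, CAIDE, CogDrisk, LIBRA and its
update LIBRA2, the UK Biobank Dementia Risk Score with and without APOE, and
a risk-ratio weighted sum over the fourteen Lancet Commission modifiable
factors — summarize a person's demographic, lifestyle and clinical profile
into a single number. They were mostly built to predict incident dementia,
but are increasingly used to study *cognitive decline*. `drscompare`
implements the full analysis chain needed to compare such indices
head-to-head as predictors of later cognitive function (MoCA, 0–30 points)
and of its change over a roughly four-year interval between two cognitive
visits: harmonized score computation from declarative weight tables,
prorating of incomplete scores, inverse-probability-of-attrition weighting,
linear mixed-effects models of level and annual change, and binary-decline
discrimination with paired AUC comparison.

Real cohorts of this design (risk factors measured a decade before the
first cognitive visit, follow-up testing in old age, registry linkage) are
access-restricted. The package therefore ships a first-class synthetic
cohort generator whose defaults emulate such a study, so every stage is
exercised and tested end-to-end without any data download.

## The synthetic cohort

`sim_config()` / `generate_cohort()` draw, per participant:

* age at risk assessment from a truncated normal, mean 66.3, SD 5.6 years,
  range 57.8–89.9; 54.1 % women; education truncated normal 12.7 (2.3)
  years — the demographic structure of a large Norwegian ageing cohort;
* independent binary risk items with the prevalences of
  `default_factor_prevalences()` (hypertension 0.45, physical inactivity
  0.30, diabetes 0.09, APOE-e4 0.27, ...), chosen as plausible values for
  this age band;
* a **true risk burden** $r_i$, a deterministic weighted sum of the items
  (weight 1 each by default) plus centred age (+0.05/year over 65) and
  education (−0.05/year over 12);
* a latent trajectory
  $y_i(t) = b_{0i} + \lambda r_i + (\beta_0 + \gamma r_i + u_{1i})\,t + e_{it}$
  with $b_{0i}\sim N(25.1,\,2.5^2)$, $\lambda=-0.35$ points per burden
  unit, $\beta_0=-0.05$ and $\gamma=-0.05$ points/year, a random slope
  $u_{1i}$ (SD 0.15/year, correlation 0.3 with the level) and residual SD
  1.2;
* an observed MoCA at each visit: the latent value rounded
  half-away-from-zero and clamped to [0, 30], so the instrument's integer
  scale and floor/ceiling are real and floor-effect sensitivity analyses
  have something to detect. Clamping counts are reported on the cohort;
* a follow-up interval truncated-normal 4.2 (0.3), range 2.9–5.2 years;
* second-visit attendance from a logistic model on age and the *latent*
  baseline cognitive level (defaults give ≈ 64 % attendance, with older and
  lower-functioning participants dropping out preferentially — the
  returner/non-returner contrasts in `summarize_cohort()` reproduce the
  familiar pattern); and
* item-level missingness completely at random, 1.5 % per item, which with
  ~22 items leaves roughly a quarter of participants with at least one
  incomplete score.

One user seed is expanded into fixed per-stage substreams
(demographics, items, trajectory, follow-up, attrition, missingness), so a
configuration is byte-reproducible and a change in one stage's consumption
does not shift the others.

What the generator deliberately does **not** emulate: correlated risk
factors (items are independent unless the weights are edited), dementia
incidence and death as competing reasons for dropout, more than two
cognitive visits, practice effects, and non-random item missingness.
Passing tests therefore show that the *pipeline* is correct under its
stated model, not that any substantive conclusion transfers to a specific
real cohort.

## The scoring engine

Each index is a YAML file under `inst/extdata/scores/`: items with a
`source` column, a type (`binary`, `categorical`, `banded`, `linear`), a
points mapping, and a `demographic` flag. The engine (`compute_score()`,
`score_cohort()`) is entirely configuration-driven — replacing a table
changes the scores with no code change. The shipped tables are editable
transcriptions of the published indices; where a source table could not be
reconstructed exactly (LIBRA2, CogDrisk, the ANU-ADRI age/sex points, the
UKBDRS linear slopes) the file says so and carries plausible values in the
published style. The CAIDE file encodes the original integer point model
(the published non-APOE variant), stated in its header.

Scores with no native demographic weights (LIBRA, LIBRA2, Lancet) declare
`augment_demographics_from: anu_adri` with `augment_items: [age, sex]`, so
the loader appends the ANU-ADRI age and sex items for head-to-head
comparability; `strip_demographics()` removes every demographic-flagged
item again for the demographics-free replication, and the two operations
are inverse on the item set.

**Prorating.** A participant missing some items is rescaled to the score's
full range:
$$\text{prorated} \;=\; \frac{\sum \text{observed item points}}
{\sum \text{max possible risk points over available items}}
\times \text{theoretical maximum}.$$
Two conventions make this well-defined for scores with protective
(negative) weights: a discrete item contributes $\max(0, \text{item
maximum})$ to both the denominator and the theoretical maximum, so
protective-only items can never zero or negate the denominator; and linear
items (UKBDRS age and education) are evaluated at configured anchors — 100
years of age, 20 years of education — even though the education slope is
negative, because that is the stated convention of this score's theoretical
maximum. A profile with *no* observed item raises an explicit unscorable
error (a silent zero would distort the score distribution); in cohort
scoring such participants are flagged, excluded from that score's analyses
and counted in the run log.

**Standardization and grouping.** `zscore()` uses the sample (n−1) standard
deviation, the convention of mainstream statistical software. Tertiles cut
at the 1/3 and 2/3 empirical quantiles (linear-interpolation quantiles) of
the standardization sample; ties at a cutpoint go to the lower group, a
deterministic rule that keeps assignments reproducible. Both are computed
once on the full baseline analysis sample and can be reused on subsamples
via their `mean_used`/`sd_used`/cutpoint attributes.

## Attrition weighting

`fit_participation_model()` fits a maximum-likelihood logistic regression
of second-visit attendance on baseline covariates (default: age, education,
heart disease, depression, diabetes, hypertension, stroke — established
predictors of attrition in ageing cohorts), erroring loudly on perfect
separation or degenerate outcomes. Weights are reciprocal predicted
probabilities, truncated at the 99th percentile of the weight distribution
(linear-interpolation quantile; ties at the cap are all truncated), which
caps roughly the upper 1 % of weights. The weights are fitted once on the
baseline analysis sample and reused across analyses, entering mixed and
logistic models as observation-level weights; weights of exactly 1
reproduce the unweighted fits bit-for-bit, which is tested.

Why attrition on the *latent* level matters: if dropout depended only on
covariates and outcomes that are themselves in the fitted model, a
likelihood-based mixed model would already be valid under that missingness
and weighting would be redundant. Attrition driven by the latent cognitive
level — which the analyst never observes, only proxies — is the regime in
which unweighted two-visit fits genuinely understate score-related decline,
and the regime in which the package's weighted-vs-unweighted property test
operates (attrition log-odds 0.6 per latent point, level/slope correlation
0.8, slope SD 0.6; the participation model uses observed first-visit MoCA
and age as proxies).

## Mixed models of level and change

`build_long_table()` produces one row per available visit (time 0 at the
first cognitive visit; the follow-up interval in years at the second), so
non-returners still inform the level part of the model. `fit_lmm()` fits
`moca ~ time * score + (1 + time | id)` — the time × score coefficient is
the additional annual MoCA change per SD of score (or per tertile vs low).
With only two observations per participant the random-slope covariance is
weakly identified; singular fits fall back, with a logged notice, to random
intercepts only. The fallback is expected, not exceptional, at this design,
and the fixed effects — the estimand — are recovered either way, which the
parameter-recovery suite verifies. REML is the default; ML is used whenever
a likelihood-ratio comparison of fixed effects is requested
(`compare_models()` refits as needed and flags variance-component
comparisons as boundary-conservative). Moderation models add age group
(under/over 65 at risk assessment) and sex, crossed with score and time up
to the three-way terms that express group-specific score-related decline;
they are intended for demographics-stripped scores, since moderating a
score that contains its own age weights is collinear by construction.

## Binary decline and discrimination

Decline is a drop of ≥ 3 raw MoCA points between visits (about one SD of
observed change; the threshold is on the integer point scale, not in z
units), with sensitivity thresholds 2/4/6/9 and baseline floor exclusions
(< 18/20/22/24) available as a grid. AUCs use the Mann–Whitney convention
(ties count half) with DeLong placement-value variances, and
`delong_test()` compares two markers on the same labelled participants via
the covariance-adjusted z statistic. These are implemented from placement
values in the package rather than delegated, because paired AUC comparison
is a load-bearing output; an independent implementation (pROC) serves as a
cross-check in the test suite, and a Monte-Carlo experiment verifies
type-I-error calibration. Single-marker AUCs are computed from the fitted
logistic model's linear predictor, which for a single marker is a strictly
increasing transform of the marker and hence identical to the raw-marker
AUC (property-tested); the demographics benchmark is a logistic model on
age and education.

## Numerical and design choices

* MoCA observation: round half away from zero, then clamp — R's default
  round-half-to-even would bias adjacent integer scores differently.
* Attrition and missingness draws use inverse-CDF sampling so each stage
  consumes a fixed amount of the stream regardless of parameter values.
* Cohort CSVs serialize doubles through `%.17g` and so round-trip exactly;
  configuration YAML uses 15 significant digits.
* Empty moderator cells, degenerate tertiles, one-class AUC cells and
  non-estimable descriptive contrasts degrade with named errors, warnings,
  or explicit `estimable = FALSE` flags rather than silently.
* Pipeline outputs contain no timestamps; provenance is the seed, package
  version and a hash of the configuration, so identical runs are
  byte-identical.

Test problem sizes are chosen to make the statistical checks sharp but the
default run quick: binomial/prevalence checks at n = 5000 against exact
99 % binomial intervals, mixed-model recovery at n = 2000 with 100
replicates per true effect (0, −0.05, −0.20 points/year/SD), DeLong null
calibration with 500 replicates at n = 200, the weighting comparison with
100 replicates at n = 1000, and the end-to-end determinism check at
n = 400–500 with toy score tables.

## Known limitations

* The shipped weight tables are working transcriptions, adequate for
  methodological use and fully editable, but they are not a validated
  clinical implementation of any index — anyone applying them to real data
  should audit each YAML against its source publication first.
* Independent risk items overstate how distinguishable the indices are on
  synthetic data (real risk factors cluster); a correlation structure can
  be emulated only by editing the generator weights.
* Two-visit data cannot separate random slope variance from residual
  variance well; conclusions about variance components (as opposed to
  fixed effects) should not be drawn at this design.
* IPW assumes the participation model is correctly specified given its
  covariates; the package implements plain (unstabilized) weights with
  upper truncation and nothing more elaborate.
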