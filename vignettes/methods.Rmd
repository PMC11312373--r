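---
title: "Methods: inflammation scoring, survival models and life-expectancy attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inflammation scoring, survival models and life-expectancy attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflascore)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter and their defaults, the
numerical conventions, what the synthetic cohort emulates (and what it
does not), and the design choices taken where more than one defensible
option existed.

## The INFLA-Score

The score summarises low-grade systemic inflammation from four routine
blood quantities: CRP (mg/L), white blood cell count, platelet count and
the neutrophil-to-lymphocyte ratio NLR = neutrophils / lymphocytes
(undefined, and treated as an exclusion, when lymphocytes are zero). Each
marker is ranked into population deciles; deciles 1–5 score −4…0 and
deciles 6–10 score 0…+4; the four components are summed, so totals live
in [−16, +16] and are approximately normal in a large population.

Numerical conventions, chosen once for reproducibility:

* **Quantile rule.** Decile cut-points are empirical quantiles with
  linear interpolation (the common "type 7" rule). A value exactly at a
  cut-point is assigned to the *lower* decile.
* **Mapping variants.** The mapping above (`"halves"`) assigns 0 to both
  deciles 5 and 6. The original composite-index literature phrases it as
  deciles 1–4 → −4…−1, 5–6 → 0, 7–10 → +1…+4 (`"bonaccio"`). Written
  out decile by decile the two phrasings induce the *same* integer
  mapping; both spellings are kept so users can see this and so future
  variants have a place to live.
* **Directions.** All four markers score positively (higher = more
  inflammatory) by default. Platelet count is occasionally discordant in
  cohort data, so its direction is configurable per marker
  (`fit_decile_map(..., directions = )`), which mirrors the decile order
  before the points mapping.
* **Population.** The decile map is fitted on the full analysis
  population, not sex-stratified, matching how population tenths are
  described for this score.

Exposure groups are empirical quantile bins (`bin_exposure`): quartiles
for the main analyses, quintiles for a sensitivity analysis, tertiles for
diet scores. With heavily tied integer scores, ties never split a block:
values equal to a cut-point go to the lower bin, so occupancy is equal
only up to tie blocks. All-equal input is a binning error.

## Outcomes

Follow-up runs from the baseline visit to the earliest of death, loss to
follow-up, or the administrative censoring date (default 2022-02-01);
years use 365.25 days. Premature death is death strictly before age 75
(74.9 counts, 75.0 does not). Deaths at or after 75 enter the
premature-death model as censoring events — by default at the death date,
optionally at the 75th birthday (`premature_censoring = "age75"`); the
conventional death-date choice is the default because the risk-set
handling for this outcome is otherwise under-determined.

Cause groups are matched on the 3-character ICD-10 category (sub-codes
ignored): CHD I20–I25, stroke I60–I64 plus I69, respiratory J00–J99,
cancer C00–C97, diabetes E10–E14. The age-related hospitalization outcome
takes a user-supplied list of qualifying categories (one code or range
per line, `#` comments); the packaged
`aging_disease_codes_example.txt` is an explicitly synthetic example of
23 common age-related categories so that demos and the generator can run
end-to-end — real analyses should substitute the study-specific list.

## Survival models

Cox proportional-hazards models are fitted by partial-likelihood
maximisation with the **Efron** tie correction (coarse time units make
ties common; Breslow is available by flag). Hazard ratios are reported
with Wald 95% intervals exp(β ± 1.96·SE) — the convention for large-n
cohort reporting. The trend test refits the model with the exposure coded
1..k as a single ordinal term and reports its Wald p-value. The
adjustment set (`default_adjustment()`) is age, sex, race, smoking,
drinking, BMI, MET, Townsend index, healthy-diet group, hypertension,
supplement and medication flags, and baseline CVD/cancer/diabetes/
respiratory disease; subgroup runs drop the stratifier from the set and
report inestimable strata as `NA` rows rather than failing.

Dose–response uses a natural (restricted) cubic spline with 4 knots at
the 5th/35th/65th/95th percentiles of the score — the standard default
where no knot placement is prescribed — with the outer knots as boundary
knots. The curve is referenced to the score median (HR = 1 there, exact
by construction) with delta-method bands, and non-linearity is tested by
a likelihood-ratio test of the spline model against the model linear in
the score (df = spline df − 1).

These are standard estimators, so the implementation stands on
`survival::coxph` and `splines::ns`; the test suite nevertheless verifies
the partial-likelihood maximum against a hand-written Efron
log-likelihood maximised by grid search, and checks parameter recovery,
null behaviour and invariance to affine covariate rescaling.

## Life-expectancy attribution

Given a reference mortality schedule m_ref(a), ages 40–100, group
prevalences p_g and age-constant hazard ratios HR_g for premature death
(reference group HR = 1), the group schedules are

    m_Q1(a) = m_ref(a) / Σ_g p_g·HR_g,   m_g(a) = HR_g · m_Q1(a),

so the prevalence-weighted mixture reproduces the reference at every age
(enforced to 1e−12). Each schedule runs through single-year life-table
arithmetic: q(a) = m(a)/(1 + ½·m(a)) (mid-interval deaths), l by
recursion from l(40) = 1, L(a) = l(a) − ½·d(a), terminal closure
L(100) = l(100)/m(100), e(a) = T(a)/l(a). The expectancy gap is
Δe_g(a) = e_Q1(a) − e_g(a).

Choices worth making explicit:

* **Age-constant HRs 40–100.** The hazard ratios come from a
  premature-death model (events < 75) but are applied across the whole
  age range, as the attribution method describes; this is flagged here
  because it extrapolates the proportional effect beyond the ages that
  identified it.
* **Prevalences.** Quartiles imply 0.25 each, the default; sex-specific
  empirical prevalences can be supplied.
* **CIs.** Propagated by substituting each group's HR bound in turn
  (others at point estimates) and re-running the full calibration; a
  parametric bootstrap (log-normal HR draws consistent with the Wald CI)
  is available since the CI method for such attributions is rarely
  stated.
* **Reference table.** The packaged
  `uk_life_table_synthetic.csv` is a synthetic Gompertz–Makeham schedule
  m(a) = A·e^{B(a−40)} + C per sex, with (A, B) fitted so the resulting
  life table matches recent UK national period expectancies at ages 40
  and 60 (men 40.5/22.5 y, women 43.8/25.2 y); C = 3e−4 is a small
  age-independent (Makeham) term. It stands in for an official national
  life table, which users should substitute for real work
  (`read_life_table(path)` with columns `sex, age, m`).
* **Oracle.** The life-table arithmetic is checked against a discrete
  cohort simulation (1-year steps, mid-interval deaths, exponential
  residual lifetime past 100) — agreement within 0.05 y.

With the printed sex-specific premature-death quartile hazard ratios
(men 1 / 1.10 / 1.25 / 1.68, women 1 / 1.11 / 1.20 / 1.47), equal
prevalences and this reference table, the Q4 gaps evaluate to about
5.05/4.32 y (men, ages 40/60) and 3.60/3.21 y (women) — the same scale
as published cohort estimates of roughly 5.0/4.1 and 3.4/3.0 y.

## Dietary pattern scores

The 6-point healthy-diet covariate awards one point each for red meat
≤ 3 times/week, vegetables ≥ 4 tablespoons/day, fruit ≥ 3 servings/day,
fish ≥ 4 times/week, grains ≥ 5 servings/week, urinary sodium
≤ 70.6 mmol/L; ≥ 3 points is a "healthy diet".

The three pattern scores follow their canonical published definitions,
because the exact component cut-offs used alongside this score in cohort
supplements are not always public:

* **HEI-2020** (0–100): 13 components, 9 adequacy and 4 moderation,
  each scored by linear interpolation between a zero-score and a
  max-score standard on a density basis (per 1,000 kcal, % of energy, or
  the (MUFA+PUFA)/SFA ratio). The standards ship as an editable CSV
  (`hei2020_standards()`), so alternative cut-offs can be swapped in
  without code changes.
* **MED** (0–9): one point per beneficial component (vegetables,
  legumes, fruit+nuts, cereals, fish, MUFA:SFA) at or above the cohort
  median, per detrimental component (meat, dairy) below it, and for
  moderate alcohol (men 10–50 g/day, women 5–25). Medians are
  sex-specific by default, as the score was defined for mixed cohorts;
  `sex_specific = FALSE` gives whole-cohort cuts.
* **DASH** (8–40): cohort quintile ranks summed over 8 components,
  reversed for sodium, red/processed meat and sweetened beverages.

Intakes from repeated 24-hour recalls (1–5 per participant) are averaged
before scoring (`average_recalls`), making scores invariant to averaging
order. Missing components yield `NA` scores — participants drop from diet
analyses but remain in the main analyses.

## Joint and modification analyses

The joint analysis cross-classifies diet-score tertile by INFLA quartile
into 12 cells, with the *highest-risk* combination (lowest diet tertile,
highest inflammation quartile) as the reference so protective cells read
as HRs below 1; a single Cox fit carries the 11 indicators plus the usual
adjustment set (minus the healthy-diet covariate, which would overlap the
exposure). Effect modification is assessed the way such analyses are
reported: independent refits within each tertile with per-stratum trend
tests. A product-term Wald interaction test is available
(`interaction_test = TRUE`) but labelled an extension — stratified
estimates, not a single p-value, are the primary output, and
interpretation is left to the user.

## The synthetic cohort generator

`generate_cohort(cohort_config(...))` is first-class, tested code: it
defines the study conditions under which every estimator is validated.

**What it emulates.** Marginals matched to published cohort moments: age
normal 57 ± 8 truncated to the 40–70 recruitment window; 54% men; CRP
log-normal with mean 2.59 and SD 4.34 mg/L (the SD exceeding the mean is
why a right-skewed law is required); platelets, neutrophils, lymphocytes
gamma (positivity) with moments 253 ± 60, 4.22 ± 1.41, 1.96 ± 1.13,
truncated at clinically plausible caps; WBC built as neutrophils +
lymphocytes + a residual gamma component, so the differential is
internally consistent and the WBC mean matches 6.88 ± ~2. Covariate
prevalences follow the published Table-1-style margins (e.g. 10% current
smokers, 27% hypertension, 38% CVD). Dependence comes from a Gaussian
copula: an exchangeable latent factor among the blood markers
(correlation 0.3 — a free parameter, since cross-marker correlations are
not published) plus a shared latent *lifestyle* factor (loading 0.3)
that raises inflammatory markers while lowering beneficial food-group
intakes, giving the non-degenerate diet × inflammation cells the joint
analyses need.

**Event processes.** Death times are Weibull on the age scale (age at
baseline + increment; shape 1.1, scale 180 y), so premature death
(< 75) is well-defined; the log hazard adds the participant's INFLA
quartile effect (defaults 0, ln 1.1, ln 1.25, ln 1.6 — the magnitudes of
published premature-death associations), a MED-tertile main effect
(0, −0.08, −0.15), an optional tertile attenuation of the quartile
effect (the effect-modification truth), and age (0.09/y, centred at 57)
and male-sex (0.45) terms. The quartile and tertile are computed on the
generated cohort itself, and the truth is exposed as
`true_infla_q`/`true_med_t` for recovery studies. Hospitalizations and
loss to follow-up are independent exponentials (0.02 and 0.01 per
person-year); recruitment dates are drawn with a late skew across
2006–2010 (recruitment ramped up over the window) so that administrative
censoring at 2022-02-01 yields a median follow-up near the published
12.65 years (realised ≈ 12.3). Defaults give roughly 5–7% premature
deaths and ~25% age-related hospitalizations.

**What it does not emulate** — and hence what passing tests do and do
not show about real data: no real food-frequency instrument (food groups
are simulated directly, not derived from item-level recalls); no
measurement error or within-person biomarker drift; loss to follow-up is
non-informative by construction; hazards are exactly proportional and
the death hazard ignores attained-age acceleration beyond the baseline
age term; disease-flag covariates are independent of the event process
given the modelled terms. Estimator validation on this cohort
demonstrates statistical correctness of the machinery, not robustness to
the confounding structures of observational data.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` use these sizes, chosen as the
package's own balance of precision against runtime:

* Score-oracle agreement: 1,000 random panels, exact match required.
* Parameter recovery: five cohorts of n = 50,000 (generator defaults);
  every quartile estimate within 3 SE of truth.
* Null CI coverage: 200 replicates of n = 3,000 via the lean
  exponential simulator (`simulate_ph_groups`); coverage expected near
  95%.
* Life-table oracle: 2 × 10^6 simulated lives; agreement within 0.05 y.
* Spline size/power: 200 replicates each — linear truth at n = 2,000
  (p-values uniform), J-shaped truth at n = 20,000 (detection ≥ 95% at
  p < 0.05).
* Effect modification: 200 replicates of n = 30,000 with the quartile
  effect switched off in the top tertile; the high-tertile stratum must
  look null while the low-tertile stratum excludes 1 in ≥ 90% of
  replicates.

The lean simulators are used for the repeated-fit studies because the
repetition is about the *estimators*, not the cohort structure; the full
generator is used wherever the cohort structure itself is under test.

## Known limitations

* Competing risks are handled cause-specifically (censoring), not by
  subdistribution (Fine–Gray) models — matching the analysis style this
  package reproduces.
* The premature-death HRs are extrapolated to ages 40–100 in the
  life-expectancy attribution, as described above.
* HEI-2020/MED/DASH use canonical published standards; a study
  supplement with different cut-offs should be loaded via the standards
  CSV / configuration rather than assumed identical.
* The packaged reference life table is synthetic (calibrated, labelled
  as such); official national life tables should be substituted for
  substantive estimates.
* Proportional-hazards diagnostics beyond a Schoenfeld smoke check, and
  frailty/random-effects terms, are out of scope.
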