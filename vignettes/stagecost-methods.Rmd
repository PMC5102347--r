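---
title: "Methods: stage-stratified costing of endometrial cancer with censoring-aware imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-stratified costing of endometrial cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagecost)
```

## The estimation problem

Hospital-activity databases record inpatient episodes and outpatient
appointments up to a fixed extraction date. For a cohort of women diagnosed
with endometrial cancer (EC) over several years, the five-year cost history
of recently diagnosed patients is therefore *administratively censored*:
follow-up ends because the data end, not because costs stopped. Naive
complete-case analysis discards exactly the patients diagnosed latest, and
annualising observed costs is biased because cost accrual is strongly
front-loaded for early-stage disease. `stagecost` estimates stage-specific
mean discounted five-year costs under this censoring by multiple imputation
of period costs, with survival information that extends beyond the cost
window.

## Costing model

Costs attach to *spells* (admission to discharge), not episodes. Episodes of
one patient with identical, overlapping or contiguous admission intervals
form one spell; the spell is reimbursed at the tariff of its *dominant*
(most expensive) episode, with ties broken by the earliest episode (this
affects only category labelling, never cost). Episodes missing a casemix
(HRG) code — about a fifth of inpatient records in the motivating data —
are resolved through an OPCS-procedure-to-HRG map; episodes resolving to
neither are costed at zero and counted in a diagnostic attribute rather
than silently dropped.

Each HRG carries a trim point `T` (days of stay its tariff covers) and a
per-day excess rate. With spell length of stay `L`:

`nominal = tariff + max(0, L - T) * excess_rate`

All inpatient admissions are treated as elective (the data carry no
admission type). Tariff-derived costs are uplifted by a configurable
2005→2012/13 hospital price-index factor (default 1.20; the index value is
a user input, not a package claim) and by the average market-forces factor
1.08. Outpatient appointments are retained only when an oncology or
gynaecology specialty (or a procedure code) is present. Within
oncology-specialty appointments, near-daily runs of ≥ 5 visits (gaps ≤ 3
days) are costed as radiotherapy fractions and remaining runs of ≥ 3 visits
with gaps ≤ 35 days as chemotherapy deliveries; both thresholds are
configurable because no interval rule is standard. All other retained
appointments receive a flat £135 (a 2012/13 figure, so it receives the MFF
only — a deliberate uniformity choice surfaced in the configuration).

Events are classified as **surgery** (hysterectomy/BSO spells, plus any
event before the surgery date or — for patients without surgery — within a
42-day post-diagnosis grace window, including pre-diagnostic
investigations), **adjuvant** (chemo/radiotherapy series) or **further**
treatment (everything else). Costs in annual bands anchored on the
diagnosis anniversary are discounted at 3.5%/year, band 0 (first year and
the six-month pre-diagnostic window) undiscounted. The costing window is
half-open: an event on the five-year anniversary day is excluded.

## Synthetic cohort generator

No public linkage of the motivating cohort exists, so the generator is a
first-class module: it encodes the study conditions and provides held-out
truth for bias testing. Per stage (AEH, IA/IB, IC, II, III, IV) it draws:

* stage with probabilities 22/277/88/65/34/5 ÷ 491; age and BMI from
  stage-specific normal distributions; deprivation quintile; Charlson score
  (positive with stage-specific probability, then 1 vs 2 at 80/20);
  grade and histology mixes that shift adverse with stage;
* time to death from a stage-specific exponential law with rate
  `-log(S5)/5` (S5 clipped to [0.005, 0.995]), snapped to mid-month; a
  39/61 fraction of deaths carry EC as underlying cause;
* events: 0–3 pre-diagnostic gynaecology visits; overnight diagnostic
  work-up spells on non-overlapping odd-day slots (days 1–11); a
  hysterectomy/BSO spell on days 14–42 with Poisson length of stay
  (occasionally a second in-spell episode, exercising the dominant-episode
  rule); an adjuvant oncology series every 21 days from day 60; and
  further-treatment events from a two-piece Poisson process — one rate to
  month 6, another thereafter — each event an inpatient readmission
  (probability 0.3, or 0.6 for stages III/IV) or an outpatient review.
  All events are truncated at death; 20% of inpatient episodes have the
  HRG blanked with OPCS retained; covariates are blanked at rates 0.4%
  (histology), 3.2% (grade), 0.4% (IMD) and 0.8% (BMI).

**Calibration.** The free intensities (diagnostic-spell mean, adjuvant
visit count, the two further-treatment rates) are solved at parameter
construction from closed-form expectations that integrate the exponential
survival function against the step discount factor on a daily grid, so the
*population expectation* of discounted five-year cost equals the configured
stage mean exactly, and the two-year surgery and adjuvant category means
are matched as well. Two deliberate departures: (i) where the configured
two-year further-treatment mean is incompatible with a non-negative early
rate (the AEH column) the early rate is clipped to zero and the five-year
total — the quantity the package reports — is matched exactly; (ii) a
fixed-point first-order correction inflates the readmission rates for the
tariff revenue lost when two nearby readmissions merge into one spell.
Diagnostic spells sit on non-overlapping slots for the same reason: spell
merging is an engine rule, and the calibration must describe what the
engine will actually compute.

The generator emulates the statistical structure the analysis depends on —
stage-dependent cost level and timing, survival, administrative censoring
at 31 March 2010 with death linkage to June 2014, missingness — but not
real coding vocabularies (only the handful of OPCS/ICD codes the pipeline
inspects), calendar trends in treatment intensity, within-patient cost
correlation beyond what the event processes induce, or non-exponential
hazard shapes (a piecewise construction can be layered on, but only the
five-year survivor fraction is calibrated). Recovery tests on synthetic
data therefore demonstrate internal consistency of the estimators under
these conditions, not external validity on real HES extracts.

## Multiple imputation

The five-year window is split into ten six-month periods. A period is
*observed* when wholly before the cutoff or when the patient's death
precedes the cutoff (after death the rest of the history is known);
periods starting after death are structural zeros — death is not censoring;
a period partially beyond the cutoff for a live patient is *censored*. We
deliberately censor partially observed periods rather than keep their
truncated costs, which would bias period costs downward.

Because administrative censoring is monotone, the chained-equations pass is
sequential: each period's model regresses observed costs on stage, age,
BMI, grade, histology, Charlson, deprivation, all earlier (completed)
periods, and two survival-linkage indicators (death within the period,
death within five years), among patients alive at the period start.
Censored cells are filled by predictive mean matching — a Bayesian draw of
the regression coefficients, then a random draw among the five observed
donors closest in predicted value — which guarantees non-negative imputed
costs on the observed support without distributional assumptions about the
heavily right-skewed cost data. Categorical covariates (grade, histology,
IMD) are imputed from multinomial models on stage and age at their
fitted-probability draws; at missingness of a few per mille the omitted
parameter-uncertainty term is negligible. BMI uses the same PMM machinery.
`m = 25` imputations by default; estimates and squared standard errors are
pooled by Rubin's rules with Barnard–Rubin small-sample degrees of freedom.
Medians and SDs are reported from the first completed dataset, flagged as
such, because pooling order statistics is ill-defined.

For interval estimates two routes exist: the Rubin t-interval from the
pooled variance, and a bootstrap that resamples patients first and then
applies a single stochastic re-imputation inside each replicate
(percentile intervals over 1,000 replicates by default). The second is the
package's composition of bootstrap with imputation; the order is a design
choice — resampling first propagates sampling *and* imputation noise
without nesting full MI inside every replicate.

## Regression and survival

Cost regressions are OLS per completed dataset, pooled on the coefficient
scale, with pre-specified covariates: age centred on 65, Charlson dummies
(1, 2+), BMI class (< 18.5, > 30; 18.5–30 reference), stage (AEH
reference), diagnosis year (whole years since January 2002), histology
(endometrioid/AEH vs other), grade (1 reference) and deprivation quintile
(middle reference). Reference levels are inferred from which dummies the
motivating analysis reports. Empty factor levels carry no dummy; genuinely
collinear designs raise an error naming the aliased columns.

Survival uses the longer mortality window, mirroring death-registry linkage
that outlives the cost extract. Kaplan–Meier estimates carry Greenwood
standard errors; Cox models use Efron tie handling (mid-month snapping
creates heavy ties) with all-cause and EC-specific endpoints, other-cause
deaths censored in the latter; the Therneau–Grambsch test uses the
Kaplan–Meier time transform. With multiply-imputed covariates the log
hazard ratios are Rubin-pooled and diagnostics run on the first completed
dataset.

## Numerical conventions and degenerate inputs

Months are 30.4375 days and years 365.25 days throughout; dates of birth
and death sit on the 15th of the month, with same-month deaths clamped to
the diagnosis day. Currency is kept at full precision internally. A
one-patient stage cell reports mean = median with SD 0; an empty cell
reports n = 0 with blank statistics; a bootstrap of a single patient
collapses to the point. `pool_rubin` requires m ≥ 2 and guards the
zero-between-variance case. The exclusion cascade applies reasons in a
fixed order (review outcome, then incomplete hospital data, then missing
stage) so that a candidate matching several is counted once under the
earliest; the order follows the sequence in which the motivating cohort
reports them.

## Problem sizes

The test suite exercises the full pipeline at 5,000 patients with 15
imputations (stage IA/IB then holds ≈ 2,800 patients and stage III ≈ 350),
Kaplan–Meier recovery at 10,000 single-stage patients, PH-test calibration
over 120 replicates of n = 250, and bootstrap coverage over 80–100
replicates of n = 250–300 — sizes at which Monte-Carlo error is small
relative to the three-standard-error acceptance bands while the whole
suite runs in well under a minute. The acceptance script uses 5,000
patients with m = 25 and a 10,000-patient survival cohort.

## Known limitations

* The tariff table shipped is synthetic; real applications must supply the
  national tariff and OPCS map.
* The generator's event-level distributions (visit counts, lengths of stay,
  series spacing) are the package's own constructions calibrated only to
  published aggregate means; event-level fit to real HES data is untested.
* Emergency vs elective tariffs, primary-care costs and quality-of-life
  outcomes are out of scope, as in the motivating analysis.
* Inverse-probability-weighted cost estimators (Bang–Tsiatis) are not
  implemented; imputation is the package's approach to censoring.
* The imputation model assumes costs are stationary in calendar time given
  covariates; a real cohort with improving data capture would need a
  diagnosis-year term in the period models.
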