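---
title: "Methods: causal DAG-guided mixed-model analysis of dog activity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal DAG-guided mixed-model analysis of dog activity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caniact)
```

## The scientific problem

Collar accelerometers classify each day of a pet dog's life into a count of
minutes spent in medium-to-high-intensity activity. Linked to veterinary
electronic health records (EHRs), such data allow population-scale questions:
how does daily activity vary with a dog's age, breed size, sex, neuter
status and body condition, and with its environment (climate, season,
weekday vs weekend, urban vs rural location, owner age)? Because the data
are observational, covariate adjustment must be justified by explicit causal
assumptions rather than by whatever happens to be measured. `caniact`
implements that full workflow — causal graph, two-source record linkage,
covariate derivation, filtering, mixed-model inference with resampling, and
a nonparametric cross-check — and, because real accelerometer/EHR data of
this kind are proprietary, pairs it with a synthetic-data generator with
recorded ground truth so every stage can be validated by parameter recovery.

## The causal graph and adjustment sets

A `causal_dag` stores observed and latent nodes plus directed edges.
The package computes:

* **d-separation** (`d_separated()`) by the moralized-ancestral-graph
  criterion: restrict to ancestors of the query nodes, moralize, delete the
  conditioning set, test connectivity. The test suite verifies it against an
  independent brute-force path-enumeration oracle (chains/forks blocked iff
  their middle node is conditioned on, colliders blocked iff neither the
  collider nor any descendant is conditioned on) on hundreds of random DAGs.
* **Minimal backdoor adjustment sets** (`minimal_adjustment_sets()`): a set
  of observed non-descendants of the exposure is valid iff it d-separates
  exposure and outcome in the graph with the exposure's outgoing edges
  removed. Enumeration proceeds by increasing subset size over observed
  candidates in the ancestral set, skipping supersets of sets already found,
  and refuses pools above 25 candidates (exponential guard).
* **Implied conditional independences** (`implied_independences()`): one
  claim per non-adjacent pair with a smallest-cardinality separating set,
  ties broken lexicographically. Emission is invariant to node declaration
  order because nodes are stored sorted.

The bundled graph (`activity_dag()`) is the package's working hypothesis for
the data-generating process: dog attributes (age, breed size, sex, neuter
status, weight status), health mediators (unhealthy diagnosis, injury,
which age, size and weight status feed into), owner and environment
variables, and one latent node (exercise opportunity, fed by location and
climate). It is shipped as an editable text file, not ground truth. Under
this graph the dog-attribute exposures need adjustment for
`{owner_age, location_type}` (both confound breed size, which owners choose),
while the environmental exposures need no adjustment beyond their
co-exposures (latitude confounds climate but is itself in the model).

### Testing a DAG against data

`test_independences()` works in the linear regime, the default testing
regime of common DAG software: both members of a claim are residualized on
the indicator-encoded conditioning set by least squares. Scalar pairs use
the partial-correlation t test with `n - 2 - q` degrees of freedom;
categorical-vs-scalar pairs use the equivalent added-variable F test; pairs
of categoricals use Pillai's trace. On data simulated faithfully from the
graph (`simulate_dag_gaussian()`) the false-rejection rate is calibrated at
the nominal level.

Repeated daily records are not independent observations, so the pipeline
tests each claim at the coarsest observational unit its variables allow:
claims among dog-constant attributes on one row per dog (dog age as its
per-dog mean), visit-level variables as per-dog means or on one row per
visit, and only genuinely record-level claims on rows. Without this, claims
such as *breed size independent of injury* are tested against thousands of
pseudo-replicated rows from a few hundred dogs and reject spuriously.
Record-level claims involving calendar variables retain an optimistic
effective sample size; the reported rejection rate for those should be read
as a screening diagnostic. One rejection is structural rather than
spurious: within a two-year window a dog's age advances with the calendar
date, so *age independent of season* fails mildly in any finite window.

## The synthetic two-source study

`sim_config()` defines the world; `simulate_cohort()`, `simulate_visits()`
and `simulate_activity()` realize it; `simulate_study()` packages the
two sources an analyst would receive: an activity source (demographics +
daily records) and an EHR source (demographics + visits).

The outcome model is multiplicative. For dog *i* on date *j*:

log *A(i,j)* = intercept + beta_age * age^-2 + breed-size effect +
(per-size age interaction) * age^-2 + sex + neuter + weight status +
owner age + location + climate + latitude slope + season + day type +
season x climate + owner-age x weekend + *u(i)* + *e(i,j)*,

with *u(i)* ~ N(0, tau2) a per-dog random intercept and *e(i,j)* ~
N(0, sigma2) record noise; active minutes are exp of this, rounded to
0.1 min. Age enters as inverse-square years, which produces a steep decline
through young adulthood that flattens in later life. Defaults: intercept
log(45) minutes; beta_age 2.4; tau2 = sigma2 = 0.2; categorical effect
presets on the log scale (for example -0.24 for toy breeds vs the
medium-large reference, +0.114 for weekends, -0.082 for winter) follow the
sign and magnitude patterns reported for real cohorts of this kind but are
presets for a synthetic world, not reproductions of any fitted table. The
per-size age-interaction preset makes the age decline steeper for larger
breeds. The latitude preset is 0.005 per degree — a printed per-degree
coefficient an order of magnitude larger would imply implausible
cross-country activity ratios, so it is treated as preset-only. Weights are
drawn per breed-size band with a 2% margin from the classification
cut-points; visit weights are the ideal weight inflated by 1/0.8 (score
4/5) or 1/0.6 (score 5/5), the exact inverse of the analysis-side
correction, with 3% lognormal measurement noise; about 30% of visits record
body condition on the 9-point scale.

Two measurement artefacts give the cleaning stages real work:

* with probability `anomaly_prob` a daily record is replaced by an
  out-of-range value (< 10 or > 600 min), mimicking partial device wear or
  user error;
* with probability `unlinkable_prob` a dog's EHR-side match key is
  perturbed (misspelled name or a birth month off by one), so deterministic
  linkage must fail for it.

What the generator deliberately does **not** emulate: raw 3 Hz accelerometer
signals (the activity-minutes algorithm is upstream of this package's
scope), real geography or geocoding (climate and rurality are attributes),
informative visit timing, seasonal activity trends caused by weather rather
than by the season label, and measurement error in the outcome beyond the
anomaly channel. Passing recovery tests therefore shows the *inference
machinery* is correct under the assumed model — not that the model captures
every feature of real accelerometer data.

## Linkage and filtering

`match_dogs()` performs deterministic exact matching within household on
species, sex, normalized name (lower-cased, trimmed, punctuation stripped —
an idempotent normalization) and birth date at month-year precision. Keys
matching zero or several candidates are excluded rather than assigned;
same-name littermates are therefore dropped from both sides.

`link_activity_to_visit()` joins each daily record to the visit with the
greatest visit date on or before the record date, at most 365 days earlier
("within one calendar year" is interpreted as a 365-day span, so leap-day
ties resolve by day count). Records with no qualifying visit are dropped;
one visit may serve many records.

`apply_filters()` runs a fixed, logged cascade with configurable thresholds
(`filter_config()`):

1. **bounds** — drop rows with under 10 or over 600 active minutes
   (inclusive bounds survive);
2. **ratio** — drop all rows of dogs with fewer than five activity rows per
   distinct linked visit;
3. **age** — drop rows where the dog is not strictly between 1.5 and 12
   years old at both the record and the linked visit date;
4. **minimum records** — drop dogs with at most 7 surviving rows
   (strictly more than seven are required), evaluated last.

The exact order of these stages is a package choice (the order is not
derivable from the study design); each stage logs rows and dogs in and out
so alternative orders can be audited, and the cascade is idempotent.
`split_healthy()` then flags the healthy-visits subset:
`in_healthy_visits = in_all_visits & health_status == "healthy" & !injury`.
This is slightly stricter than removing only unhealthy/injury-linked
records — visits that are neither unhealthy nor preventive-care
("other") are excluded too, so the healthy subset is exactly the
preventive-care stratum.

Derived covariates (`build_analysis_table()`): 9-point body condition
scores translate two-per-unit onto the 5-point scale (4-5 -> 3, 6-7 -> 4,
8-9 -> 5; 1 -> 1, 2-3 -> 2 by the same rule); recorded weights of dogs
scored 4/5 and 5/5 are multiplied by 0.8 and 0.6; a dog's breed size is the
mean of its corrected adult (> 1.5 years) visit weights classified against
the cut-points 6.5 / 9 / 15 / 30 / 40 kg (left-open right-closed, toy at or
below 6.5, giant above 40); weight status dichotomizes the score at 4;
visits are classified unhealthy (any chronic-illness code, historic codes
included), else healthy (preventive-care reason), else other, with an
independent injury flag; seasons are northern-hemisphere meteorological and
weekends are Saturday and Sunday.

## Mixed-model inference

`fit_lmm()` fits log active minutes with the spec's fixed effects and a
per-dog random intercept by REML (`lme4::lmer`), with age entering as
`I(age^-2)`. Confidence intervals are Wald (estimate +/- 1.96 SE) — the
interval method is a package choice. The conditional pseudo-R-squared is
(fixed + random variance) / (fixed + random + residual), the random-effect
share is reported against the same total, and RMSE is on the log scale.
Singular fits (random variance collapsing to zero) are returned with a flag
rather than an error. Factors that collapse to a single level in a subset
are dropped from that fit with a message, since their contrast is
inestimable.

`select_interactions()` evaluates candidate interactions one at a time, in
order, against the current specification: maximum-likelihood refits compared
by likelihood-ratio test, keeping a candidate only when p < 0.05 *and* the
AIC decreases. ML (not REML) refits are the standard requirement for
comparing fixed-effect structures.

`resampled_inference()` implements the repeated-subsample strategy: per
repetition, draw K records per dog without replacement (dogs with fewer
records contribute all — they already passed the 8-record floor, so
dropping them would waste the cohort), fit, and collect. Aggregation
(`aggregate_repetitions()`) takes the arithmetic mean of estimates and of
interval endpoints, and the p-value of a term is the fraction of
repetitions whose interval contains zero — so p is granular in units of
1/R. The default K is 50. Repetitions that fail to fit are skipped and
counted; more than 10% failures aborts the run.

This aggregation is nonstandard, so the package treats its operating
characteristics as empirical properties to be measured, not assumed: the
acceptance suite verifies parameter recovery (mean aggregated estimate
within Monte-Carlo error of the generating value for every term), interval
coverage of the truth in the 90-99% band, near-nominal p for null effects,
decisive p for a 0.2 log-unit effect at 500 dogs, and monotonicity of the
median p in effect size.

`estimate_marginal_means()` predicts on the response scale for each level of
a focal predictor with other categoricals at reference levels, continuous
covariates at data means, and zero random effect; the back-transform is a
plain exponential. The log-normal mean correction
exp((tau2 + sigma2)/2) is implemented behind `bias_correct` but off by
default: the naive exponential predicts the *median* response, the
corrected one the mean, and the median is the more robust summary under the
model's heavy right tail. For aggregated inference the interval is the
2.5-97.5 percentile band of per-repetition linear predictors. Reference-grid
prediction (not population averaging) is the default interpretation of
"holding other variables constant".

`grouped_kfold_consistency()` partitions dogs (never records) into k
near-equal folds, fits the model per fold, and reports coefficient and
metric SDs across folds.

`check_multicollinearity()` screens predictor pairs with absolute Pearson
correlation (continuous), Cramer's V (categorical) and the multiple
correlation from indicator encoding (mixed), flagging values above 0.5.

## Flexible-model validation

`fit_flexible_model()` is the nonparametric cross-check: gradient-boosted
trees (xgboost; defaults eta 0.05, depth 4, 400 rounds, no subsampling so
the fit is exactly reproducible under its seed) on log active minutes with
*all* DAG predictors — a flexible learner does not need the adjustment set.
The repeated-measures grouping uses a one-step backfit: fit, shrink the
per-dog residual means empirical-Bayes style using moment estimates of the
between- and within-dog variances, refit on the outcome minus the shrunken
dog effects. Fully demeaning the outcome by dog — the obvious alternative —
destroys all between-dog signal and would make dog-level effects (sex,
breed size) invisible to the trees, which is why the backfit is used
instead. It remains an approximation to a jointly estimated random
intercept: whatever dog-level signal the first-stage fit misses is absorbed
into the dog effects and lost to the second stage, slightly compressing
dog-level effect curves.

`compare_marginal_curves()` sets the focal variable to each grid value over
the whole data set, averages the log-scale predictions (partial
dependence), back-transforms, and reports the maximum absolute difference
in minutes and the Spearman rank correlation against the linear model's
marginal means. The comparison is one-way validation: flexible-model
results are never fed back into the linear specification.

**A scaling caveat that shapes the agreement study.** Beyond age five or so
the conditional age curve varies by under 2%, while the between-dog
intercept noise contributed to each region of an estimated curve is roughly
sqrt(tau2 / dogs-per-age-bin) — about 6% for a few hundred dogs at
tau2 = 0.2. At desk scale the raw binned means themselves show spurious
upturns of that size, so *no* estimator can rank-order the flat tail of the
curve there; at population scale (tens of thousands of dogs) the same noise
is negligible. The agreement study therefore scales the variance components
with the cohort size (tau2 = 0.005, sigma2 = 0.03 at 600 dogs, 40
records/dog), preserving the population-scale signal-to-noise exactly as
the cohort size itself is scaled down, and keeps the agreement thresholds
(rank correlation at least 0.9; sign agreement for contrasts of at least
0.05 log units) unchanged.

## The pipeline

`run_pipeline(run_config(seed = ...))` sequences simulate -> match -> link
-> derive -> filter -> DAG checks -> models -> k-fold -> flexible
validation. The dog-attribute models (all-visits and healthy-visits) use
the DAG-indicated adjustment (union of the first minimal adjustment set per
exposure, minus co-exposures); the environmental model (all-visits only,
since dog attributes do not confound the environmental exposures under the
graph) uses the environmental variables alone. The master seed fans out to
fixed per-stage offsets, so every stage and the whole report are
reproducible; a failed stage is recorded and downstream stages are skipped.
With `out_dir` set, coefficient tables, marginal means and a diagnostics
JSON are written. The package's interface is these R functions;
`scripts/acceptance.R` in the source repository is a thin Rscript that runs
the pipeline end to end and writes its headline numbers.

## Problem sizes and numerical choices

Validation studies run at desk scale, chosen to finish in minutes on one
CPU while keeping every statistical check well-powered: recovery uses 50
replicates of 150 dogs x ~40 records (K = 30, R = 15); the power study uses
500 dogs where a 0.2 log-unit effect must be detected; interaction
selection uses 100 seeds of 100 dogs with a generous interaction (the
inverse-square age predictor has little spread at adult ages, so per-size
age-slope differences must be large to be detectable at that size); the
agreement study uses 600 dogs as described above; independence-test
calibration uses 200 Gaussian datasets of n = 500. The pipeline default
`R = 1000, K = 50` mirrors the study design; validation runs pass smaller
`R` explicitly.

Degenerate inputs are handled explicitly: cyclic or malformed DAG text and
unknown nodes raise parse/lookup errors naming the problem; adjustment-set
enumeration refuses candidate pools over 25 nodes; constant columns skip
independence tests with a warning; zero-variance outcomes flag singular
fits; `k = 1` cross-validation returns undefined SDs with a degenerate
flag; empty interaction-candidate lists return the spec unchanged.

## Known limitations

* The bundled DAG is a plausible transcription of the hypothesized process,
  shipped as an editable input; conclusions about adjustment sets are
  conditional on it.
* The linear residualization behind the independence tests detects only
  linear (partial) association, and record-level claims involving calendar
  variables retain an optimistic effective sample size.
* The backfitted dog effect in the flexible model is an approximation to a
  jointly estimated random intercept and slightly compresses dog-level
  partial-dependence contrasts.
* The fraction-of-CI p-value has no closed-form null distribution; its
  operating characteristics are established empirically by the test suite
  under the generator's conditions only.
* The generator's effect presets are synthetic-world values; nothing in the
  package reproduces coefficients estimated from proprietary data.
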