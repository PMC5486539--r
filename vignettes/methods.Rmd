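---
title: "Methods: classifying and modelling active-season body temperature in a heterothermic rodent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and modelling active-season body temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dormouseTb)
```

## The measurement problem

Implanted temperature loggers (iButton-class, 0.5 °C resolution, one
sample every 3850 s) record core body temperature (Tb) in edible dormice
(*Glis glis*) across the active season.  Three operational states carry
the biology:

* **torpor** — Tb < 32 °C; controlled metabolic suppression, occurring in
  short daytime bouts (< 24 h) during the active season and in multiday
  bouts during hibernation;
* **euthermia** — regulated normothermic Tb between the cutoffs;
* **slight hyperthermia** — Tb > 40 °C, reached at night during intense
  locomotor activity; the daily time above 40 °C ("hours above") is the
  package's proxy for locomotor effort.

From per-sample states the package derives bouts, daily summaries,
weekly animal-level metrics, and two phenological dates: hibernation
onset (entry into the first multiday torpor bout in fall) and
parturition (a sudden sustained rise of roughly half a degree in daily
mean Tb).

## Classification and aggregation rules

**Strict cutoffs.** A reading of exactly 32.0 °C is euthermic and 40.0 °C
is euthermic.  At 0.5 °C logger resolution no observable reading can sit
between "just below" and "at" a cutoff, so the convention is
observationally neutral — but it is fixed and documented here.

**Route correction.** Subcutaneous implants read about 2 °C below
intraperitoneal ones during the nocturnal active phase; the activity
threshold is therefore lowered to 38 °C for subcutaneous series
(`effective_thresholds()`).  The torpor cutoff is not corrected: a
30 °C subcutaneous reading is torpid either way.

**Hours above.** Daily hours above the activity threshold are the count
of hyperthermic samples times the sampling interval.  At hourly cadence
this interval weighting is the simplest defensible estimator and carries
a quantisation of roughly ±0.5 h/day on daily totals; interpolating
between samples would add assumptions without adding information.

**Bouts.** Maximal runs of one state form bouts; a data gap longer than
twice the nominal interval closes the bout, so logger outages cannot
fabricate multi-hour bouts.  Bout duration is (last − first sample time
+ one interval).  Torpor bouts are *short* below 24 h and *multiday* at
or above it; 24 h is adopted from the standard contrast between
active-season torpor ("typically < 24 h") and hibernation-type bouts.

**Days and weeks.** The day boundary is local midnight, so the nocturnal
active phase splits across two calendar days — as it does in any
per-calendar-day metric.  Days with fewer than 12 samples are flagged
incomplete and excluded from weekly means.  Weeks of year are fixed
7-day blocks anchored at January 1 (week 35 is then the last week of
August in every year); ISO weeks would shift block boundaries between
years and locales.  Weeks relative to hibernation count backwards from
week 0, the 7 days ending at onset.  Weekly values are means over an
animal's complete days; weeks with fewer than 4 complete days are
dropped, and the weekly mean of daily maximum Tb first discards daily
maxima of 35 °C or less so that multiday torpor cannot contaminate a
maximum-Tb profile.

**Hibernation onset.** The start date of the earliest multiday torpor
bout beginning on or after August 1.  The fall window is needed because
occasional multiday summer-dormancy bouts would otherwise be mistaken
for hibernation entry; the date is configurable.

## The parturition detector

Parturition produces an abrupt, sustained rise in daily mean Tb.  The
detector works on torpor-free complete days (one torpor day depresses
the daily mean by tens of degrees and would dominate any step
statistic).  For each day *d* in the search window (weeks 26–37 by
default, covering late-July to late-August births) it computes the
symmetric contrast

c(d) = mean(mean Tb over the k days after d) − mean(mean Tb over the k
days up to d),

with k = 5.  Local maxima of c with c ≥ 0.3 °C whose mean contrast over
the following k days stays positive become candidates; the candidate
date is d + 1 (the first elevated day), the step estimate is c(d), and
the score is c(d) over the residual SD of detrended daily means.
Day-level persistence checks proved brittle at realistic daily-mean
noise (a single 1-day wiggle would veto a genuine step), which is why
persistence is enforced on the mean of the following contrasts.  The
detector returns all candidates ranked by score, supporting the
two-step pattern of a lost first litter followed by a replacement
litter.

## The synthetic cohort generator

No public data accompany the analyses this package implements, so the
generator is the test-bed: it emulates annual dormouse Tb/Ta records
with known ground truth, calibrated so the full pipeline reproduces the
published cohort-level summaries.  The default configuration *is* the
study design: 7 females and 7 males per year, one mast year (2013)
between two mast-failure years (2012, 2014), sampling every 3850 s,
0.5 °C quantisation.

Each animal-year contains:

* a circadian baseline — daytime rest phase near 36.2 °C, nocturnal
  active phase near 38.3 °C, with per-animal (SD 0.18 °C), per-day
  (SD 0.07 °C) and per-sample noise;
* one contiguous nocturnal hyperthermic block per night, anchored
  mid-night, whose Gamma-distributed duration tracks a
  sex-by-mast-by-week target profile.  Contiguous blocks (rather than
  scattered hyperthermic samples) match the continuity of activity and
  make hours-above recovery exact up to interval weighting;
* daytime short torpor days, drawn per day from a seasonal probability
  that is damped on warm days and on high-activity days, with torpor Tb
  tracking daily ambient temperature plus 2 °C with a 5 °C floor
  (invented: only the < 32 °C definition constrains it);
* for mast-year females: a gradual gestational rest-phase rise to
  37.3 °C, the late-pregnancy activity dip (< 2 h/day above 40 °C,
  minimum Tb held near 36.9 °C), a parturition step of +0.49 °C in the
  daily baseline, and a lactation minimum-Tb elevation of +1.37 °C
  relative to non-reproductive females, decaying after week 35.  The
  active-phase share of the step is derived from the configured daily
  mean step and phase sample counts, so the injected daily-mean step
  equals the configured value by construction;
* a pre-hibernation maximum-Tb ramp: nightly peak temperatures rise
  over weeks −7…−1 to 40.45 °C and fall to 39.53 °C in week 0, when
  activity collapses;
* Bernoulli test drops in the final week (80 % of animals show them;
  some show none), then entry into a multiday torpor bout on the onset
  date, mid-September to mid-October.

**Calibration by construction.** Activity targets and torpor rates are
rescaled per animal so that the expected mean over the analysed weeks
(week 20 up to the week before onset) equals the configured group mean
(4.20 / 2.53 / 2.06 / 2.55 h/day; 2.29 vs 0.26 torpor days/week).
The one remaining free parameter — the strength of the torpor–activity
coupling — was set by a coarse grid search so that the pooled weekly
correlation between torpor frequency and hours above threshold matches
the published −0.39; the calibrated value (−0.6 per target-hour) ships
as the default.  Enclosure mode scales the activity targets by the
ratio of the published site means (2.32/2.90) and leaves torpor
untouched (site does not affect torpor frequency); subcutaneous mode
subtracts 2 °C from active-phase samples, so hours-above at the
corrected 38 °C threshold equal the intraperitoneal values.

**Quantisation margins.** Hyperthermic samples are generated at
≥ 40.3 °C raw and euthermic active samples at ≤ 40.2 °C, so 0.5 °C
quantisation maps them to ≥ 40.5 and ≤ 40.0 respectively; torpor is
capped at 30.9 °C raw.  Per-sample classification of a generated trace
therefore equals the ground-truth labels exactly, which is what the
oracle tests assert.

**What the generator does not emulate.** Weather-driven activity
bursts, body-mass dynamics, logger drift, gaps and explant artefacts,
social synchrony between animals, and litter loss are absent.  Passing
the closed-loop tests therefore shows that the pipeline recovers the
structure the generator encodes at realistic noise — not that it is
robust to every failure mode of field data.

## The inferential stage

Weekly animal-level rows feed linear mixed models fitted with
`nlme::lme`: a per-animal random intercept and an AR(1) within-animal
residual correlation indexed by week.  Week enters as a categorical
factor — the published degrees of freedom for week terms equal the
number of observed week levels, indicating factor coding.  Tests are
type-3 Wald chi-squares (`car::Anova` under sum-to-zero contrasts).
Skewed responses (maximum and mean Tb) can be Box-Cox transformed; the
exponent is chosen by profile likelihood on a fixed grid (−2…2, step
0.01).  The pseudo-R² is the squared correlation between marginal
(fixed-effects) fitted values and the observed response; the marginal
level is used because the week-scheme comparison asks which *predictor*
explains more variance, and conditional fits would mask that with the
random intercepts.  Interactions are screened and only significant ones
retained; no multiple-testing correction is applied, matching the
source analysis.  Non-convergence is an explicit `status = "failed"`
result, never a silent fallback.

Within a single year mast does not vary; such constant terms are
dropped with a warning rather than producing a singular fit.

**Simulation sizes.** The calibration of the Wald tests is checked on
tables drawn from the model itself: 60 animals × 25 weeks for the
500-replicate null (the type-3 Wald test on a between-animal term is
asymptotic, and materially fewer weeks per animal lets the AR(1)
absorb part of the between-animal variance, inflating the type-I
error — a property of the estimator, not of this implementation), and
42 animal-years × 12 weeks at the published effect magnitude
(+2.14 h/day for mast-year females) for the power check.  The
parturition benchmark uses 100 reproductive females, mirroring the
±3-day agreement reported against nest-box juvenile ageing.

## Known limitations

* The torpor Tb law and the ambient-temperature climate are plausible
  stand-ins (temperate deciduous forest), not fitted to any site data.
* Calendar-day metrics split the active phase across days; per-night
  aggregation would be an alternative but would not match the
  per-day definitions used here.
* The Wald type-3 tests are asymptotic in the number of animals; with
  very few animals per group a parametric bootstrap would be more
  defensible than the chi-square reference.
* Week-level degrees of freedom depend on observed week coverage, so
  model tables from synthetic cohorts need not match any published
  degrees of freedom.
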