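---
title: "Correcting programme-level mortality for loss to follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting programme-level mortality for loss to follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltfucorrect)
library(tibble)
```

## The problem

Antiretroviral-therapy (ART) programmes in resource-limited settings lose a
substantial fraction of their patients to follow-up, and patients who
disengage from care die at much higher rates than those who stay. The
standard Kaplan-Meier analysis censors lost patients at their last visit,
which silently assumes they die like patients who remain in care. When they
do not, the programme-level mortality estimate is biased downward — often
severely: a programme can report 1.4% one-year mortality while the mortality
of everyone who started ART is closer to 11%.

`ltfucorrect` implements the simple, field-usable correction: programme
mortality is a weighted average of mortality among patients retained and
patients lost,

$$M_C = (1 - r)\,M_{NL} + r\,M_L,$$

which, divided by $M_{NL}$, yields a correction factor

$$C = (1 - r) + r\,\frac{M_L}{M_{NL}}$$

that converts the observed mortality among retained patients into a
corrected programme-level estimate, $M_C = C \cdot M_{NL}$. $C$ can be read
off a nomogram of straight lines (one per proportion lost $r$) against the
mortality ratio $M_L/M_{NL}$; all lines pass through $(1, 1)$, because equal
mortality in both groups means no bias.

## Inputs and where they come from

Three quantities, which must refer to the same period (here: the first year
of ART):

* **`r`** — the proportion lost to follow-up. From patient-level data this
  is computed with the nine-month rule: a patient whose last visit is more
  than `window_days` (default 274 days) before the database closure date is
  lost; patients who started ART within `window_days` of closure never had
  the chance to be classified and are ineligible. The closure date defaults
  to the most recent visit in the table. One deliberate refinement: a
  patient whose death was ascertained by the programme is retained — a
  known outcome is not loss to follow-up — otherwise every early death
  would be misclassified as lost and `r` inflated.
* **`m_nl`** — Kaplan-Meier cumulative mortality at the horizon among
  retained patients, computed through `survival::survfit()` with Greenwood
  variance and complementary log-log confidence limits (the
  boundary-respecting default; linear and log transforms are selectable).
* **`m_l`** — mortality among patients lost, which no programme observes
  directly. Either a *tracing* estimate (outreach ascertains vital status of
  a sample of lost patients) or a *meta* prediction from the published
  logistic meta-regression
  $M_L = \operatorname{logit}^{-1}(a + b\,r)$ with $a = 0.57287$,
  $b = -4.04409$ and $r$ a fraction. The negative slope reflects that
  programmes losing many patients lose many low-risk self-transfers.

```{r box1}
# the worked tracing-method example: 40.5% lost, 2.2% mortality among
# retained, 20% among traced lost patients
correct_mortality(tibble(r = 0.405, m_nl = 0.022, m_l = 0.20))
```

## The prediction band and how it was calibrated

The meta-regression's variance components were never published; the only
recoverable evidence about its uncertainty is the set of eleven printed 95%
intervals for predicted $M_L$. `calibrate_interval()` therefore fits a
spread on the logit scale to those intervals by least squares. Three
structures are offered:

* a single **constant** symmetric spread (closed form: half the mean
  logit-scale interval width divided by $z_{0.975}$);
* an **asymmetric** pair of spreads below/above the curve;
* the default **leverage** form: a symmetric spread whose *variance* is
  quadratic in $r$, $s(r)^2 = v_0 + v_1 r + v_2 r^2$.

The leverage form is the package's own design choice. It is the structure a
regression prediction variance actually has
($\widehat{\mathrm{var}}(\hat a) + 2r\,\widehat{\mathrm{cov}}(\hat a,\hat b)
+ r^2\,\widehat{\mathrm{var}}(\hat b) + \tau^2$), so the band widens away
from the covariate mean of the calibration studies — visibly so at the
smallest $r$, where a constant spread under-reproduces the printed upper
bound by more than 3 percentage points while the leverage fit keeps every
reproduced bound within about 2.5 points of print. The residuals are stored
on the model rather than asserted away:

```{r calibration}
m <- meta_model()
glance(m)
```

Whether the published band was a confidence band for the mean curve or a
prediction interval for a new programme is not stated in the source; the
calibration treats it as a single band and records how well it is
reproduced, which is all the printed evidence supports.

Predictions are labelled valid for first-year-of-ART loss to follow-up
only; `predict_mortality_lost()` warns when asked about horizons beyond
about 18 months, where the mix of reasons for disengagement (death, silent
transfer, financial constraints) is different and the regression has no
support.

## Uncertainty propagation

`monte_carlo_ci()` propagates uncertainty in all three inputs into a 95%
interval for $M_C$ by simulation (default 100,000 iterations). The
distributional choices are the package's own, selected to be
boundary-respecting and derivable from exactly what a programme reports,
and each is overridable through `mc_spec()`:

* $r \sim \mathrm{Beta}(n_{lost} + \tfrac12,\; n_{retained} + \tfrac12)$
  (Jeffreys) from the classification counts;
* $M_{NL}$ and traced $M_L$: Jeffreys Beta from death counts, or a normal
  on the logit scale with its spread back-solved from the reported 95% CI;
* predicted $M_L$: normal on the logit scale around $a + b r$ with the
  calibrated spread $s(r)$.

The three draws are independent, matching the way the three uncertainty
sources are reported separately. The headline point estimate is always the
deterministic plug-in value — simulation supplies only the interval — and
the percentile interval is fully reproducible from the recorded seed.

`coverage_check()` validates the construction: it simulates programmes with
known true $M_C$, forms the interval from each realised summary, and
reports the fraction covering the truth, which sits between 0.90 and 0.99
at the nominal 0.95 in the shipped tests (500 replications of programmes
with 2,000 eligible patients, 2,000 iterations per interval — sizes chosen
to estimate coverage to about a one-percentage-point standard error).

## The synthetic cohort generator

`simulate_cohort()` produces patient-level records with known truth so the
whole pipeline is testable without any real cohort. Patients are lost with
probability `true_r`; death times follow a constant-hazard exponential
calibrated so that $P(T \le \text{horizon})$ equals the group's true
mortality exactly (an optional multiplier front-loads hazard into the first
90 days, reflecting that patients who disengage often die soon after,
while preserving the calibration). Lost patients stop visiting early enough
to satisfy the nine-month rule and their deaths are invisible to the
programme — only the tracing subsample (default 17% of the lost, the order
achieved by outreach programmes) reveals vital status, evaluated at the
horizon. Enrolment is uniform over a three-year span ending
`window_days + horizon_days` before closure, so every simulated patient is
LTFU-eligible with a fully observable horizon.

What the generator does *not* emulate: covariates (CD4, sex, age), silent
transfers as a distinct state from death among the lost, calendar trends,
left truncation, or tracing that reaches patients at varying times. Passing
the recovery tests therefore shows the estimators are consistent under
clean informative loss, not that any real programme satisfies these
assumptions.

```{r recovery}
sim <- simulate_cohort(8977, true_r = 0.405, true_m_nl = 0.022,
                       true_m_l = 0.20, seed = 2024)
sm <- summarize_programme(sim$cohort)
correct_mortality(sm)[, c("m_u", "m_nl", "m_l", "c", "m_c")]
```

## Numerical and interface choices

* All proportions live in $[0,1]$ internally; percentages appear only at
  I/O (`units = "percent"`, CLI `--percent`) and in printed output
  (correction factors to 2 decimals, percentages to 1 decimal). Files with
  values above 1 are rejected unless they declare `# units=percent` —
  never silently rescaled.
* "Nine months" is fixed at 274 days ($9 \times 30.44$, rounded), and
  configurable, since no month length is canonical.
* Dates are ISO 8601 calendar dates; durations are whole days; a death on
  the day of ART start is an event at duration 0.
* Retained patients are censored at their last visit by default
  (`censor_at = "closure"` is available); deaths recorded after a patient
  was classified lost are excluded from $M_{NL}$ and the naive $M_U$ —
  the programme does not know about them — but feed traced $M_L$.
* $M_{NL} = 0$ with $M_L > 0$ leaves $C$ undefined (flagged `NA`) while
  the weighted average $M_C$ is still reported; $r = 1$ returns
  $M_C = M_L$ with a warning that $M_{NL}$ is then based on nobody.
* A traced patient found dead without a recorded death date counts as an
  event at the horizon, so that with no earlier censoring the traced
  estimate equals the crude proportion dead — the desk-calculation it
  should reduce to.
* The nomogram family of lines (2.5% steps to 30%, then 5% steps to 50%)
  is a readability choice, not a reproduction of any published list.

## Known limitations

The correction is a sensitivity-analysis tool, not a causal fix: it stands
or falls with the $M_L$ input. Tracing samples may miss the hardest-to-find
(and highest-mortality) patients; the meta prediction carries wide
uncertainty that the Monte-Carlo interval makes visible but cannot shrink.
$M_{NL}$ itself can be biased by informative censoring among retained
patients, which nothing here corrects. The method applies to a single
user-chosen horizon (one year by default); multi-interval corrections,
competing risks, and weighted-KM / double-sampling estimators that use
tracing data directly are out of scope.
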