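---
title: "Segmented interrupted time series with AR(1) errors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented interrupted time series with AR(1) errors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itsar)
```

## The problem

In April 2012 Korea replaced its tiered generic-pricing rules with the
"Single Price System" (SPS), cutting the reimbursement price of a large set
of off-patent drugs at a stroke. Because the national insurance system files
a claim for essentially every prescription in the country, the policy can be
evaluated as an interrupted time series (ITS): build monthly series of drug
cost and utilization for the diabetic outpatient population, let the series
run through the intervention date, and ask whether the level or the trend
changed when the policy arrived. A second policy in the observation window,
the Outpatient Prescription Incentive Program (OPIP, October 2010), is
handled the same way as a covariate interruption so that its effect is not
attributed to the price cut.

`itsar` implements that full evaluation as a reusable, tested pipeline. The
original claims data are confidential, so the package pairs the estimator
with a synthetic claims generator whose ground truth is known exactly; every
stage of the analysis can therefore be checked against what was put in.

## The model

For month $t = 1, \dots, 54$ (January 2009 to June 2013):

$$
Y_t = \beta_0 + \beta_1\,\mathrm{time}_t + \beta_2\,\mathrm{OPIP}_t +
\beta_3\,\mathrm{timeafterOPIP}_t + \beta_4\,\mathrm{SPS}_t +
\beta_5\,\mathrm{timeafterSPS}_t + \beta_6\,\mathrm{Feb}_t + \varepsilon_t
$$

`time` is the 1-based month counter; each policy contributes a level
indicator (0 before, 1 from its start month on) and an elapsed-time counter
(0 before, 1 in the start month, counting up thereafter); `Feb` flags
Februaries, whose fewer dispensing days depress utilization. The policy
start month itself is coded as post-policy. With the default schedule the
OPIP terms switch on at month 22 and the SPS terms at month 40, so
`timeafterOPIP` runs to 33 and `timeafterSPS` to 15 in June 2013.
$\beta_1$, $\beta_1 + \beta_3$ and $\beta_1 + \beta_3 + \beta_5$ are the
baseline, post-OPIP and post-SPS segment slopes; $\beta_2$ and $\beta_4$ are
the two abrupt level changes.

Monthly series are short and serially correlated, so the errors are modelled
as a stationary AR(1) process, $\varepsilon_t = \rho\,\varepsilon_{t-1} +
u_t$ with $u_t \sim N(0, \sigma^2)$ i.i.d. and $\varepsilon_1$ drawn from
the stationary distribution $N(0, \sigma^2/(1-\rho^2))$.

## Estimation and model choice

`its_fit()` estimates the model twice:

* **OLS** via the standard linear-model machinery, with the Gaussian
  log-likelihood evaluated at the ML variance $\hat\sigma^2 = RSS/n$.
* **Exact AR(1) maximum likelihood.** The exact stationary likelihood is
  profiled over $\rho$: for fixed $\rho$ the Prais–Winsten transform
  ($y_1^* = \sqrt{1-\rho^2}\,y_1$, $y_t^* = y_t - \rho y_{t-1}$, same for
  the design) reduces the GLS problem to least squares, and
  $\ell(\rho) = -\tfrac n2\{\log(2\pi S/n)+1\} + \tfrac12\log(1-\rho^2)$
  is maximised by a bracketed 1-D search on $(-0.999, 0.999)$ to
  tolerance $10^{-8}$. A single AR parameter makes this more robust than a
  general multivariate optimiser, and there is no convention ambiguity:
  positive $\hat\rho$ means positive serial correlation. A search ending
  within $10^{-3}$ of the boundary flags the fit and warns. Standard errors
  come from the observed information (numerical Hessian of the exact
  likelihood in $(\beta, \rho, \sigma^2)$ coordinates) at the optimum, with
  two-sided normal p-values.

The final model is the one with the smaller AIC, with all free parameters
counted ($k = 8$ for OLS: seven coefficients plus $\sigma^2$; $k = 9$ for
AR(1)); only with every parameter counted are the two likelihoods
comparable. Ties go to OLS, the smaller model. The Durbin–Watson statistic
is reported on both fits as a diagnostic, with a Monte-Carlo p-value
obtained by projecting i.i.d. Gaussian errors through the same design
(seeded, one-sided against positive autocorrelation) — the null distribution
of DW depends on the design matrix, so tabulated bounds are unnecessary.
Where significance of serial correlation and minimum AIC could disagree,
AIC decides and DW is reported alongside; this is the one place the
published description leaves the precedence open, and a single unambiguous
rule was preferred. Residual ACF/PACF values against the
$\pm 1.96/\sqrt{n}$ band (`white_noise_check()`) complete the diagnostics.

`confint()` uses t quantiles with $n - p$ degrees of freedom for both
methods, matching the linear-model convention; this is the package's
small-sample choice and slightly widens AR(1) intervals relative to normal
quantiles.

### A caution on AR(1) interval coverage at n = 54

The package's own simulations (see the acceptance suite) show that at the
54-month design with $\rho \approx 0.28$, exact ML underestimates $\rho$
substantially (detrending seven regressors absorbs much of the
low-frequency variation), and model-based standard errors evaluated at
$\hat\rho$ then understate the sampling variability of $\hat\beta$ by
roughly 20%: empirical coverage of nominal 95% intervals is about
0.83–0.93 depending on the coefficient, even though the estimates
themselves are unbiased. This is a property of the method at this series
length, not of the implementation (which agrees with an independent
dense-covariance likelihood evaluation to $10^{-6}$ and with a generalized
least squares cross-check to $10^{-4}$). Interval statements on AR(1) fits
at this design should be read accordingly.

## Counterfactuals and policy effects

The counterfactual series sets the SPS level and slope columns to zero in
the design and applies the fitted coefficients: the pre-policy trend
extended "as if the policy were not in existence". Effects are computed
between model predictions (with-policy vs counterfactual) rather than
observed-vs-counterfactual: this matches the forecast framing and is robust
to month-to-month noise; the observed series is available in the
`counterfactual()` output for anyone wanting the other contrast.

Three percent summaries are reported, because a single "percent effect in a
year" admits more than one reading: the cumulative percent over post-policy
months 1–12 (the headline figure), the endpoint percent at a stated horizon
(12 or 15 months), and the arithmetic mean of the per-month percent
differences. The confidence band around the counterfactual covers its
*mean* (coefficient-covariance based, $x^\top \hat V x$), not a new
observation, which is what a forecast-trend band in this design shows.
Percent effects are undefined when the counterfactual is not bounded away
from zero; the package raises an error rather than returning an unstable
ratio.

Complication-procedure burden is summarised as monthly episodes per 1000
cohort patients in consecutive 12-month periods; `annual_growth()` computes
period-over-period absolute change (2 decimals) and percent growth rounded
half away from zero to an integer — the only rounding rule consistent with
all fifteen published transitions simultaneously.

## The synthetic-data generator

The generator emulates the statistical structure of the study, not its
confidential content. Its defaults are the study conditions: a 54-month
window from January 2009, interruptions at months 22 and 40, true
aggregate-cost coefficients equal to the published overall-cost row
(billion KRW), $\rho = 0.282$ (the published AR(1) value for that outcome)
and innovation SD 0.8 billion KRW, inside the 0.86–1.78 range of
within-period SDs in the published descriptive table. One integer seed
governs everything: each named substream (series noise, patient attributes,
claims allocation, contamination, procedure counts) derives its own seed as
`(seed * 1009 + hash(stream)) mod (2^31 - 1)`, so any stage can be
reproduced in isolation.

Patient-level claims are generated to hit known aggregate targets: monthly
treated-patient counts per price group exactly, and monthly cost totals up
to half a KRW per record (record costs are whole KRW, as claims are in
practice). Quantity and DDD per record follow from the registry — quantity
is the cost share divided by the era-appropriate unit price, and DDD is
quantity divided by the WHO DDD or, for entries without one, the standard
adult daily dose. Cost and DDD targets cannot be set independently once
`cost = quantity × price` is enforced at the record level, so patient
counts and costs are the claims-level ground truth and DDD series follow
from prices; independent DDD series are available from the aggregate-level
generator. The published classification of 97 antidiabetic ingredient codes
with 32 price-cut ingredients sets the default registry shape.

Two guarantees make the cohort stage testable. Every pool patient receives
one diagnosis-only outpatient visit inside the index window, so cohort
selection cannot silently drop a patient the targets rely on; and
contamination records (under-20 patients, non-diabetic diagnoses, a few
inpatient events) are generated deliberately so the filters have something
to remove. Per-patient cost and quantity distributions are conventions of
this generator — the study reports no patient-level distributional facts —
so tests exercise aggregate contracts, not distributional shape. The
default pool is 2000 patients, a desk-scale stand-in for the roughly four
million real ones; complication events, being aggregate Poisson draws, use
the full four-million denominator by default. Monthly event counts per
category are Poisson with mean `rate/1000 × cohort size`, rates stepping
through consecutive 12-month periods at the published magnitudes.

What passing tests do *not* show about real data: the generator's months
are balanced (no claim spans months), prices change once on a single date,
diagnosis codes are independent across claims, and there is no prescription
shifting, entry of new ingredients, or demographic drift. Conclusions about
the estimator transfer; conclusions about Korean claims behaviour do not.

## Cohort and aggregation rules

Diagnosis matching is by 3-character ICD-10 category (E11, E14), since the
study cites category-level codes only. Age at the first qualifying claim
decides eligibility; the reference date is otherwise unspecified and this
is the simplest reproducible rule. A patient dispensed drugs from both
price groups in a month counts once in each group's patient series and once
in the overall distinct count, so group series are self-contained and the
overall count is not a sum of group counts. Months with no treated patients
yield missing per-patient values, not zeros. Period summaries use the
sample SD (n−1); single-month periods report a missing SD.

## Numerical choices and degenerate inputs

Missing months in the fit window are an error, not an imputation target:
the covariates are calendar-defined, so a gap would silently shift every
counter. Singular designs abort with the names of the dependent columns.
The Durbin–Watson statistic is undefined for all-zero residuals and errors.
The DW Monte-Carlo p-value is invariant to residual scaling by
construction. Growth percentages with a zero earlier rate are undefined and
error rather than returning infinity.

## Problem sizes used in the tests

The test suite and acceptance checks run at the study's own design
(n = 54) for estimation checks; 500 replicates for parameter recovery; 200
replicates per condition for model selection; 2000 replicates of length 200
for the AR(1) autocorrelation check; 100 replicates of length 300 for
$\hat\rho$ consistency; and 10,200 simulated months for the Poisson rate
check. These sizes give Monte-Carlo standard errors comfortably below the
tolerances asserted while keeping the whole suite around half a minute.

## Known limitations

* No higher-order ARMA errors, HAC alternatives, or seasonal ARIMA; the
  February dummy is the only seasonal term, as in the published model.
* AR(1) interval coverage at n = 54 falls short of nominal (above); a
  parametric bootstrap would close the gap but is out of scope.
* The real Korean price schedule (80%/70%/59.5%/53.55% tiers), prescriber
  behaviour and prescription-shift dynamics are not modelled; the registry
  carries one pre/post price per drug.
* Percent effects published for the real data are not reproducible from
  printed coefficients alone (they depend on the unpublished series); the
  package reports what its formulas compute and documents both readings of
  "percent effect in a year".
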