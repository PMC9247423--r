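---
title: "Adjusting dementia mortality trends for changing certification practices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting dementia mortality trends for changing certification practices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(certadjust)
```

## The model

Official cause-of-death statistics report, per death, the underlying cause
(UCOD) that ICD-10 coding rules select from everything on the death
certificate. Whether dementia is selected depends heavily on *where* the
certifier placed it (part 1, conditions directly leading to death, versus
part 2, other significant contributing conditions) and on which comorbid
conditions compete with it in part 1 — for instance, ischemic heart
disease in part 1 takes precedence over dementia, while ischemic heart
disease in part 2 does not. Secular change in these certification habits
therefore moves the dementia-UCOD series even when true dementia mortality
is flat.

The package separates the two signals with a counterfactual
standardization. Among deaths aged 50+ with dementia reported anywhere on
the certificate (the *dementia MCOD* cohort), it fits per country × sex
stratum a logistic model

$$\operatorname{logit} P(\text{dementia UCOD}) = \beta_0 +
\sum_g \beta^{(1)}_g \mathbf{1}[\text{$g$ in part 1}] +
\sum_g \beta^{(2)}_g \mathbf{1}[\text{$g$ in part 2}] +
\beta_{\text{age}(i)} + \beta_{\text{year}(i)},$$

where $g$ ranges over the non-dementia cause groups of the taxonomy, age
is banded in ten 5-year groups (reference 50–54), and calendar year enters
as a categorical block (reference: first year). Predicting each death's
probability with its year coefficient replaced by the *reference year's*
(the most recent year), then summing probabilities within year × age cells
and age-standardizing, yields the UCOD rate series that would have been
observed under reference-year certification practice. A further rescaling
by the ratio of reference-year to current-year MCOD ASDR
($\text{out}_t = \text{adj}_t / \text{mcod}_t \times \text{mcod}_{ref}$)
additionally holds the propensity to report dementia *anywhere* on the
certificate constant.

### Design choices

Several modelling choices were genuinely open; the defaults and their
rationale:

* **Year as a categorical block.** The counterfactual is defined by "the
  coefficient of the most recent year", which presupposes one coefficient
  per year rather than a linear year term.
* **No age × year interactions.** The simplest structure consistent with
  per-age-group and per-year effects. Interactions would also make young,
  sparse age × year cells prone to quasi-separation. (See "Calibration"
  below for a consequence.)
* **Dementia's own placement is not a covariate.** Under coding rules,
  dementia in part 1 nearly determines the outcome, which both answers the
  wrong question (we want the effect of *practice*, integrated over
  placement) and induces separation. `include_dementia_placement = TRUE`
  re-enables it for sensitivity analysis.
* **Strata are never pooled.** Each country × sex gets its own fit.
* **Separation handling.** The IRLS fit (convergence: max |score|
  $< 10^{-8}$ or relative deviance change $< 10^{-10}$) detects runaway
  coefficients and refits with a ridge penalty $\lambda = 10^{-6}$
  (intercept unpenalized), always reported in the fit object and
  diagnostics, never applied silently. Cause-group indicators never
  observed in a cohort are dropped as aliased and reported as `NA`
  coefficients.
* **Trend estimation.** The annual rate of change of a rate series is, by
  default, $100(e^{\hat\beta}-1)$ from an OLS fit of log rate on year —
  robust to single-year noise — with the endpoint geometric method
  (`method = "endpoint"`) as an alternative; both agree exactly on
  geometric series, and every output records which method produced it.
* **Taxonomy as data.** The default cause groups (ischemic heart disease
  I20–I25, stroke I60–I69, other CVD, cancers C00–C97, pneumonia J12–J18,
  chronic and other respiratory disease, ill-defined R00–R99, renal,
  Parkinson disease, urinary tract infection, diabetes, falls and other
  injuries) are plausible standard groupings, but they are loaded from
  data, so users can match any supplement's exact ranges. Falls (W00–W19)
  are kept disjoint from the remaining external-cause interval so that
  every code maps to at most one group. Four-character codes inherit their
  three-character root's group. A code reported in both parts is kept in
  part 1 only, treating the duplicate as transcription noise.

## Calibration at the reference year

Because the model contains an intercept and a categorical year block, the
maximum-likelihood score equations force the sum of fitted probabilities
over the records of any year to equal that year's observed dementia-UCOD
count; the same holds per age band. At the reference year the
counterfactual probability *is* the fitted probability, so the adjusted
series reproduces the observed yearly UCOD *count* there exactly (the test
suite asserts this to relative $10^{-6}$).

The corresponding *age-standardized* rates coincide only approximately.
The score equations pin year totals and age totals, not year × age cells,
and the ASDR weights cells unequally whenever the standard population is
not proportional to the current population's age structure. The residual
gap is $O(1/\sqrt{n})$ — around $10^{-3}$ relative at cohort sizes of a
few tens of thousands — and would vanish only under a saturated age × year
model (rejected above) or a standard matching the reference-year
population. We document this rather than hide it: the acceptance suite
asserts ASDR-level coincidence at $10^{-6}$ and that assertion fails by
design of the main-effects model, while the count-level calibration it
rests on passes.

## The synthetic generator

`synthetic_config()` describes a cohort with known truth; per year × age ×
stratum cell the generator draws a Poisson number of dementia-MCOD deaths
with mean population × true rate, places the dementia code in part 1 with
a (logit-linearly trending) probability, samples each comorbid group
independently into part 1 / part 2 / absent with trending probabilities,
and assigns dementia-as-UCOD by a Bernoulli draw on the true logistic
model above. Non-dementia UCODs are drawn uniformly from the record's
part-1 comorbid codes, falling back to part 2 and finally to the
ill-defined code R99 for dementia-only certificates (2–3 % of real
dementia-MCOD deaths also carry no other cause, and such records are
retained throughout). `true_expected_series()` computes the analytic
expectation of the observed and counterfactual series by exact enumeration
of all $3^G$ comorbidity placement patterns, which is what the recovery
tests compare against.

Default study conditions: ten 5-year age bands with a steeply age-rising
true MCOD rate (3 to 9,500 per 100,000), a population shape matching the
packaged synthetic standard (an Australia-2006-like 50+ age distribution,
labelled synthetic — it is not census data) with faster growth at older
ages, and an expected 5,000 dementia-MCOD deaths per stratum-year, i.e.
roughly 50,000 records per stratum over a 10-year window. The presets:

* `flat_truth` — flat true rates, constant comorbidity reporting, year
  effects rising linearly to +1.2 logits: the observed UCOD trend is
  +4–5 %/yr while the truth is flat, so a correct pipeline recovers a
  constant-MCOD-adjusted trend within ±0.3 %/yr of zero.
* `au_like` — 2006–2016, MCOD ASDR drifting +0.5 %/yr, comorbidity part-1
  and part-2 frequencies interpolating realistic Australian-style
  endpoints (pneumonia part 1 declining from 26 % to 17 %, ischemic heart
  disease part 1 from 17 % to 12 %, ill-defined part 1 rising), year
  effects sized — analytically, via `true_expected_series()` — so the
  observed UCOD trend lands near +4.2 %/yr.
* `us_like` — 2006–2017, faster MCOD growth (+1.3 %/yr), higher baseline
  dementia-UCOD share, gentler year effect; observed trend near +2.9 %/yr.

What the generator does **not** emulate: correlation between comorbid
causes (they are sampled independently given age and year; a real
certificate's causal chain induces dependence), the full ICD-10
underlying-cause selection rules (the UCOD comes from the logistic truth
directly), place-of-death effects, and cause-specific age profiles of
comorbidity. Passing recovery tests therefore demonstrate that the
pipeline inverts the certification dynamics it models, not that the model
captures every feature of real certification behaviour.

## Numerical conventions

Rates are per 100,000; percentages and published-style tables round half
away from zero to one decimal. Standard-population weights must sum to 1
within $10^{-9}$. A zero rate makes the log-linear trend undefined; the
error message points at the endpoint method. Missing age bands are an
error unless zero-imputation is requested explicitly. Leading-cause ranks
are 1-based descending with ties sharing the smaller rank. The problem
sizes used in the test suite (hundreds to a few thousand deaths per year
for unit tests, the full 5,000 deaths per stratum-year with five seeds for
the recovery suite) were chosen as the smallest cohorts at which the
Monte-Carlo error of the recovered quantities is well below the asserted
tolerances.

## Limitations

The adjustment attributes to "certification practice" everything the year
coefficients absorb, conditional on the recorded covariates; genuine
changes in the age- and comorbidity-adjusted lethality of dementia within
a year would be absorbed too. Coefficient uncertainty is not propagated
into the adjusted ASDR series (no confidence bands). The pipeline consumes
a canonical CSV dialect; parsing national fixed-width MCOD files, ICD-9 or
ICD-11 codes, and full UCOD selection logic are out of scope.
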