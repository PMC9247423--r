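# certadjust

Adjusting cause-of-death mortality trends for changing death-certification
practices, using multiple-cause-of-death (MCOD) data — with dementia as the
motivating cause.

## The problem

Official mortality statistics count, for each death, the single *underlying
cause of death* (UCOD) selected by ICD-10 coding rules from everything the
certifier wrote on the death certificate. For dementia, the UCOD series has
risen steeply in several high-income countries, while prevalence and
incidence studies suggest the disease burden is roughly stable. A plausible
explanation is a change in *certification practice*: certifiers have become
more willing to report dementia at all, and to place it in part 1 of the
certificate (conditions directly leading to death) rather than part 2
(other significant contributing conditions) — and part-1 placement is what
makes a cause eligible to be selected as the UCOD.

`certadjust` implements, as a tested and reusable pipeline, the
MCOD-based adjustment of such trends:

1. **Classification and filtering.** Deaths aged 50+ with a dementia code
   (ICD-10 F00, F01, F03, G30, G31) anywhere on the certificate form the
   *dementia MCOD* cohort; comorbid causes are grouped by a configurable
   ICD-10 interval taxonomy.
2. **Rates.** Age-specific rates per 100,000 and directly age-standardized
   death rates (ASDR), `ASDR = Σ_a w_a r_a`, with the standard weights
   `w_a` over ten 5-year bands (50–54 … 95+); percent-of-MCOD tabulations;
   log-linear and endpoint annual rates of change.
3. **Certification model.** Per country × sex stratum, a logistic
   regression (own IRLS implementation) of the outcome *dementia is the
   UCOD* among dementia-MCOD deaths, on indicators for each comorbid cause
   group in part 1 and in part 2, age band, and calendar year:
   `logit P(dementia UCOD) = β0 + Σ_g β1g·part1_g + Σ_g β2g·part2_g + β_age + β_year`.
4. **Counterfactual adjustment.** Each death's probability of dementia-UCOD
   is re-predicted with the year effect fixed at the reference (most
   recent) year; summing these probabilities by year × age and
   standardizing gives the *adjusted* UCOD ASDR — the series that would
   have been observed under reference-year certification practice.
5. **Constant-MCOD adjustment.** A further rescaling
   `out_t = adjusted_t / mcod_t × mcod_ref` emulates a stable rate of
   reporting dementia anywhere on the certificate.
6. **Synthetic generator.** Individual-level MCOD cohorts with known ground
   truth (true rates, reporting trends, certification coefficients) so
   every stage is testable without any confidential national data file.

## Worked example

```r
library(certadjust)

# a cohort where the true dementia mortality is flat and only the
# certification year effect rises
cfg <- preset("flat_truth", seed = 7, deaths_per_year = 1500)
sim <- generate_cohort(cfg)
res <- run_adjustment(sim$cohort, sim$population, sim$standard)
make_table2(res)
```

```
#> # A tibble: 3 x 3
#>   type                   SYN.male SYN.female
#>   <chr>                     <dbl>      <dbl>
#> 1 observed                    4.3        4.1
#> 2 adjusted_to_reference      -0.2       -0.2
#> 3 adjusted_constant_mcod      0          -0.1
```

The observed dementia-UCOD ASDR rises by ~4%/year, but the whole rise is an
artefact of certification: adjusted to reference-year practice the trend is
≈ 0%/year, matching the generator's flat truth. On the `au_like` preset
(realistic comorbidity trends and rising certification propensity) the same
pipeline reproduces the qualitative pattern reported for real national
data: observed trend > adjusted trend > constant-MCOD trend, with negative
part-1 cardiovascular coefficients and positive part-1 pneumonia and
ill-defined coefficients.

File-based use (canonical CSV dialect documented in `?load_records`):

```sh
exec/certadjust simulate --preset au_like --seed 42 --out sim/
exec/certadjust run --records sim/records.csv --population sim/population.csv \
    --standard sim/standard.csv --out results/
```

## Scope

The package consumes a canonical CSV dialect, not the proprietary
fixed-width national source files, and the synthetic generator assigns the
UCOD from its logistic truth rather than implementing the full ICD-10
underlying-cause selection logic. See the methods vignette
(`vignettes/certification-adjustment.Rmd`) for the model, its assumptions,
and known limitations.
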