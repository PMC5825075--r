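---
title: "Costing excess length of stay: model, coding rules and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing excess length of stay: model, coding rules and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excesscost)
```

## The problem and the estimand

Hospital episodes that run longer than the average stay for their casemix
class tie up the most modifiable component of inpatient expenditure: the
per-day ("variable") costs of ward nursing, pharmacy, hotel services and
the like, as opposed to one-off ("fixed") costs such as theatre time or
prostheses that are incurred regardless of how long the patient stays.
`excesscost` estimates how much of that excess cost is attributable to
different kinds of patient complexity — dementia, hospital-acquired
complications, comorbidity burden, admission severity, surgery, age and
sex — in an older (50+) overnight hospital population.

For an episode in DRG $g$ with integer length of stay $L$ and DRG average
overnight stay $\bar L_g$ (day-stays removed, generally fractional), the
excess cost is

$$C = \max(0,\; L - \bar L_g)\cdot \frac{V_g}{\bar L_g},$$

where $V_g$ is the DRG's variable-cost total. Only episodes *strictly*
longer than their average ($L > \bar L_g$) enter the analysis; an episode
exactly at the average has no excess. Extra days are kept as a real number
— the average is fractional and rounding it would break the
`extra_cost = extra_days × daily_variable_cost` identity that the tests
enforce on every row.

On the above-average subset, the model is ordinary least squares on the
natural log of excess cost, entered in two fixed blocks:

$$\ln C = \beta_0 + \underbrace{\beta_1\,\mathrm{age} + \beta_2\,\mathrm{male}}_{\text{step 1}}
 + \underbrace{\beta_3\,\mathrm{surgical} + \beta_4\,\mathrm{dementia}
 + \beta_5\,\mathrm{cw} + \beta_6\,\mathrm{charlson} + \beta_7\,k}_{\text{step 2}} + \varepsilon,$$

with $\mathrm{cw}$ the DRG cost weight (admission-severity proxy) and $k$
the number of complications (0–4). "Hierarchical" here means fixed-order
block entry: both blocks are pre-specified and no data-driven selection is
performed, so the reported full model is exactly the specified one and
$R^2_{\text{step2}} \ge R^2_{\text{step1}}$ holds by construction.

The log transform addresses the strong right skew of cost data, at the
price that standard errors do not back-transform exactly. The package
therefore reports, per predictor: the log-scale coefficient $b$; the
standardised beta $b\,\mathrm{sd}(x)/\mathrm{sd}(\ln C)$ for relative
importance; a dollar effect; and the dollar effect as a percentage of the
mean excess cost, rounded half-away-from-zero.

### Back-transformation choices

"The dollar effect of one unit of $x$" is not uniquely defined after a log
transform, so the method is an explicit configuration
(`back_transform_method`):

- `mean_multiplicative` (default): $(e^{b}-1)\cdot\overline{C}$ — the
  multiplicative effect evaluated at the sample mean excess cost. With
  this default the percentage column is exactly
  $100\,(e^b-1)$ rounded, so dollars, mean and percentages stay mutually
  consistent.
- `median_multiplicative`: the same at the sample median, less sensitive
  to the long right tail.
- `exp_at_means`: evaluated at the geometric-mean-style baseline
  $\exp(\overline{\widehat{\ln C}})$.

The percentage column always divides by the sample mean, whatever baseline
priced the dollars.

## Coding rules and their assumptions

**Dementia** is a person-level attribute: any qualifying code (F00–F02,
G30, G31) as principal *or* additional diagnosis on any episode of the
person admitted within a two-year lookback window flags every episode of
that person. The window is anchored at the end of the study window
(`window_end − lookback_years`); linkage across episodes is what
distinguishes this from single-stay coding and is why the generator must
produce multi-field person histories.

**Complications** (urinary tract infection, pressure injury, pneumonia,
delirium) are flagged only from *additional* diagnoses — a principal
diagnosis is what the patient was admitted with, hence never
hospital-acquired — and are vetoed by aetiology exclusions: a
urinary-tract principal diagnosis blocks the UTI flag
(`exclusion_scope = "principal_only"`), paralysis anywhere on the record
blocks pressure injury (`"principal_or_additional"`). The packaged
pneumonia exclusions (immunodeficiency, cystic fibrosis, pneumonia in
diseases classified elsewhere) and delirium exclusions
(psychoactive-substance disorders) follow the same conservative spirit but
are packaged assumptions, not a published vocabulary: the rule table in
`inst/extdata/complication_rules.csv` is deliberately editable, because
the engine — prefix matching on normalised codes, inclusion among
additional diagnoses, scoped exclusion veto — is the tested artifact, not
the specific code lists. Code matching is prefix-based on normalised codes
(dots stripped, uppercase), standard practice for administrative extracts
with heterogeneous subcode depth.

**Charlson index**: the original 1/2/3/6 weights restricted to the
conditions used as the comorbidity summary (diabetes,
hemiplegia/paraplegia, any cancer, HIV/AIDS, and major cardiovascular,
renal, rheumatic, peptic-ulcer and liver diseases). Each condition counts
once regardless of code multiplicity, so the score is idempotent and
order-invariant. Dementia is *always* excluded from the index — it is a
standalone predictor, and double-counting it would split its coefficient —
and the packaged map keeps a dementia row precisely so this exclusion is
exercised rather than implicit.

**Cohort filters**: age ≥ 50 (inclusive), overnight stays only
(LOS ≥ 1), and LOS ≤ 90 days, the usual trim for complication analyses of
discharge data. Each excluded episode is counted once under the first
failing rule (day-stay, under-age, over-trim), so the run log's waterfall
sums exactly to the input count.

## The synthetic generator

No public dataset carries this structure (state administrative data are
restricted), so the generator *is* the study-condition definition, chosen
once:

- **Prevalences** (defaults): dementia 11.9% of persons, UTI 8.2%,
  pressure injury 2.6%, pneumonia 3.7%, delirium 1.9% per episode,
  surgery 23.7%, male 47%. Complications are assigned independently per
  episode; at these rates multiple complications are appropriately rare
  (~0.9% with two or more) without explicit dependence modelling.
- **Ages** uniform on 50–107 (the observed range of the target
  population); one episode per person by default, more via a Poisson
  excess when person linkage should be stressed.
- **True effects** (log scale): dementia 0.14, 0.13 per complication,
  0.05 per cost-weight unit, 0.04 per Charlson point, 0.003 per year of
  age, 0.015 male, 0.008 surgical, intercept 7.87, residual SD 0.9. The
  intercept puts the mean excess cost of the above-average subset near
  $5,900 at the default covariate mix. Note these effect sizes imply
  $R^2 \approx 0.01$–$0.02$ for the full model: individually meaningful
  dollar effects against a noisy outcome, which is exactly the regime the
  estimator must handle.
- **Above-average membership** is an independent Bernoulli draw
  (p = 0.369): roughly as in the population this emulates, about 37% of
  overnight episodes exceed their DRG average. Because membership is
  independent of the covariates, subsetting cannot bias the recovered
  effects.
- **DRG costing structure**: average overnight LOS lognormal around
  4.2 days; cost weight lognormal (clamped to 0.1–46); daily variable
  cost lognormal around 600/day with only 15% spread, with severity
  loading on the fixed components (1,600 per cost-weight unit). Keeping
  the *daily* rate roughly constant across DRGs is a deliberate numerical
  choice: excess stays then fall in the ~2–40 day range, where the
  integer-day LOS grid is harmless. If instead the daily rate scaled with
  severity, high-cost-weight episodes would have sub-day excess stays and
  day rounding would systematically distort their log cost — a
  generator-induced bias, not an estimator defect.
- **LOS back-derivation**: the generator draws
  $\ln C = \eta + \varepsilon$, converts to exact extra days through the
  cost model's own daily-variable-cost arithmetic, and sets
  $L = \max(1, \mathrm{round}(\bar L_g + \text{extra}))$ with half-up
  rounding. The rounding error is centred (±0.5 day), so re-running the
  costing stage reproduces the intended excess cost up to day rounding
  without attenuating slopes. A handful of episodes (~0.3%) round to at
  or below the average or beyond the 90-day trim and drop out, mirroring
  the small exclusion tails such analyses report.
- **Recoverability by construction**: dementia persons carry a qualifying
  code on an episode inside the final two years of the window;
  complication episodes carry an inclusion code and never a matching
  exclusion code (in particular hemiplegia/paraplegia is never
  co-assigned with a generated pressure injury); principal diagnoses come
  from a neutral pool that triggers no rule. The ground-truth sidecar is
  written only for tests — the coding, costing and regression stages
  never read it.

### What the generator does not emulate

Real discharge data have correlated complications (frail patients acquire
several), dementia-complication interactions, hospital-level cost
variation, heteroscedastic and non-Gaussian log-cost residuals, seasonal
admission patterns, and far deeper ICD-10 coding. Passing parameter
recovery here shows the pipeline is a calibrated estimator *under its own
assumptions*; it does not validate the coding vocabularies clinically, nor
license causal readings of the coefficients on real data.

## Numerical and degenerate-input behaviour

- Strictly positive `extra_cost` is required before the log; the fit
  refuses anything else rather than silently dropping rows.
- Missing model fields: listwise deletion, with the dropped count kept in
  `n_dropped` and reconciled in the run log.
- Perfect collinearity is detected by QR rank and reported with the
  offending column names; zero-variance predictors likewise.
- Standard errors are plain OLS by default, matching the reporting
  convention this analysis style uses; `robust = TRUE` switches to HC0
  sandwich errors as a sensitivity option.
- Retransformation bias in `predict(type = "cost")` is handled with
  Duan's smearing estimator.
- Percentages round half-away-from-zero (so 14.5% → 15%), independent of
  R's banker's rounding.
- Currency is unit-agnostic: rescaling all subcategory amounts by $k$
  rescales every dollar quantity by $k$ and leaves standardised betas and
  the percentage column unchanged (tested as a property).

## Problem sizes in the test suite

The calibration property — every true effect covered by its nominal 95%
CI in at least 90 of 100 replicates, and step-2 R² never below step-1 —
is run at 20,000 episodes per replicate across 100 seeds, which keeps the
full suite under a couple of minutes while leaving each replicate's
standard errors small enough (≈0.03 on the dementia log effect) for the
coverage check to be meaningful. Unit tests use hand-enumerable fixtures
of 10–200 rows with independent brute-force oracles: naive per-code rule
matching for flags and Charlson, normal-equations OLS for the regression.

## Known limitations

- The complication and Charlson ICD-10 lists are illustrative; swap in a
  validated vocabulary via the rule-table and map CSVs before any real
  use.
- The two-year dementia lookback is anchored to the study window's end;
  staggered per-episode lookbacks are not implemented.
- Multiple episodes within one hospital stay are treated as independent
  episodes.
- Purchasing-power conversion of outputs is out of scope; results carry
  whatever currency unit the DRG reference uses.
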