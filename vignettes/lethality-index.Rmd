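---
title: "Seizure-based lethality indices for overdose mortality surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure-based lethality indices for overdose mortality surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Official overdose-mortality statistics lag events by months to years, while
law-enforcement drug-seizure data are typically reported monthly. Each
street-level seizure analysed by a crime lab is a sample of the local
illicit drug market, so the frequency and composition of seizures carry
information about both the availability and the lethality of the drugs in
circulation. `sdli` implements a surveillance methodology that converts
case-level seizure and death records into a supply-side index that tracks
— and can therefore anticipate — annual unintentional overdose mortality.

```{r, eval = FALSE}
library(sdli)
```

## The index

All quantities are computed per *drug category* (six analytic categories:
fentanyl, cocaine, prescription opioids, heroin, amphetamines,
benzodiazepines; anything else is carried as an `other:` category). Raw
substance names from lab results and toxicology reports are first mapped to
categories with a user-editable dictionary (`substance_mapping()`), and a
record's substance set is deduplicated at the category level, so a
toxicology listing two distinct prescription opioids is a *single-drug*
record.

For a chosen **reference year** (default 2017, a peak-mortality year that
maximizes the events informing the ratios):

1. **Single-drug deaths** $D_d$: unintentional overdose deaths (ICD-10
   underlying cause X40–X44, matched case-insensitively on the first three
   characters) whose toxicology lists exactly the one category $d$.
2. **Single-drug seizures** $S_d$: seizure events in which lab analysis
   identified exactly category $d$.
3. **Lethality ratio** $LR_d = D_d / S_d$, deaths per seizure. Mixed
   records are excluded from both counts so the ratio isolates the
   lethality of each drug on its own.
4. **Street-Drug Lethality Index**, per drug and year:
   $SDLI_{d,y} = LR_d \times A_{d,y}$, where $A_{d,y}$ is the *total*
   number of seizures involving $d$ in year $y$ (single plus mixed; a
   mixed seizure counts once toward each drug present).
5. **Summed Annual Lethality Index**: $SALI_y = \sum_d SDLI_{d,y}$.

Deaths enter the index only through the reference-year ratios: the
year-to-year variation in $SALI$ reflects the seizure record alone, which
is what makes it usable as a low-lag predictor.

A simple linear regression then links the index to mortality on the
square-root scale,

$$\sqrt{\text{deaths}_y} = a + b\,SALI_y + \varepsilon_y,$$

fitted by ordinary least squares (`fit_sali_regression()`), with two-sided
$t$ inference on $b$ at $n-2$ degrees of freedom and the Durbin–Watson
statistic on year-ordered residuals to check their independence. Predicted
deaths are the squared linear predictor, clamped at zero
(`predict_deaths()`); no retransformation bias correction is applied, so
predictions correspond directly to the fitted line (a
smearing-type correction would change predictions by a factor that is
negligible at the $r^2$ this model is useful at, and would complicate the
spreadsheet-reproducible character of the method).

## Tunable parameters

* `reference_year` (default 2017): the year the ratios are computed on.
  Any year can be used; the SALI for the reference year itself is computed
  like any other year.
* `ci_level` (default 0.95): the slope interval's two-sided confidence
  level. The published-style reports use 95%, the field standard.
* `unmapped_policy` (default `"keep_as_other"`): unmapped substance names
  become `other:<name>` categories. `other` substances *do* count against
  single-drug status by default — a fentanyl + alcohol death is not a pure
  fentanyl death. Because registries differ in how exhaustively they list
  non-abuse substances, `ignore_other_substances = TRUE` restores
  single-drug status judged on analytic categories only.
* `deaths_scope` (default `"all_unintentional"`): the regression's
  dependent variable counts all X40–X44 deaths;
  `"indexed_drugs_only"` restricts it to deaths involving an indexed
  category.

Numerical conventions: ratios are kept at full floating precision
throughout the pipeline and rounded only in reports, to 3 decimals, half
away from zero (`format_lethality_table()`), matching how such tables are
conventionally printed (254/5781 = 0.0439… prints as 0.044). A drug with
zero single-drug seizures in the reference year is *excluded* from the
table with a warning, not assigned a ratio of 0 or infinity — no lethality
can be estimated for it. Degrees of freedom are always computed from the
data actually fitted. Duplicate seizure rows sharing an id are merged
(union of substances) with a warning; years are calendar years of the
seizure date / date of death.

## The synthetic market generator

The administrative registries this methodology was developed on are
restricted, so the package ships a generator (`market_params()`,
`generate_market()`) that emulates their structure with known ground
truth, making every pipeline stage testable:

* Seizure counts per drug and year are Poisson at a specified intensity —
  seizure frequency as a proxy for availability, with no within-year
  seasonality.
* A seizure is mixed with probability `p_mixed`; partner drugs are drawn
  with probability proportional to a co-occurrence weight times the
  partner's same-year intensity, so co-occurrence tracks availability
  (fentanyl rarely appears as an adulterant in years when it is rare). A
  mixed seizure gains a third drug with probability `p_third = 0.15`, a
  plausible polydrug rate.
* Single-drug deaths per drug-year are Binomial(single seizures,
  $\theta_d$), where $\theta_d$ is the true per-drug lethality the
  pipeline's $LR$ should recover.
* Under the `linear_sqrt` death model, additional polydrug death records
  (always ≥ 2 toxicology substances, so they can never contaminate the
  single-drug counts) are appended until each year's total equals
  $\mathrm{round}\big((a + b\,SALI^{true}_y + \varepsilon_y)^2\big)$.
  If a year's mechanistic single-drug deaths already exceed that total the
  parameters are rejected as infeasible.
* One RNG stream per run, seeded from the parameters; identical seeds give
  byte-identical output files, and the caller's RNG state is preserved.

The `ohio2017_like()` preset scales 2017 intensities and $\theta$ to the
magnitudes of the published reference-year table (≈3,800 expected pure
fentanyl seizures at $\theta = 0.393$, etc.) with plausible 2009–2018
availability trends. Its death model uses $b = 0.0095$, `noise_sd = 0.3`
and $a = 20$: the intercept is set high enough that the early, low-index
years remain feasible — with the reference-year lethality values, an
intercept near 12 would demand fewer total deaths in 2009 than the
single-drug deaths the mechanistic layer itself produces.

What the generator does **not** emulate: county-level structure,
seasonality, purity/weight of seizures, polydrug interaction effects on
death risk, reporting noise in toxicology, and secular changes in
lethality within a drug category. Passing recovery tests on this generator
therefore shows the pipeline computes its estimands correctly and that the
statistical machinery is calibrated under the stated model — not that the
index will predict mortality in any particular jurisdiction.

## Validation design and problem sizes

The test suite validates each stage against independent oracles:
exhaustive per-record scans for all counting operations, the generator's
own event log for IO, direct-formula evaluation (and the `lmtest`
implementation) for Durbin–Watson, an independent third-moment
implementation for skewness, and spreadsheet-style recomputation for SALI.
Statistical calibration uses: lethality recovery at ~10,000 single
seizures per drug (within 3 binomial standard errors); slope CI coverage
over 200 replicates of a 12-year market (a deliberately small three-drug
market, ~100–170 expected seizures per drug-year, where the
reference-year lethality ratios are estimated precisely enough that
sampling error in the index does not distort nominal coverage); and 500
regression-level replicates at Gaussian noise 0.5 on the square-root
scale. The full-scale preset (~300,000 seizure records) is run once
end-to-end. These sizes were chosen to make sampling error quantifiable
while keeping the whole suite comfortably reproducible on a laptop.

## Known limitations

* The lethality ratio is a ratio of counts from two different reporting
  systems; it is a *relative* lethality score, not a per-use death risk.
* Ratios from a single reference year freeze each drug's lethality over
  the study period; a potency shift within a category (e.g. fentanyl
  analogues) appears only through seizure counts.
* With ~10 annual observations, the regression supports interpolation and
  short-range surveillance, not structural inference; no
  autocorrelation-robust or time-series machinery is applied beyond the
  Durbin–Watson check.
* Whether seizure frequency tracks availability or enforcement effort is
  not identifiable from these data alone.
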