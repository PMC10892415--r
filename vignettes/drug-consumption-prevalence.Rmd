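---
title: "Estimating treated and overall T2DM prevalence from drug consumption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating treated and overall T2DM prevalence from drug consumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmprev)
library(dplyr)
```

## The estimation problem

Direct prevalence surveys for chronic disease are costly and infrequent.
For a condition that is (i) almost always treated pharmacologically,
(ii) treated with drugs specific to it, and (iii) treated year-round without
seasonality, aggregate drug-dispensing data are an indirect prevalence
instrument: the amount of drug sold constrains the number of people taking
it. Type 2 Diabetes mellitus (T2DM) satisfies these conditions — its drugs
occupy a dedicated ATC branch (`A10`, split into insulins `A10A` and
non-insulin antidiabetics, NADs, `A10B`) — and is the disease this package
is calibrated for, although the machinery is generic to any drug-specific
chronic condition.

The catch is that consumption maps to patient counts only through a chain of
behavioural and clinical quantities: how much of the prescribed dose patients
actually collect (adherence), how many drug classes a patient combines
(concomitance), which insulin users have T2DM at all, and how many true cases
are undiagnosed. The model makes each link an explicit, replaceable
parameter.

## Consumption accounting

Dispensing records are aggregated sale lines: an ATC level-5 code, a number
of dose units, the strength per unit, a region and a year. The package
normalizes them with the standard drug-utilization units:

* **DDD** (Defined Daily Dose): the assumed average adult maintenance dose
  per day for the drug's main indication. `record_total_ddd()` computes
  `units × strength / DDD`; for fixed-dose combinations (`A10BD`), whose DDD
  is expressed in unit doses (UD), it is `units / DDD` — one dose unit is one
  count, strength has no meaning there.
* **DID**: DDD per 1000 inhabitants per day, `did() = total DDD × 1000 /
  (N × 365)`. A DID of `x` says that roughly `x` per 1000 inhabitants
  receive a standard daily dose each day. The year is fixed at 365 days by
  convention, also in leap years, so that DIDs are comparable across years.

`aggregate_consumption()` produces the region × year × ATC-class table and a
`TOTAL` row per year whose DID uses the *summed* population — the national
DID is a population-weighted aggregate, never the mean of regional DIDs.
DIDs are kept at full precision internally; rounding (half up, one decimal)
happens only in `render_reports()` and the `*_report` columns.

A single multiplicative `coverage_factor` (default 1) is exposed for
databases that cover only part of the market; no coverage scaling is applied
by default because the correct factor depends on whether the source already
reflects full-market sales.

## The six-step model

With insulin DID $c_I$, NAD DID $c_N$ and population $N$ for a scope-year,
`run_model()` chains:

1. $P_N = c_N N / 1000$ and $P_I = c_I N / 1000$ — patient-equivalents at
   exactly one DDD/day per class.
2. $P_N / a_N$ and $P_I / a_I$ — adherence correction. Partial adherence
   ($a<1$) means observed consumption under-counts patients, so the count is
   divided. Base case: $a_N = 0.60$ (European chronic-disease adherence),
   $a_I = 1.00$ (insulin adherence treated as complete; the parameter is
   exposed anyway).
3. $P_N^{adj} = w \cdot P_N / a_N$ with the concomitance weight
   $w = 1/(1 + \pi_2 + 2\pi_3 + 3\pi_4)$, where $\pi_k$ is the probability
   that a treated patient combines $k$ NAD classes. A patient on $k$ classes
   is counted $k$ times by consumption, and $1/w$ is exactly the expected
   class count per patient; `weight_factor()` computes $w$ from the
   $\pi$'s, or $w$ can be given directly (base 0.608 from a Portuguese
   survey; 0.596 from a multi-country prescription-pattern study is wired
   into the sensitivity defaults). Steps 2 and 3 commute.
4. $T = P_N^{adj} + f \cdot P_I/a_I$. Insulin consumption also reflects
   Type 1 diabetes and insulin-only users, who must not enter a T2DM count;
   the rule removes all insulin-derived patients and re-admits the fraction
   $f$ (base 0.075) as T2DM insulin users. Note the rule is strictly
   increasing in $f$: assuming more T2DM insulin users can only raise the
   estimate. The companion count `patients_dm` keeps the full
   $P_N^{adj} + P_I/a_I$.
5. Treated prevalence $\hat p = 100\,T/N$ (percent).
6. Overall prevalence $\hat p / (1-u)$, where $u$ is the undiagnosed
   fraction (base 0.44 for 2018 and 0.357 for 2021, supplied per year).

Patient counts stay real-valued through the whole chain; nothing is rounded
to whole persons. The model consumes the level-3 insulin/NAD split; the
level-4 chemical-subgroup table is the reporting layout, and the two are
consistent because DID is additive within a population.

## Sensitivity analysis

`run_scenarios()` is strictly one-at-a-time: each `scenario()` re-runs the
model with only its overrides, everything else at base. The base block is
always the first rows and is bitwise identical to a direct `run_model()`
call. For scenarios that vary only $u$, the treated columns repeat the base
values — $u$ acts after step 5 by construction.

`tornado_ranges()` summarises, per varied parameter, the outcome range
across its scenarios *together with the base case* (so a single scenario
differing from base has nonzero spread), using the treated column for
parameters acting before step 6 and the overall column for $u$; ties in the
spread ordering break alphabetically. On the default scenario set the
adherence and undiagnosed-fraction parameters dominate the spread, ahead of
$w$ and $f$.

## The synthetic cohort and what a green test establishes

`generate_cohort()` builds a person-level world with known truth:

* a fraction `true_prevalence` of `n_pop` has T2DM (default 0.139, the 2018
  national estimate);
* of those, `1 − undiagnosed_fraction` are diagnosed and NAD-treated
  (default u = 0.44); insulin-treated T2DM users are added as
  `insulin_t2dm_fraction` of that NAD-treated block (default 0.075); the
  rest of the T2DM block is undiagnosed. The realized undiagnosed share is
  therefore `1 − (1−u)(1+f)`, slightly below `u` — the generator keeps the
  T2DM total exact and takes the insulin top-up out of the undiagnosed
  remainder;
* Type 1 diabetes (default prevalence 0.5%) contributes insulin-only
  persons, so the step-4 exclusion is exercised non-trivially;
* NAD regimen sizes follow `regimen_probs` (default
  `c(0.46, 0.28, 0.19, 0.07)`, treatment-line shares observed in a
  multi-country European prescription study); a regimen never holds two
  drugs of the same level-4 class; insulin statuses carry exactly one
  insulin code and never a NAD, mirroring the additive step-4 rule's
  no-double-counting assumption.

In **deterministic mode** every count is a largest-remainder apportionment of
its expectation and every treated person contributes exactly
`adherence × 365` DDDs per drug; in **stochastic mode** statuses are
multinomial, regimens sampled, and DDD-days binomially thinned with the
adherence probability (no overdispersion — the model's accounting is
mean-based, and matching its assumption is the point). An optional
`pack_size` rounds dispensed units up to whole packs for probing
quantization bias; it is off by default because the model has no
quantization correction.

**Exactness needs matched parameters.** The model is exact on a cohort only
when its parameters equal the cohort's *realized* quantities:
`effective_params()` computes them from `true_summary()` — the realized
inverse mean regimen size for $w$, the realized T2DM share among *all*
insulin users for $f$ (the model sees only insulin consumption and cannot
tell Type 1 from Type 2), and the realized undiagnosed share for $u$. The
recovery tests calibrate the Type 1 prevalence so that the T2DM share of
insulin users equals the nominal $f$, making the generating configuration
and the effective parameters coincide. A green recovery test therefore
establishes that the pipeline inverts its own generative assumptions — it
says nothing about how well those assumptions describe any real population,
where adherence is heterogeneous, insulin+NAD combination users exist (they
break the additive step-4 rule and are deliberately not generated), and
off-label use inflates consumption.

## Numerical conventions and edge cases

* Reported percentages are rounded half away from zero (`round_half_up()`),
  one decimal by default; base R's half-to-even rounding would disagree on
  exact .x5 boundaries.
* Zero consumption is legal everywhere and yields zero estimates; zero or
  negative populations, adherences, or weights outside $(0,1]$ are errors,
  as is $u \ge 1$.
* Missing DDD registry entries are a hard error by default;
  `permissive = TRUE` downgrades to a warning, skips the records and reports
  the skipped totals (attribute `"skipped"`).
* Region labels match exactly after whitespace trimming; no fuzzy matching.
* All tables are UTF-8, comma-delimited, dot-decimal, header mandatory;
  reports are byte-identical across runs on identical inputs.

## Known limitations

DID cannot be stratified by sex or age, so neither can the estimates. The
insulin side of the model is crude: a single fraction $f$ stands in for the
whole Type 1 / insulin-only / combination-therapy structure. Adherence is a
single scalar per drug class group. The concomitance weight is a survey
constant, not estimated from the data at hand. The packaged DDD registry
fixture is synthetic scaffolding for tests — real analyses must supply a
registry from the current ATC/DDD index.
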