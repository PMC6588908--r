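---
title: "plymod: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plymod: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`plymod` is a static microsimulation pipeline that values the lost
productive life years (PLYs) of older workers (45–64) whose main
chronic condition in the ischemic heart disease (IHD) group has pushed
them out of the labour force. This vignette is the package's own
account of the model: what each stage assumes, which parameters matter,
what the synthetic data do and do not emulate, and where the design was
genuinely open.

## The pipeline

A *static* microsimulation never simulates individual life events. It
takes a weighted cross-sectional base file, reweights it so the
weighted margins match a projection year's benchmarks, rescales dollar
amounts for real growth, and then runs its analyses on the aged file.
`plymod` composes, in order:

1. disease-trend adjustment of weights (`apply_disease_trend()`),
2. calibration to population and employment benchmarks
   (`gregwt_calibrate()`),
3. real-terms uprating of weekly amounts (`uprate_economics()`),

wrapped by `project_to_year()`, followed by group classification,
counterfactual Monte Carlo and national cost aggregation. The order
matters only up to the third stage, and only for interpretability:
calibration operates on weights and uprating on dollars, so those two
commute (a property the test suite asserts); trend adjustment must
precede calibration so that the benchmarks, not the trends, have the
last word on totals.

## Lost PLYs and the analysis groups

A record contributes a lost PLY due to IHD in a year exactly when it is
(a) not in the labour force, (b) for the reason "own ill-health or
disability", and (c) carries heart disease, angina or myocardial
infarction as its main chronic condition. Only the main condition is
consulted — comorbidity is out of scope, mirroring how the underlying
survey instrument attributes early retirement to a single condition.
Every record falls in exactly one of six groups: full-time/part-time
employment split by IHD status, the lost-PLY group, and a residual
("other") that absorbs the unemployed, those out of the labour force
for other reasons, and ill-health exits with a non-IHD main condition.

## Synthetic data: what it emulates, and what it does not

The real base file and donor pool are restricted microdata, so the
package ships a generator (`population_config()`,
`generate_base_population()`, `generate_donor_pool()`) whose defaults
*are* the study conditions:

* **group shares** (base year): 53.08 % employed full-time without
  IHD, 1.06 % full-time with IHD, 20.09 % part-time without IHD,
  0.40 % part-time with IHD, 0.11 % out of the labour force due to
  IHD, 25.26 % residual;
* **income law**: log-normal per group, anchored so the group *median*
  equals its target (AU$/week, 2013 dollars: 1305.46, 1186.08, 600.78,
  567.83, 415.83, and 430 for the residual group). The median is the
  anchoring statistic because it is the robust location summary for
  right-skewed income microdata; the per-group `sdlog` defaults were
  set from the reported mean/median ratios where available
  (e.g. `sdlog = 0.615` full-time) and to moderate values elsewhere;
* **welfare**: the lost-PLY group receives a Disability Support
  Pension-like amount — 77.4 % of income with 5 % multiplicative noise,
  capped at income — so welfare forms roughly three quarters of that
  group's income; other groups receive welfare with a per-group
  probability and a log-normal amount;
* **tax**: `rate × max(0, income − threshold)` per group, with the
  threshold placed so the group's median tax hits its target; people
  out of the labour force pay zero tax at the median;
* **weights**: uniform on (0.5, 1.5) × `target_population/n`, a
  moderate-variance positive law whose total approximates the 5.945
  million 45–64-year-olds the base year represents. Weights vary so
  weighted statistics are genuinely exercised;
* **matching variables**: drawn from one joint categorical law shared
  by base and donor generation, so donor cells cover base cells with
  probability approaching one as the pool grows.

The generator emulates the *statistical structure the analysis
consumes*: group shares, medians, weight dispersion, matching-cell
coverage, and the condition codelist. It does **not** emulate household
structure beyond income-unit type, multi-condition morbidity,
geographic or occupational detail, item non-response, or the complex
survey design (stratification, clustering) of the real collections.
Passing tests therefore demonstrate that the pipeline's machinery is
correct under known conditions — not that real-world levels would be
reproduced, which requires the restricted microdata.

The base file is produced as a single pooled file; the pooling weights
of the two underlying survey years are not separately modelled, since
nothing downstream distinguishes them.

## Synthetic matching (hot-deck imputation)

Weekly income, welfare and tax are donated from the donor pool by
exact-key matching on ten variables in a fixed priority order — sex,
age group, labour force status, DSP receipt, age-pension receipt,
education, income quintile, hours band, income unit type, home
ownership. When a cell is empty, variables are dropped from the *end*
of that order (home ownership first), preserving the variables most
predictive of income; a record with no donor even at `(sex, age_group)`
is excluded and counted. Within a cell the donor is chosen uniformly at
random, with replacement across base records — the simplest
exchangeable rule, since nothing identifies a better one. Hours are
matched as bands (0, 1–34, 35+): exact-hours cells would be empty at
realistic pool sizes. Distance-based and propensity-score matching are
deliberate non-goals; wealth is not imputed because no downstream
result consumes it.

## Calibration

The calibration step is a GREGWT-family algorithm written for this
package: minimise the chi-square distance
\(\sum_i (w_i - d_i)^2 / d_i\) from the design weights subject to the
benchmark equations \(X^\top w = T\). The unconstrained minimiser is
linear, \(w_i = d_i(1 + x_i^\top\lambda)\) with
\((X^\top D X)\,\lambda = T - X^\top d\); multipliers are truncated to
bounds (default 0.1–10) and the system re-solved over the unrestricted
units until every cell total is within tolerance (default relative
1e-6, iteration cap 50). On a feasible problem with no bound hits this
converges in a single step and equals the closed-form linear
calibration, which the tests assert to 1e-8. Rank-deficient systems
fall back to a pseudoinverse solve. Infeasible margins (a positive
target with no contributing records) raise an error naming the cell;
non-convergence returns diagnostics rather than silently truncated
weights.

Margins calibrated by default: population totals by age band × sex,
plus full-time and part-time counts in the same cells (24 cells) — the
two benchmark families the projection uses. The default benchmark
tables place the four projection-year population totals (5,945,000 to
7,130,200) over cells with a mild ageing gradient and rescale fixed
age/sex employment-rate profiles so the weighted overall full-time and
part-time shares drift upward across years, as mature-age employment is
projected to do. Education margins are not calibrated: their benchmark
form in the source projections is unclear, and the employment and
population margins are the ones that drive every downstream number
here.

## Disease trends

Trended conditions are stroke, cancer, IHD, type 2 diabetes and COPD.
Within each sex × age-band stratum the weighted prevalence of disease
*d* is moved to `base prevalence × m_d^(min(year, 2023) − 2009)` and
untrended records are rescaled so the stratum's total weight is exactly
conserved (asserted to 1e-9 relative). After 2023 prevalence is held
constant. The default annual multipliers are direction-consistent
choices (IHD 0.990 and stroke 0.995 both sexes, cancer 1.000, type 2
diabetes 1.015, COPD 1.000 men / 1.010 women), constant across age
bands — the trend source reports directions by sex, not printed
age-specific rates, so a single per-sex multiplier in log scale is the
least-structured choice consistent with it.

## Counterfactual Monte Carlo

Each lost-PLY case is matched to a counterfactual drawn with
replacement from a pool sharing sex, age band and education. Three
pools are supported: full-time without IHD, part-time without IHD, and
the whole labour force without IHD (including the unemployed), the last
being the one national costs use. Two genuinely open choices were
resolved as follows:

* *Sampling law within a cell*: the source describes only "at random
  with replacement". Default is probability proportional to the
  donor's survey weight, which makes the counterfactual represent the
  weighted pool rather than the sample; a uniform switch
  (`weight_proportional = FALSE`) is provided.
* *Empty cells*: education is dropped first (same drop-from-the-end
  rule as imputation); an empty `(sex, age_group)` cell is an error
  listing the cells, since silently matching across sex or age would
  change the estimand.

Each replicate records the case-weighted mean difference
\(\sum w_i (x_i^{case} - x_i^{cf}) / \sum w_i\) per outcome; the
convention is that negative values mean cases receive less. With 1000
replicates the percentile interval takes order statistics 25 and 975
(nearest-rank rule `floor(n·α/2)` / `ceiling(n·(1−α/2))`). Replicate
`k` is seeded by a fixed hash of `(master_seed, k)`, so runs are
reproducible and replicate order is irrelevant. Survey replicate
weights and BCa intervals are out of scope.

## Costs

National annual costs scale the labour-force-wide weekly difference:
`|Δ| × n_lost_PLY × weeks_per_year / 1e6` AU$ millions, CI endpoints
transformed by the same monotone map. The annualisation factor defaults
to 52 weeks/year — the simplest convention consistent with back-solving
the published annual totals from their weekly inputs — and is
config-overridable. Lost GDP uses the proportional-labour decomposition
`GDP × n_lost_PLY / workforce`. The reference workforce is an explicit
input: the packaged `gdp_inputs_synthetic.csv` carries the published
GDP projections and a workforce column *back-derived* from the
published GDP, lost-GDP and headcount figures (~12.7M in 2015, growing
to ~15.5M), a synthetic stand-in for the non-public workforce
projections that reproduces the published GDP-loss mechanics.
Currency conversion, discounting and the friction-cost method are
non-goals; the valuation is a human-capital approach.

## Published derived statistics

`published_values()` is a read-only fixture of headline figures that
can be recomputed from *other printed figures* (growth rates, shares,
GDP gains); `reproduce_derived_statistics()` recomputes each through
the cost-aggregation operations and compares after half-up rounding to
two decimals — rounding is applied only at comparison time, never
inside computation. Four published figures are carried with role
`display_only` because their own printed inputs do not reproduce them
at two decimals (they recompute to 19.94 vs 19.95, 58.11 vs 58.12,
34.91 vs 43.91 and 33.62 vs 63.94); they are retained for completeness
and deliberately never asserted.

## Numerical choices and degenerate inputs

* Weighted median: lower-median convention (smallest value whose
  cumulative weight reaches half the total) — deterministic and
  order-independent where interpolation rules are not.
* Weighted SD: population form (same weights as the mean), so a
  single record has SD 0.
* Money is generated to the cent and weights to 1e-4, making CSV
  round-trips exact.
* Empty groups summarise to count 0 with `NA` moments; an empty base
  file, donor pool or case set is an error, not a silent zero.
* All randomness flows through explicit seeds (`withr::with_seed`), so
  identical `(config, seed)` pairs give byte-identical output files.

## Problem sizes

The test suite validates distributional targets on one 100,000-record
generation; calibration properties on a perturbed 1,000-record file
with 16 benchmark cells; imputation against a brute-force
admissible-set oracle over 500 seeds on a 20-record fixture; parameter
recovery of a designed AU$950/week income gap on a 10,000-record
full-chain run with 1000 replicates (the recovery design places the
full-time log-normal so the mean gap is exactly 950 with equal absolute
income dispersion on both sides, which also makes the percentile
interval's nominal 95 % coverage hold); and interval coverage over 200
repeated syntheses of 500 cases against 9,000 donors. The acceptance
script runs the full pipeline at 20,000 base records and 30,000 donors
with 1000 replicates per comparison. These sizes were chosen so each
property is tested at meaningful precision while the whole suite stays
fast enough to run routinely.

## Limitations

* Mortality, migration and dynamic ageing are not modelled; the lost
  PLY metric is prevalence-based (cross-sectional), not a panel
  life-course quantity.
* Results at synthetic defaults inherit small-sample noise in the rare
  lost-PLY group (a 0.11 % state yields ~22 records per 20,000).
* The residual group's economic profile is a modelling choice
  (log-normal, median AU$430/week) that influences imputed NILF
  incomes through shared matching cells.
* Real-data levels (e.g. the published AU$273M lost income in 2015)
  are not reproducible without the restricted microdata; the package's
  claims are the mechanics, the derived published ratios, and
  parameter recovery under known synthetic truth.
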