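---
title: "Methods: costing assistive technologies for ageing in place"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: costing assistive technologies for ageing in place}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageplacecost)
```

This vignette is the package's own account of the model: what each stage
assumes, where the design was genuinely open and which choice we made, and
what the tests do and do not demonstrate.

## The problem

A growing share of older people live with several chronic diseases at
once, and multimorbidity is the main driver of moves from home into
residential care. Digital assistive technologies — fall detectors, ECG and
blood-pressure self-monitors, glucose meters, cognition aids — can delay
that move, but a regional program would have to equip a whole population,
not a trial cohort. The package estimates that population-wide annual cost
for a regional case study (Fitzroy and Central West, Queensland) by
chaining five stages: demographic forecast, assistance-need estimation,
comorbidity categorisation, combinatorial allocation, and life-cycle
costing.

## Stage 1: progressive forecasting

`forecast_population()` advances 5-year age cohorts through 5-year steps.
One annual step of a cohort is survival then migration,
`N ← N(1 − m/1000) + g`, compounded five times per band transition
(`advance_cohort()`). Assumptions and choices:

- **Death-rate units.** Published schedules for these ages run from ~4 to
  ~190 per 1,000 per year; the rates are therefore interpreted as
  per-1,000 annual rates and compounded annually within a step.
- **Which band's rate governs a transition.** A cohort moving from 65–69
  into 70–74 spends the step partly in each band; the schedule never says
  which rate applies. The default uses the *destination* band's rate at
  the destination year; `rate_convention = "origin"` and `"mean"` are
  provided. This choice is one reason the model's 2026 endpoint (46,694)
  sits ~7% above the published projection (43,824): published per-band
  forecasts are not recoverable from the printed inputs under any of the
  three conventions, so exact per-band agreement is explicitly out of
  scope and the tests check direction and order of magnitude only.
- **Death-rate projection.** With only three census observations per band,
  anything richer than a straight line is unidentifiable; missing forecast
  years are filled by per-band OLS trends (`fit_linear_trend()`), clamped
  at zero. A fully projected schedule can also be supplied directly, so
  published forecast rates can be injected as-is.
- **Migration.** Net overseas (−0.006%/yr) and interstate (+0.058%/yr)
  migration rates are applied to the whole regional population of the
  destination year — this reproduces the published regional counts (−14
  and +137 persons in 2021) — and the resulting persons are apportioned to
  the 65+ bands in proportion to their feeder cohorts. Whether the
  original analysis applied the rates to the region or to the 65+
  subpopulation is not stated; the regional convention is the one that
  matches the printed counts.
- **Top band.** The mortality schedule splits 85–89 and 90–94 while the
  population table ends at 85+. `collapse_top_band()` uses the 85–89 rate
  for the open band by default (most of an 85+ cohort is 85–89; the
  alternative `"mean"` overstates mortality by weighting 90–94 equally).
- **No births**, because entrants to the 65+ bands over a 10-year horizon
  were all 55+ at base. Under zero mortality and migration the forecast
  conserves the total exactly — a property the tests assert.

## Stage 2: assistance need

The cost denominator is the population both living in households and
needing help with at least one daily activity. Per band this is the
product of the two survey marginals (`household_assist_rate()`); the
overall 36.61% is kept as a scalar input rather than recomputed, because
the product of the *rounded* printed marginals (38.6% × 94.8% = 36.59%)
differs by a rounding artifact, and downstream tables require 36.61%
exactly. Recomputing the per-band combined cells from printed marginals
deviates by up to ~0.06 percentage points (the survey's own unrounded
sources are not published); the tests document this tolerance.

## Stages 3–4: comorbidity categorisation and allocation

`categorize()` splits the assisted population by the national
disease-count shares. The source table is internally inconsistent by 0.9
thousand (its four pools sum to 3,286.5 against a printed total of
3,285.6), which forces a modelling decision:

- **published mode** (default) divides by the printed total, reproducing the
  published tables cell-for-cell at the cost of categories summing
  slightly above the input (~3 persons in 11,098);
- **strict mode** normalises by the pool sum and conserves exactly.

The same switch governs `breakdown_single()`: published mode rounds each
disease's share to 0.1% before multiplying and applies it to the rounded
pool, reproducing all eight published cells (including their documented
overshoot: cells sum to 2,961 against a pool of 2,947, because the
single-disease column itself sums to 876.0, not 872.6); strict mode
renormalises unrounded shares.

The two-disease pool is spread over all 28 pairs by normalised ratios of
the pairwise comorbidity matrix (`pair_shares()`). The matrix
double-counts people with three or more diseases (a pair cell counts
everyone with both diseases), so applying its normalised ratios to the
exactly-two pool is an approximation, retained deliberately because it is
the prescribed method.

For the 219 subsets of three or more diseases (`multi_shares()`), the
method is stated only loosely ("combinatorial methods" for the common
combinations, "weighted average" for the rest), so the implementation had
to pin it down:

- each triple is scored by the **sum** of its three pairwise counts
  (alternatives `min` and `prod` are provided; under sum-scoring the top
  triples are arthritis+back+CVD, arthritis+CVD+mental,
  arthritis+CVD+diabetes, matching the three the source lists first —
  its fourth listed triple ranks fifth under all three scores, so no test
  hard-codes it);
- the `top_k = 4` best triples take mass proportional to their scores
  relative to all triples;
- the remaining mass goes to every other size-≥3 subset in proportion to
  the mean marginal prevalence of its member diseases — the most natural
  reading of "weighted average", and the fraction of mass given to the
  top triples is configurable because the original split is never stated.

Shares sum to one by construction (asserted to 1e−9), allocation is
equivariant under relabelling the diseases, and strict mode conserves the
assisted population to ±1 person.

## Stage 5: life-cycle costing

`annual_item_cost()` amortizes purchase plus one-off installation (5% of
price) uniformly over the device lifespan (5 years) and adds annual
maintenance (15% of price): a 1,000 AUD device costs 360 AUD/yr. The
amortized presentation matches smooth published annual figures; a
cash-flow mode that books purchases in replacement years is provided for
budget planning, and over one full lifespan the two modes spend the same
money. No discounting is applied — all figures are constant base-year
(2016) dollars; prices observed later are deflated by compound inflation
(`deflate_price()`), with the rate a config value (0.019/yr in the shipped
config, a typical Australian CPI figure for 2016–18, since the source
cites but never prints its rate).

Per-person cost sums the device bundle — basic bundle ∪ per-disease
bundles, duplicates removed, so cost is monotone under disease-set
inclusion. Per-capita figures divide by *unrounded* populations: AUD 2,289
for the no-chronic-disease group is 3,458,063 / 1,510.53 and is missed by
the displayed 1,511.

## Synthetic data

The real device price list is not available in a redistributable form, so
`synth_catalog()` generates a schema-compatible catalog (prices uniform
within per-category ranges, average price a 1.2–3× multiple of low) and
bundle map (2–6 monitoring-type devices per disease; basic bundle from
safety/mobility/fitness). All cost totals computed on it are
order-of-magnitude illustrations, not estimates; every published-table
quantity in the tests and acceptance script is independent of it.

`synth_individuals()` draws disease sets from a log-linear pairwise model:
independent prevalences tilted by pairwise odds multipliers, normalised
over the 2⁸ = 256 outcomes. This family was chosen because its exact
distribution is enumerable (`disease_set_distribution()`,
`exact_pair_probs()`), giving closed-form oracles for the samplers, and
because it can match both a disease-count distribution and a pairwise
matrix — the two aggregate structures the pipeline consumes. Sampling
tests use n = 100,000 draws (a 256-cell multinomial, fractions of a
second) and check empirical pair frequencies within 3 standard errors and
2% absolute. What the synthetic model does *not* emulate: age-dependent
prevalence, higher-than-pairwise interactions, and any correlation between
disease burden and residence or assistance need — so passing tests show
the pipeline's arithmetic is right, not that the survey tables themselves
generalise.

## Numerical conventions

- Full precision everywhere internally; `round_half_up()` (half away from
  zero, the convention of published demographic tables — base R rounds
  half to even) only at display.
- Degenerate inputs fail loudly: fewer than two distinct years for a
  trend, an all-zero comorbidity matrix, a zero population divisor, a gap
  in the age-band ladder (the error names the bands).
- Heavy out-migration clamps cohorts at zero rather than going negative.
- Deterministic tie-break (score, then name) when selecting top triples;
  all randomness flows from a single integer seed and seeded generators
  restore the caller's RNG state.

## Known limitations

- Absolute cost totals depend on the synthetic catalog; only per-capita
  ratios of published aggregates are reproduced.
- The published per-band population forecast cannot be matched exactly
  from printed inputs; the forecast is validated directionally.
- Pair-share allocation inherits the comorbidity matrix's double-counting.
- The multivariate death-rate regression described for the original
  analysis is under-determined with three census observations; this
  package fits year-only trends and accepts externally projected
  schedules instead.
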