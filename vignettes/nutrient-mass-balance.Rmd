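---
title: "Methods: mass-balance modelling of global nutrient availability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-balance modelling of global nutrient availability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutribalance)
```

## The model and its assumptions

`nutribalance` implements food-balance-sheet (FBS) accounting at global
scale.  The model is deterministic: given the input tables there is no
estimation step, only a chain of accounting identities.  Its assumptions
are those of the FBS tradition:

* **The world is one region.**  Production and use are netted globally,
  so imports and exports must cancel per commodity (the `strict_zero`
  trade mode enforces `|imports − exports| ≤ 10⁻⁶ × production`, a
  float-safe tolerance for "equal").  Distributional inequality between
  regions is deliberately out of scope; the only regional structure
  retained is in-home waste, which is observed per region and collapsed
  to a global fraction.
* **Availability, not intake.**  The model measures what the food
  system delivers for human consumption after non-food uses, losses,
  inedible portions and in-home waste — not what people actually eat.
* **One reference year.**  Balances may contain several years; the
  pipeline selects one (by default the latest).  No trend estimation or
  smoothing across years is attempted: the estimator such a step would
  need is not part of this model, and the reference-year ledger is used
  directly.
* **Commodity resolution.**  Foods are modelled at producing-commodity
  resolution (e.g. "pig meat"), not as consumed dishes.  Processing is a
  commodity tree: a parent's recorded `processing_input` mass is
  distributed to children by extraction rates, the residual leaving the
  food system.  `processing_input` is ledger data, not a derived
  fraction; a two-level chain (animal → carcass → cuts) composes as the
  product of rates when the intermediate's `processing_input` records
  the mass it receives, which is how FBS commodity trees are published.
* **Bioavailability is nutrient-selective.**  Only protein and the seven
  indispensable amino acids (cystine, histidine, leucine, lysine,
  methionine, threonine, tryptophan) are scaled by coefficients in
  (0, 1]; for every other nutrient the composition data are used
  unadjusted, because coefficient data across foods are too sparse.
  Diet-level interactions (e.g. phytate inhibition of mineral
  absorption) are outside the model.

## Parameters that matter

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| masses | tonnes/year | — | FBS convention |
| composition | per 100 g edible portion | — | food-composition-table convention; one conversion constant, 1 t = 10⁴ × 100 g |
| inedible portion | fraction of food mass | 0.08–0.43 for meats | bone/skin share by meat type (poultry highest) |
| in-home waste | fraction of edible mass | 0.02–0.11 for meats | regional estimates, population-weighted to global |
| bioavailability | fraction | 0.68–1 | published digestibility ranges; offal lower than muscle meat |
| days per year | d | 365 | per-capita conversion |
| requirement table | per person per day | `default_requirements()` | adult reference values in registry units |

The 29-nutrient unit registry (`nutrient_registry()`) fixes kcal for
energy, grams for macronutrients and amino acids, mg or µg for
micronutrients.  Published sources do not pin the unit of every
micronutrient, so the registry is shipped as a documented default and
travels with the bundle (`units.csv`); validation rejects composition
rows whose `unit` disagrees with it.  Vitamin A is one aggregated
quantity; retinol and pro-vitamin A are not separated.

## Design choices where the design was open

* **Order of adjustments.**  Inedible portion is removed first, then
  waste is taken from the *edible* mass.  The two orders differ
  numerically; this order matches how waste fractions are defined
  (shares of food, not of carcass) and is fixed and documented.
* **Global waste from regional data.**  Regional waste fractions are
  averaged with regional population headcounts as weights.  The intent
  is a food-mass-weighted mean; regional food masses are not part of the
  schema, and under the model's global-uniformity assumption population
  shares are the same weights.
* **Contribution basis.**  The decomposition uses bioavailable
  quantities for protein and the amino acids and gross quantities for
  all other nutrients (`basis = "mixed"`), matching how such tables are
  published; `"gross"` and `"bioavailable"` are available for
  sensitivity checks.
* **Denominator.**  Contribution percentages divide by availability
  from *all* foods in the bundle, never just the focus groups.
* **Scenario scaling.**  A group multiplier scales every supply-side
  field of its commodities uniformly, preserving each ledger's food
  fraction; this makes availability exactly linear in the multiplier,
  which the closed-form replacement solver relies on:
  `m = (R·P·365 − A_other) / A_donor`, clamped at 1, `Inf` when the
  donor supplies none of the nutrient.
* **Missing data.**  An absent composition cell is an error in strict
  mode; a recorded `NA` marker (or, in lenient reading, an absent cell
  converted to one) contributes zero with a single summary warning —
  sparse tables are normal at FBS scale, but silent zeros must stay
  visible.  Commodities without a bioavailability record default to a
  coefficient of 1, again with a warning.

## Numerical choices

* **Conservation identity.**  `consumed_mass()` reports components by
  subtraction (`inedible = available − edible`, `wasted = edible −
  consumed`), so `(consumed + wasted) + inedible` reproduces the input
  bit-for-bit whenever both fractions are below one half (Sterbenz
  subtractions; all realistic food fractions qualify).  For
  adversarial fractions above 0.5 the identity holds to ~2 × 10⁻¹⁶
  relative error, which the property tests assert.
* **Negative net supply** (possible in real data through stock
  variation, which the model omits) is clamped to zero with a warning.
* **Degenerate totals.**  A nutrient with zero global availability
  yields undefined (`NA`) contribution cells, rendered `"n/a"` — never
  silently 0.
* **Display rounding** is round-half-up to integer percent (`20.5 →
  "21"`); values in (0, 0.5) render `"<0.5"`, exact zero renders
  `"No contribution"`.  Whether published tables rounded ties up or to
  even is unknowable, so the convention is fixed here and all invariant
  checks run on raw values.
* **CSV dialect** is fixed (comma, UTF-8, header, `.` decimal) and
  numerics are written with 17 significant digits, so
  `read(write(x)) == x` exactly.

## What the synthetic generator emulates — and what it does not

`generate_world()` draws miniature worlds with the structure of the real
inputs: the five meat groups plus at least two non-meat groups,
log-uniform production and composition magnitudes per nutrient class
(so contribution shares are non-degenerate), globally netting trade, one
carcass→offal processing chain, meat waste/inedible/bioavailability
drawn inside the observed ranges, regionally split populations, and a
configurable share of missing composition cells.  Meat-like commodities
carry no fiber or carbohydrate and plant commodities no vitamin B12,
reproducing the characteristic zero-contribution rows.  Defaults: 20
commodities, 8 groups, 5% composition sparsity, 7.53 × 10⁹ people.

Generated worlds are *not* statistically realistic FBS time series: no
country resolution, no stock variation, no correlated composition
profiles, no multi-year dynamics.  A passing oracle-equivalence suite
therefore certifies the accounting — that the vectorized pipeline
computes exactly the quantities the per-record definitions state — not
that any particular real-world number is right, which depends entirely
on the input tables supplied.

Two fixed fixtures complement the random worlds.
`make_paperlike_world()` hard-codes (rather than samples) the published
2018 meat structure — 333 Mt farm gate, 316 Mt available as food, meat
shares 23/34/32/2/9%, ~7% of global food mass, ~115 g/person/day — as a
regression surface.  `make_replacement_world()` inverts the replacement
closed form so that removing meat leaves a vitamin B12 gap that exactly
a tripling of dairy closes; the round trip through `apply_scenario()`
must drive the gap to ≤ 10⁻⁹.

## Problem sizes and verification

The test suite cross-checks the pipeline against an independent
brute-force oracle (`oracle_outputs()`, explicit per-record loops) on
20 seeded worlds of 10–17 commodities, demanding exact raw-value
equality; invariants (column sums of 100, bioavailable ≤ gross, scale
invariance, monotonicity under removal, identity-scenario no-op) run on
additional seeds.  These sizes keep each suite run comfortably in the
seconds-to-a-minute range while exercising every code path; the model
itself is linear in commodities × nutrients and handles far larger
bundles.

## Known limitations

Global-only resolution; availability ≠ intake; single reference year;
bioavailability only for protein and amino acids; aggregated nutrient
groups (vitamin A); no stock variation, bilateral trade, price or
land-use response; requirements are single global per-capita values
without demographic stratification; supplements are excluded.  Scenario
results are structural statements about the accounting, not forecasts.
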