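# nutribalance

A global food-system mass-balance model for quantifying what individual
food groups contribute to the world's supply of nutrients.

Public debate about foods — meat especially — usually argues from health
or environmental evidence, while a more basic question often goes
unanswered: how much of the global availability of each essential
nutrient does a food group currently deliver?  `nutribalance` answers
that question with food-balance-sheet (FBS) accounting.  It is written
for nutrition and food-systems researchers who want a transparent,
fully testable implementation of the approach: commodity supply ledgers
in, per-nutrient contribution percentages, per-capita availabilities and
counterfactual scenarios out.

## The model

For each commodity *c* the supply-side ledger resolves into the mass
available as food (tonnes/year):

```
food_c = production_c + imports_c − exports_c − feed_c − seed_c
         − other_uses_c − losses_c − processing_c
```

Commodity trees distribute processed mass to child commodities (e.g.
carcass → meat cuts + separated offal and fats) with extraction rates
`production_child += r × processing_parent`.  Subtracting the inedible
portion `i_c` (bone, skin; 8–43% for meats depending on type) and then
the in-home waste share `w_c` (2–11% for meat depending on region,
population-weighted to a global figure) approximates the mass consumed:

```
consumed_c = food_c × (1 − i_c) × (1 − w_c)
```

Consumed mass converts to 29 nutrients through per-100 g composition
tables, `gross_cn = consumed_c × 10⁴ × amount_cn`, and protein and seven
indispensable amino acids are additionally scaled by bioavailability
coefficients β ∈ (0, 1] reflecting their digestibility:
`bioavailable_cn = β_cn × gross_cn`.  A food group's contribution to a
nutrient is its share of the global total,

```
contribution_gn = 100 × Σ_{c∈g} avail_cn / Σ_c avail_cn   (%)
```

using bioavailable quantities for protein/amino acids and gross
quantities otherwise.  Scenario analysis perturbs the ledgers (remove
groups, scale production, change population) and reports per-nutrient
gaps against reference intakes, `gap_n = max(0, 100 × (1 −
available_n / requirement_n))`, plus the smallest donor-group scaling
that closes a gap, solved in closed form.

## Worked example

The package ships a fixed fixture world shaped like the published 2018
global meat situation: 333 Mt of meat commodities at the farm gate, 316
Mt available as food, a 7.53 billion population.

```r
library(nutribalance)
fit <- nb_model(make_paperlike_world())
summary(fit)
```

```
<nb_model>
  year 2018, 12 commodities, 11 groups, basis 'mixed'
  global food mass: 4514.3 Mt available, 3660.6 Mt consumed
  focus groups (ruminant_meat, poultry_meat, pig_meat, other_meat, offal_and_fats): 316.0 Mt, 7.0% of food mass
  focus per-capita availability: 115.0 g/person/day
  subgroup shares of focus food mass (%):
    ruminant_meat        23.0
    poultry_meat         34.0
    pig_meat             32.0
    other_meat            2.0
    offal_and_fats        9.0
  focus share of energy 6.8%, fat 31.4%, protein 22.6%
  largest focus-group nutrient contributions (% of global):
    vitamin_b12      64.4
    vitamin_a        54.9
    lysine           37.3
    fat              31.4
    methionine       28.4
    histidine        27.8
    threonine        26.6
    copper           24.9
```

Reading: meat makes up 316 Mt — 7% of global food mass, about 115
g/person/day — split 23/34/32/2/9% between ruminant, poultry, pig,
other meat and separated offal and fats; on this synthetic composition
its share of nutrient availability is far larger than its mass share
for vitamin B12, vitamin A, the amino acids and fat.  `cmd_run()`
writes the full tables (`contributions.csv` with raw percentages and the
`"<0.5"`/`"No contribution"` display convention, `availability.csv`,
`per_capita.csv`, `food_mass.csv`, `summary.csv`).

Scenarios:

```r
rw <- make_replacement_world()
replacement_multiplier(rw, "dairy", "ruminant_meat", "vitamin_b12")
#> [1] 3
```

In that tuned world, removing meat leaves a vitamin B12 shortfall that
closes only when dairy production triples.

A command-line wrapper with `generate`, `validate`, `run` and
`scenario` subcommands is installed at
`system.file("cli", "nutribalance.R", package = "nutribalance")`.

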