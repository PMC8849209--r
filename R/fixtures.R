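# Fixed synthetic fixtures.
#
# make_paperlike_world() reproduces the published 2018 headline structure
# for meat: 333 Mt of meat commodities at the farm gate, 316 Mt available
# as food, split 23/34/32/2/9 between ruminant meat, poultry meat, pig
# meat, other meat and separated offal and fats, against a plant-
# dominated global food supply (~7% of food mass is meat) and a 7.53e9
# population.  make_replacement_world() is tuned so that, with meat
# removed, tripling dairy production exactly closes the vitamin B12 gap.

# full 29-nutrient composition grid; unspecified cells are zero
full_composition <- function(spec, units = nutrient_registry()) {
  rows <- lapply(names(spec), function(cid) {
    amount <- rep(0, nrow(units))
    names(amount) <- units$nutrient_id
    given <- spec[[cid]]
    if (length(given)) {
      stopifnot(all(names(given) %in% units$nutrient_id))
      amount[names(given)] <- given
    }
    data.frame(commodity_id = cid, nutrient_id = units$nutrient_id,
               amount = unname(amount), unit = units$unit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

iaa_only <- function(protein, cys, his, leu, lys, met, thr, trp) {
  c(cystine = cys, histidine = his, leucine = leu, lysine = lys,
    methionine = met, threonine = thr, tryptophan = trp, protein = protein)
}

#' Fixture world shaped like the published 2018 meat results
#'
#' A fixed, hand-specified world in which 333 Mt of meat commodities
#' leave the farm gate, 316 Mt are available as food, and the meat food
#' mass splits 23/34/32/2/9 (%) between ruminant meat, poultry meat, pig
#' meat, other meat and separated offal and fats (offal arises through a
#' carcass-processing chain).  Six non-meat groups supply the rest of the
#' global food mass so that meat is ~7% of the total; the population is
#' 7.53e9, making meat availability roughly 115 g/person/day.
#' Composition and bioavailability values are realistic food-composition
#' magnitudes (meat coefficients are midpoints of the published 0.83-1
#' meat ranges; offal uses the published offal coefficients).
#'
#' @return A validated `nb_bundle`.
#' @export
make_paperlike_world <- function() {
  Mt <- 1e6  # tonnes per megatonne
  units <- nutrient_registry()
  meat_target <- c(ruminant_meat = 0.23, poultry_meat = 0.34,
                   pig_meat = 0.32, other_meat = 0.02) * 316 * Mt
  carcass_prod <- 31.6 * Mt            # processed; 0.9 becomes offal
  direct_prod_total <- 333 * Mt - carcass_prod
  s <- direct_prod_total / sum(meat_target)
  prod <- meat_target * s
  slack <- prod - meat_target          # lost to feed + supply-chain losses

  meat_ids <- c("bovine_meat", "poultry_meat_fresh", "pig_meat_fresh",
                "game_meat")
  bal_meat <- data.frame(
    commodity_id = meat_ids,
    group_id = names(meat_target),
    year = 2018,
    production = unname(prod), imports = 0, exports = 0,
    feed = unname(0.4 * slack), seed = 0, processing_input = 0,
    other_uses = 0, losses = unname(0.6 * slack),
    stringsAsFactors = FALSE
  )
  bal_chain <- data.frame(
    commodity_id = c("carcass_byproducts", "offal_and_fats_sep"),
    group_id = c("offal_and_fats", "offal_and_fats"),
    year = 2018,
    production = c(carcass_prod, 0), imports = 0, exports = 0,
    feed = 0, seed = 0, processing_input = c(carcass_prod, 0),
    other_uses = 0, losses = 0, stringsAsFactors = FALSE
  )
  other <- data.frame(
    commodity_id = c("cereal_grains", "vegetables_fresh", "fruits_fresh",
                     "milk_dairy", "fish_seafood", "eggs_shell"),
    group_id = c("cereals", "vegetables", "fruits", "dairy",
                 "fish_and_seafood", "eggs"),
    year = 2018,
    production = c(2400, 1300, 650, 400, 180, 73.3) * Mt,
    imports = 0, exports = 0,
    feed = c(300, 0, 0, 0, 20, 0) * Mt, seed = 0, processing_input = 0,
    other_uses = 0,
    losses = c(200, 200, 50, 20, 10, 5) * Mt,
    stringsAsFactors = FALSE
  )
  balances <- rbind(bal_meat, bal_chain, other)

  processing <- data.frame(parent_id = "carcass_byproducts",
                           child_id = "offal_and_fats_sep",
                           extraction_rate = 0.9, stringsAsFactors = FALSE)

  composition <- full_composition(list(
    bovine_meat = c(energy = 217, protein = 26.1, fat = 11.8,
      calcium = 12, copper = 0.08, iron = 2.7, magnesium = 21,
      phosphorus = 198, potassium = 318, selenium = 26, zinc = 6.3,
      vitamin_a = 2, vitamin_b1 = 0.07, vitamin_b2 = 0.18,
      vitamin_b5 = 0.65, vitamin_b6 = 0.38, vitamin_b9 = 9,
      vitamin_b12 = 2.6, vitamin_e = 0.2,
      cystine = 0.33, histidine = 0.83, leucine = 2.07, lysine = 2.2,
      methionine = 0.68, threonine = 1.04, tryptophan = 0.17),
    poultry_meat_fresh = c(energy = 165, protein = 31, fat = 3.6,
      calcium = 15, copper = 0.05, iron = 1, magnesium = 29,
      phosphorus = 228, potassium = 256, selenium = 27, zinc = 1,
      vitamin_a = 9, vitamin_b1 = 0.07, vitamin_b2 = 0.12,
      vitamin_b5 = 0.98, vitamin_b6 = 0.6, vitamin_b9 = 4,
      vitamin_b12 = 0.34, vitamin_e = 0.27,
      cystine = 0.4, histidine = 0.96, leucine = 2.33, lysine = 2.63,
      methionine = 0.86, threonine = 1.31, tryptophan = 0.36),
    pig_meat_fresh = c(energy = 291, protein = 25, fat = 21,
      calcium = 19, copper = 0.07, iron = 0.9, magnesium = 22,
      phosphorus = 213, potassium = 362, selenium = 38, zinc = 2.4,
      vitamin_a = 2, vitamin_b1 = 0.87, vitamin_b2 = 0.3,
      vitamin_b5 = 0.7, vitamin_b6 = 0.46, vitamin_b9 = 5,
      vitamin_b12 = 0.7, vitamin_e = 0.29,
      cystine = 0.32, histidine = 1, leucine = 2, lysine = 2.25,
      methionine = 0.66, threonine = 1.14, tryptophan = 0.32),
    game_meat = c(energy = 150, protein = 30, fat = 3,
      calcium = 5, copper = 0.25, iron = 4.5, magnesium = 24,
      phosphorus = 226, potassium = 343, selenium = 11, zinc = 4.4,
      vitamin_b1 = 0.2, vitamin_b2 = 0.5, vitamin_b5 = 0.8,
      vitamin_b6 = 0.7, vitamin_b9 = 8, vitamin_b12 = 3.2,
      vitamin_e = 0.4,
      cystine = 0.35, histidine = 0.9, leucine = 2.3, lysine = 2.5,
      methionine = 0.75, threonine = 1.2, tryptophan = 0.3),
    carcass_byproducts = c(),
    offal_and_fats_sep = c(energy = 135, protein = 20, fat = 5,
      calcium = 5, copper = 9.8, iron = 6.5, magnesium = 18,
      phosphorus = 387, potassium = 313, selenium = 40, zinc = 4,
      vitamin_a = 9440, vitamin_b1 = 0.2, vitamin_b2 = 2.8,
      vitamin_b5 = 6, vitamin_b6 = 1, vitamin_b9 = 290,
      vitamin_b12 = 26, vitamin_c = 1.3, vitamin_e = 0.4,
      cystine = 0.3, histidine = 0.53, leucine = 1.8, lysine = 1.4,
      methionine = 0.5, threonine = 0.9, tryptophan = 0.24),
    cereal_grains = c(energy = 350, carbohydrates = 72, protein = 11,
      fat = 2, fiber = 11, calcium = 30, copper = 0.4, iron = 3.5,
      magnesium = 120, phosphorus = 290, potassium = 360, selenium = 15,
      zinc = 2.5, vitamin_b1 = 0.4, vitamin_b2 = 0.15, vitamin_b5 = 0.9,
      vitamin_b6 = 0.3, vitamin_b9 = 40, vitamin_e = 1,
      cystine = 0.25, histidine = 0.27, leucine = 0.8, lysine = 0.35,
      methionine = 0.2, threonine = 0.35, tryptophan = 0.14),
    vegetables_fresh = c(energy = 35, carbohydrates = 6.5, protein = 1.8,
      fat = 0.3, fiber = 2.5, calcium = 40, copper = 0.07, iron = 0.9,
      magnesium = 18, phosphorus = 45, potassium = 280, selenium = 0.5,
      zinc = 0.4, vitamin_a = 180, vitamin_b1 = 0.06, vitamin_b2 = 0.07,
      vitamin_b5 = 0.3, vitamin_b6 = 0.15, vitamin_b9 = 60,
      vitamin_c = 30, vitamin_e = 0.6,
      cystine = 0.02, histidine = 0.04, leucine = 0.08, lysine = 0.08,
      methionine = 0.02, threonine = 0.06, tryptophan = 0.02),
    fruits_fresh = c(energy = 60, carbohydrates = 14.5, protein = 0.8,
      fat = 0.3, fiber = 2.2, calcium = 15, copper = 0.08, iron = 0.3,
      magnesium = 12, phosphorus = 18, potassium = 200, selenium = 0.1,
      zinc = 0.1, vitamin_a = 30, vitamin_b1 = 0.04, vitamin_b2 = 0.04,
      vitamin_b5 = 0.25, vitamin_b6 = 0.09, vitamin_b9 = 20,
      vitamin_c = 40, vitamin_e = 0.4,
      cystine = 0.01, histidine = 0.01, leucine = 0.03, lysine = 0.03,
      methionine = 0.01, threonine = 0.02, tryptophan = 0.01),
    milk_dairy = c(energy = 64, carbohydrates = 4.8, protein = 3.3,
      fat = 3.7, calcium = 119, copper = 0.01, iron = 0.05,
      magnesium = 13, phosphorus = 93, potassium = 151, selenium = 3.7,
      zinc = 0.4, vitamin_a = 46, vitamin_b1 = 0.05, vitamin_b2 = 0.18,
      vitamin_b5 = 0.37, vitamin_b6 = 0.04, vitamin_b9 = 5,
      vitamin_b12 = 0.45, vitamin_e = 0.07,
      cystine = 0.03, histidine = 0.09, leucine = 0.32, lysine = 0.26,
      methionine = 0.08, threonine = 0.15, tryptophan = 0.05),
    fish_seafood = c(energy = 120, protein = 18, fat = 5, calcium = 20,
      copper = 0.05, iron = 0.6, magnesium = 30, phosphorus = 220,
      potassium = 340, selenium = 40, zinc = 0.6, vitamin_a = 20,
      vitamin_b1 = 0.07, vitamin_b2 = 0.1, vitamin_b5 = 0.8,
      vitamin_b6 = 0.4, vitamin_b9 = 10, vitamin_b12 = 3,
      vitamin_e = 0.6,
      cystine = 0.2, histidine = 0.6, leucine = 1.5, lysine = 1.7,
      methionine = 0.55, threonine = 0.82, tryptophan = 0.21),
    eggs_shell = c(energy = 143, carbohydrates = 0.7, protein = 12.6,
      fat = 9.5, calcium = 56, copper = 0.07, iron = 1.8,
      magnesium = 12, phosphorus = 198, potassium = 138, selenium = 30,
      zinc = 1.3, vitamin_a = 160, vitamin_b1 = 0.04, vitamin_b2 = 0.46,
      vitamin_b5 = 1.5, vitamin_b6 = 0.17, vitamin_b9 = 47,
      vitamin_b12 = 0.89, vitamin_e = 1,
      cystine = 0.27, histidine = 0.31, leucine = 1.09, lysine = 0.91,
      methionine = 0.38, threonine = 0.56, tryptophan = 0.17)
  ), units)

  # meat coefficients: midpoints of the published meat ranges; offal:
  # the published offal column
  meat_coef <- c(protein = 0.955, cystine = 0.92, histidine = 0.935,
                 leucine = 0.94, lysine = 0.945, methionine = 0.945,
                 threonine = 0.94, tryptophan = 0.915)
  offal_coef <- c(protein = 0.76, cystine = 0.68, histidine = 0.7,
                  leucine = 0.8, lysine = 0.77, methionine = 0.8,
                  threonine = 0.76, tryptophan = 0.69)
  flat_coef <- function(cid, coef) {
    data.frame(commodity_id = cid,
               nutrient_id = names(coef),
               coefficient = unname(coef), stringsAsFactors = FALSE)
  }
  uniform_coef <- function(cid, value) {
    flat_coef(cid, stats::setNames(rep(value, 8), bioavailable_nutrients()))
  }
  bioavailability <- rbind(
    flat_coef("bovine_meat", meat_coef),
    flat_coef("poultry_meat_fresh", meat_coef),
    flat_coef("pig_meat_fresh", meat_coef),
    flat_coef("game_meat", meat_coef),
    flat_coef("offal_and_fats_sep", offal_coef),
    uniform_coef("milk_dairy", 0.95),
    uniform_coef("fish_seafood", 0.9),
    uniform_coef("eggs_shell", 0.9),
    uniform_coef("cereal_grains", 0.8),
    uniform_coef("vegetables_fresh", 0.72),
    uniform_coef("fruits_fresh", 0.72)
  )

  inedible <- data.frame(
    kind = "inedible",
    commodity_id = balances$commodity_id,
    region_id = "GLOBAL",
    fraction = c(0.08, 0.43, 0.18, 0.25,   # meats: type-dependent
                 0, 0.08,                  # carcass (never food), offal
                 0, 0.12, 0.2, 0, 0.25, 0.12),
    stringsAsFactors = FALSE
  )
  regions <- c("region_1", "region_2", "region_3")
  waste <- expand.grid(commodity_id = balances$commodity_id,
                       region_id = regions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meatlike <- balances$group_id[match(waste$commodity_id,
                                      balances$commodity_id)] %in%
    meat_groups()
  regional_waste <- c(region_1 = 0.11, region_2 = 0.06, region_3 = 0.02)
  waste <- data.frame(
    kind = "waste", commodity_id = waste$commodity_id,
    region_id = waste$region_id,
    fraction = ifelse(meatlike, regional_waste[waste$region_id], 0.12),
    stringsAsFactors = FALSE
  )
  fractions <- rbind(inedible, waste)

  population <- data.frame(
    region_id = c("GLOBAL", regions), year = 2018,
    headcount = c(7.53e9, 1.2e9, 4.3e9, 2.03e9), stringsAsFactors = FALSE
  )

  nb_bundle(balances = balances, processing = processing,
            composition = composition, fractions = fractions,
            bioavailability = bioavailability, population = population,
            requirements = default_requirements(), units = units)
}

#' Fixture world where tripling dairy closes the vitamin B12 gap
#'
#' Tuned so that, at baseline, total vitamin B12 availability exactly
#' meets the global requirement with meat supplying 60%, dairy 30% and
#' cereals 10%.  Removing meat therefore leaves a gap that closes exactly
#' when dairy production is tripled:
#' `m = (R*P*365 - A_cereals) / A_dairy = (1 - 0.1) / 0.3 = 3`.
#'
#' @return A validated `nb_bundle` with groups `ruminant_meat`, `dairy`
#'   and `cereals`.
#' @export
make_replacement_world <- function() {
  units <- nutrient_registry()
  pop <- 1e9
  req_b12 <- 2.4                            # ug/person/day
  needed <- req_b12 * pop * 365             # ug/year
  b12_per_100g <- c(meat_c = 2, dairy_c = 0.5, cereal_c = 0.01)
  share <- c(meat_c = 0.6, dairy_c = 0.3, cereal_c = 0.1)
  production <- share * needed / (1e4 * b12_per_100g)

  balances <- data.frame(
    commodity_id = names(production),
    group_id = c("ruminant_meat", "dairy", "cereals"),
    year = 2018,
    production = unname(production), imports = 0, exports = 0, feed = 0,
    seed = 0, processing_input = 0, other_uses = 0, losses = 0,
    stringsAsFactors = FALSE
  )
  composition <- full_composition(list(
    meat_c = c(vitamin_b12 = unname(b12_per_100g["meat_c"]),
               energy = 200, protein = 25),
    dairy_c = c(vitamin_b12 = unname(b12_per_100g["dairy_c"]),
                energy = 64, protein = 3.3),
    cereal_c = c(vitamin_b12 = unname(b12_per_100g["cereal_c"]),
                 energy = 350, protein = 11)
  ), units)
  fractions <- data.frame(kind = character(), commodity_id = character(),
                          region_id = character(), fraction = numeric(),
                          stringsAsFactors = FALSE)
  bioavailability <- data.frame(
    commodity_id = names(production),
    nutrient_id = "protein",
    coefficient = c(0.95, 0.95, 0.8), stringsAsFactors = FALSE
  )
  population <- data.frame(region_id = "GLOBAL", year = 2018,
                           headcount = pop, stringsAsFactors = FALSE)
  requirements <- data.frame(nutrient_id = "vitamin_b12",
                             per_capita_daily = req_b12,
                             stringsAsFactors = FALSE)
  nb_bundle(balances = balances, composition = composition,
            fractions = fractions, bioavailability = bioavailability,
            population = population, requirements = requirements,
            units = units)
}
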