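# Nutrient registry and unit conventions.
#
# Internal mass unit is the tonne (as in FAO food balance sheets); nutrient
# composition is expressed per 100 g edible portion (food-composition-table
# convention).  One tonne = 1e4 x 100 g, so converting a consumed mass in
# tonnes into nutrient units multiplies by TONNES_TO_100G once, here and
# nowhere else.

TONNES_TO_100G <- 1e4
GRAMS_PER_TONNE <- 1e6
DAYS_PER_YEAR <- 365

#' Default nutrient unit registry
#'
#' The 29 nutrients tracked by the model, each with its reporting unit and
#' broad class.  Units follow food-composition-table practice: kcal for
#' energy, grams for macronutrients and amino acids, milligrams or
#' micrograms for micronutrients.  Vitamin A is a single aggregated
#' quantity (retinol and pro-vitamin A are not separated).
#'
#' @return A data frame with columns `nutrient_id`, `unit` and `class`
#'   (one of `"macronutrient"`, `"mineral"`, `"vitamin"`, `"amino_acid"`).
#' @export
#' @examples
#' nrow(nutrient_registry())  # 29
nutrient_registry <- function() {
  data.frame(
    nutrient_id = c(
      "carbohydrates", "energy", "fat", "fiber", "protein",
      "calcium", "copper", "iron", "magnesium", "phosphorus",
      "potassium", "selenium", "zinc",
      "vitamin_a", "vitamin_b1", "vitamin_b2", "vitamin_b5", "vitamin_b6",
      "vitamin_b9", "vitamin_b12", "vitamin_c", "vitamin_e",
      "cystine", "histidine", "leucine", "lysine", "methionine",
      "threonine", "tryptophan"
    ),
    unit = c(
      "g", "kcal", "g", "g", "g",
      "mg", "mg", "mg", "mg", "mg",
      "mg", "ug", "mg",
      "ug", "mg", "mg", "mg", "mg",
      "ug", "ug", "mg", "mg",
      rep("g", 7L)
    ),
    class = c(
      rep("macronutrient", 5L),
      rep("mineral", 8L),
      rep("vitamin", 9L),
      rep("amino_acid", 7L)
    ),
    stringsAsFactors = FALSE
  )
}

#' Nutrients subject to bioavailability adjustment
#'
#' Protein and the seven indispensable amino acids carried by the model.
#' Only these nutrients are scaled by bioavailability coefficients; all
#' other composition data are used unadjusted.
#'
#' @return Character vector of nutrient identifiers.
#' @export
bioavailable_nutrients <- function() {
  c("protein", "cystine", "histidine", "leucine", "lysine",
    "methionine", "threonine", "tryptophan")
}

#' Meat food-group identifiers
#'
#' The five-way disaggregation of meat used for headline summaries:
#' ruminant meat, poultry meat, pig meat, other meat, and separated offal
#' and fats.
#'
#' @return Character vector of group identifiers.
#' @export
meat_groups <- function() {
  c("ruminant_meat", "poultry_meat", "pig_meat", "other_meat",
    "offal_and_fats")
}

#' Default per-capita daily nutrient reference values
#'
#' Adult per-capita daily reference intakes in the registry unit of each
#' nutrient, in the spirit of international nutrient reference value
#' tables.  Used as the default requirement table by the synthetic-world
#' generator and the gap analysis; any column-compatible table can be
#' supplied instead.
#'
#' @return A data frame with columns `nutrient_id` and `per_capita_daily`.
#' @export
default_requirements <- function() {
  data.frame(
    nutrient_id = nutrient_registry()$nutrient_id,
    per_capita_daily = c(
      130, 2100, 70, 25, 50,           # macronutrients (g, kcal, g, g, g)
      1000, 0.9, 14, 350, 700,         # minerals (mg)
      3500, 60, 11,                    # K mg, Se ug, Zn mg
      750, 1.2, 1.2, 5, 1.3,           # vitamins A..B6
      400, 2.4, 75, 10,                # B9 ug, B12 ug, C mg, E mg
      0.3, 0.7, 2.7, 2.1, 0.7,         # IAA (g/day, ~70 kg adult)
      1.0, 0.28
    ),
    stringsAsFactors = FALSE
  )
}

# round-half-up to integer; base round() is half-to-even
round_half_up <- function(x) floor(x + 0.5)

# run expr with a private RNG stream, restoring global state afterwards
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
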