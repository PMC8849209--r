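# Hand-built miniature bundles with numbers simple enough to verify by
# hand; all tests that assert exact arithmetic use these.

empty_fractions <- function() {
  data.frame(kind = character(), commodity_id = character(),
             region_id = character(), fraction = numeric(),
             stringsAsFactors = FALSE)
}

balance_row <- function(commodity_id, group_id, production,
                        imports = 0, exports = 0, feed = 0, seed = 0,
                        processing_input = 0, other_uses = 0, losses = 0,
                        year = 2018) {
  data.frame(commodity_id = commodity_id, group_id = group_id, year = year,
             production = production, imports = imports, exports = exports,
             feed = feed, seed = seed, processing_input = processing_input,
             other_uses = other_uses, losses = losses,
             stringsAsFactors = FALSE)
}

# full 29-cell composition grid, zero except the named amounts
comp_grid <- function(...) {
  nutribalance:::full_composition(list(...))
}

# two commodities, two groups, clean numbers:
#   beef: production 100 t, no other flows, protein 20 g/100 g
#   wheat: production 300 t, protein 10 g/100 g
mini_bundle <- function(beef_extra = c(), wheat_extra = c(),
                        bioavailability = NULL, requirements = NULL,
                        population = 1e6) {
  if (is.null(requirements)) {
    requirements <- data.frame(nutrient_id = "protein",
                               per_capita_daily = 50,
                               stringsAsFactors = FALSE)
  }
  if (is.null(bioavailability)) {
    bioavailability <- data.frame(commodity_id = c("beef", "wheat"),
                                  nutrient_id = "protein",
                                  coefficient = 1, stringsAsFactors = FALSE)
  }
  nb_bundle(
    balances = rbind(balance_row("beef", "ruminant_meat", 100),
                     balance_row("wheat", "cereals", 300)),
    composition = comp_grid(
      beef = c(c(protein = 20, energy = 200, fat = 15), beef_extra),
      wheat = c(c(protein = 10, energy = 340, fat = 2,
                  carbohydrates = 70), wheat_extra)),
    fractions = empty_fractions(),
    bioavailability = bioavailability,
    population = data.frame(region_id = "GLOBAL", year = 2018,
                            headcount = population,
                            stringsAsFactors = FALSE),
    requirements = requirements
  )
}

expect_same_frame <- function(a, b, tolerance = 0) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  rownames(a) <- NULL; rownames(b) <- NULL
  expect_equal(a, b, tolerance = tolerance, ignore_attr = TRUE)
}
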