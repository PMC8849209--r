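simple_food <- function(consumed, ids = paste0("c", seq_along(consumed))) {
  data.frame(commodity_id = ids, group_id = ids, consumed = consumed,
             stringsAsFactors = FALSE)
}

test_that("consumed mass converts to nutrient units through the 1e4 factor", {
  comp <- comp_grid(c1 = c(protein = 20))
  av <- nutrient_availability(simple_food(1, "c1"), comp,
                              data.frame(commodity_id = "c1",
                                         nutrient_id = "protein",
                                         coefficient = 1))
  p <- av[av$nutrient_id == "protein", ]
  expect_equal(p$gross, 200000)       # 1 t x 1e4 x 20 g/100 g
  expect_equal(p$bioavailable, 200000)
  expect_equal(p$unit, "g")

  # an offal-like coefficient scales only the bioavailable quantity
  av <- nutrient_availability(simple_food(1, "c1"), comp,
                              data.frame(commodity_id = "c1",
                                         nutrient_id = "protein",
                                         coefficient = 0.76))
  p <- av[av$nutrient_id == "protein", ]
  expect_equal(p$bioavailable, 0.76 * p$gross)
})

test_that("missing composition contributes zero with a warning; units are checked", {
  comp <- comp_grid(c1 = c(protein = 20))
  comp$amount[comp$nutrient_id == "fiber"] <- NA
  coef1 <- data.frame(commodity_id = "c1", nutrient_id = "protein",
                      coefficient = 1)
  expect_warning(
    av <- nutrient_availability(simple_food(1, "c1"), comp, coef1),
    "missing composition")
  expect_equal(av$gross[av$nutrient_id == "fiber"], 0)

  comp2 <- comp_grid(c1 = c(protein = 20))
  comp2$unit[comp2$nutrient_id == "energy"] <- "g"
  expect_error(nutrient_availability(simple_food(1, "c1"), comp2),
               "unit mismatch")
})

test_that("absent bioavailability records default to 1 with a warning", {
  comp <- comp_grid(c1 = c(protein = 20))
  expect_warning(av <- nutrient_availability(simple_food(1, "c1"), comp,
                                             NULL),
                 "defaulted")
  expect_equal(av$bioavailable[av$nutrient_id == "protein"],
               av$gross[av$nutrient_id == "protein"])
})

test_that("group aggregation is exact summation over member commodities", {
  comp <- comp_grid(c1 = c(protein = 10, iron = 2),
                    c2 = c(protein = 10, iron = 2),
                    c3 = c(protein = 5))
  food <- simple_food(c(2, 2, 4), c("c1", "c2", "c3"))
  av <- suppressWarnings(nutrient_availability(food, comp))

  # one commodity per group: identity
  tax1 <- data.frame(commodity_id = c("c1", "c2", "c3"),
                     group_id = c("g1", "g2", "g3"))
  agg1 <- aggregate_by_group(av, tax1)
  expect_equal(agg1$gross[agg1$group_id == "g1" &
                            agg1$nutrient_id == "protein"],
               av$gross[av$commodity_id == "c1" &
                          av$nutrient_id == "protein"])

  # two equal commodities in one group: exactly double
  tax2 <- data.frame(commodity_id = c("c1", "c2", "c3"),
                     group_id = c("g", "g", "h"))
  agg2 <- aggregate_by_group(av, tax2)
  expect_equal(agg2$gross[agg2$group_id == "g" &
                            agg2$nutrient_id == "protein"],
               2 * av$gross[av$commodity_id == "c1" &
                              av$nutrient_id == "protein"])

  # group totals always sum to the global total, nutrient by nutrient
  by_n <- tapply(agg2$gross, agg2$nutrient_id, sum)
  global <- tapply(av$gross, av$nutrient_id, sum)
  expect_equal(by_n[names(global)], global)

  expect_error(aggregate_by_group(av,
                                  tax1[tax1$commodity_id != "c2", ]),
               "not mapped")
})

test_that("contribution percentages decompose the global total", {
  comp <- comp_grid(c1 = c(protein = 10, iron = 1),
                    c2 = c(protein = 30, iron = 3))
  food <- simple_food(c(1, 1), c("c1", "c2"))
  av <- suppressWarnings(nutrient_availability(food, comp))

  # a single group supplying everything gets 100% of each nonzero nutrient
  one <- contribution_percentages(aggregate_by_group(
    av, data.frame(commodity_id = c("c1", "c2"), group_id = "all")))
  expect_true(all(one$percent[!is.na(one$percent)] == 100))
  # zero-total nutrients are undefined-marked, not zero
  expect_true(all(is.na(one$percent[one$nutrient_id == "fiber"])))

  # hand-set 25/75 shares
  two <- contribution_percentages(aggregate_by_group(
    av, data.frame(commodity_id = c("c1", "c2"),
                   group_id = c("a", "b"))))
  expect_equal(two$percent[two$group_id == "a" &
                             two$nutrient_id == "protein"], 25)
  expect_equal(two$percent[two$group_id == "b" &
                             two$nutrient_id == "protein"], 75)
  # a group with zero availability of a present nutrient shows 0
  comp2 <- comp_grid(c1 = c(fiber = 5, protein = 10),
                     c2 = c(protein = 10))
  av2 <- suppressWarnings(nutrient_availability(food, comp2))
  ct2 <- render_display(contribution_percentages(aggregate_by_group(
    av2, data.frame(commodity_id = c("c1", "c2"),
                    group_id = c("plants", "meat")))))
  meat_fiber <- ct2[ct2$group_id == "meat" & ct2$nutrient_id == "fiber", ]
  expect_equal(meat_fiber$percent, 0)
  expect_equal(meat_fiber$display, "No contribution")
})

test_that("percentage columns sum to 100 and bioavailable never exceeds gross", {
  for (seed in c(21, 22, 23)) {
    b <- generate_world(world_config(seed = seed, n_commodities = 15,
                                     n_groups = 8))
    m <- suppressWarnings(nb_model(b))
    av <- m$availability
    expect_true(all(av$bioavailable <= av$gross + 1e-12))
    expect_true(all(av$gross >= 0))
    sums <- tapply(m$contributions$percent, m$contributions$nutrient_id,
                   sum)
    sums <- sums[!is.na(sums)]
    expect_true(all(abs(sums - 100) < 1e-9))
  }
})

test_that("percentages are invariant to uniform scaling; per-capita scales", {
  b <- generate_world(world_config(seed = 31, n_commodities = 12,
                                   n_groups = 7))
  m1 <- suppressWarnings(nb_model(b))
  k <- 3.7
  b2 <- b
  for (f in nutribalance:::BALANCE_MASS_FIELDS) {
    b2$balances[[f]] <- b2$balances[[f]] * k
  }
  m2 <- suppressWarnings(nb_model(b2))
  expect_equal(m2$contributions$percent, m1$contributions$percent,
               tolerance = 1e-12)
  expect_equal(m2$per_capita$per_capita_daily,
               k * m1$per_capita$per_capita_daily, tolerance = 1e-12)
})

test_that("subgroup contributions add to the aggregate-group contribution", {
  b <- make_paperlike_world()
  m <- nb_model(b)
  ct <- m$contributions
  merged_tax <- b$balances[c("commodity_id", "group_id")]
  merged_tax$group_id[merged_tax$group_id %in% meat_groups()] <- "all_meat"
  m2 <- suppressWarnings(nb_model(local({
    b2 <- b; b2$balances$group_id <- merged_tax$group_id; b2
  }), focus_groups = "all_meat"))
  for (nut in c("protein", "methionine", "vitamin_b12", "iron")) {
    split_sum <- sum(ct$percent[ct$group_id %in% meat_groups() &
                                  ct$nutrient_id == nut])
    merged <- m2$contributions$percent[
      m2$contributions$group_id == "all_meat" &
        m2$contributions$nutrient_id == nut]
    expect_equal(split_sum, merged, tolerance = 1e-9)
  }
})

test_that("per-capita daily conversion handles mass and nutrient units", {
  expect_equal(per_capita_daily(365, 1e6, mass_tonnes = TRUE), 1)
  expect_equal(per_capita_daily(0, 1e6), 0)
  expect_error(per_capita_daily(10, 0), "positive")
  # 316 Mt across 7.53e9 people is roughly 115 g/person/day
  expect_equal(per_capita_daily(316e6, 7.53e9, mass_tonnes = TRUE), 115,
               tolerance = 0.001)
})

test_that("display rendering follows the published-table convention", {
  ct <- structure(
    data.frame(group_id = "g",
               nutrient_id = paste0("n", 1:6),
               percent = c(0.3, 0, 20.5, 20.4, 0.5, NA)),
    class = c("nb_contributions", "data.frame"))
  out <- render_display(ct)
  expect_equal(out$display,
               c("<0.5", "No contribution", "21", "20", "1", "n/a"))
  expect_equal(parse_display(out$display),
               c(NA, 0, 21, 20, 1, NA))
})

test_that("the shipped reference contribution table is complete and parseable", {
  ref <- meat_contribution_reference()
  expect_equal(nrow(ref), 29)
  expect_setequal(ref$nutrient_id, nutrient_registry()$nutrient_id)
  expect_equal(parse_display(ref$all_meat[ref$nutrient_id == "fiber"]), 0)
  expect_true(is.na(parse_display("<0.5")))
})
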