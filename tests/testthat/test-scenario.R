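test_that("the identity scenario is a bitwise no-op", {
  b <- generate_world(world_config(seed = 41, n_commodities = 10,
                                   n_groups = 7))
  out <- apply_scenario(b, scenario_spec())
  expect_identical(out, b)
  m1 <- suppressWarnings(nb_model(b))
  m2 <- suppressWarnings(nb_model(out))
  expect_identical(m1$contributions$percent, m2$contributions$percent)
  expect_identical(m1$food, m2$food)
})

test_that("removing meat zeroes its contribution to every nutrient", {
  b <- make_paperlike_world()
  spec <- scenario_spec(removals = meat_groups(), default_multiplier = 1.2)
  out <- apply_scenario(b, spec)
  m <- nb_model(out)
  meat_rows <- m$contributions$group_id %in% meat_groups()
  pct <- m$contributions$percent[meat_rows]
  expect_true(all(pct[!is.na(pct)] == 0))
  # and the non-meat ledgers scaled by exactly 1.2
  wheat0 <- b$balances$production[b$balances$commodity_id == "cereal_grains"]
  wheat1 <- out$balances$production[out$balances$commodity_id ==
                                      "cereal_grains"]
  expect_equal(wheat1, 1.2 * wheat0)
})

test_that("scaling one of two equal groups by 2 yields a 2/3 share", {
  b <- mini_bundle(wheat_extra = c())
  # equalise: both commodities same protein availability
  b$balances$production <- c(100, 100)
  b$composition$amount[b$composition$nutrient_id == "protein"] <- 20
  spec <- scenario_spec(scalings = c(ruminant_meat = 2))
  m <- suppressWarnings(nb_model(apply_scenario(b, spec),
                                 focus_groups = character()))
  p <- m$contributions
  expect_equal(p$percent[p$group_id == "ruminant_meat" &
                           p$nutrient_id == "protein"], 200 / 3,
               tolerance = 1e-12)
})

test_that("scenario validation rejects inconsistent specs", {
  expect_error(scenario_spec(removals = "dairy",
                             scalings = c(dairy = 2)), "both")
  expect_error(scenario_spec(scalings = c(dairy = -1)), ">= 0")
  expect_error(scenario_spec(scalings = 2), "named")
  b <- mini_bundle()
  expect_error(apply_scenario(b, scenario_spec(removals = "atlantis")),
               "atlantis")
})

test_that("gap percentages follow the shortfall formula", {
  mk <- function(avail_ratio) {
    # availability = ratio x requirement via production choice:
    # consumed c t -> protein g/yr = c*1e4*20; requirement 50 g/day
    req_year <- 50 * 1e6 * 365
    b <- mini_bundle()
    b$balances <- b$balances[b$balances$commodity_id == "beef", ]
    b$composition <- b$composition[b$composition$commodity_id == "beef", ]
    b$bioavailability <- b$bioavailability[
      b$bioavailability$commodity_id == "beef", ]
    b$balances$production <- avail_ratio * req_year / (1e4 * 20)
    b
  }
  g <- suppressWarnings(nutrient_gaps(mk(0.65)))
  expect_equal(g$gap_percent[g$nutrient_id == "protein"], 35,
               tolerance = 1e-9)
  expect_false(g$surplus[g$nutrient_id == "protein"])
  g <- suppressWarnings(nutrient_gaps(mk(1)))
  expect_equal(g$gap_percent[g$nutrient_id == "protein"], 0,
               tolerance = 1e-9)
  expect_true(g$surplus[g$nutrient_id == "protein"])
  g <- suppressWarnings(nutrient_gaps(mk(1e-12)))
  expect_equal(g$gap_percent[g$nutrient_id == "protein"], 100,
               tolerance = 1e-6)
  b0 <- mk(0)
  b0$balances$production <- 0
  g <- suppressWarnings(nutrient_gaps(b0))
  expect_equal(g$gap_percent[g$nutrient_id == "protein"], 100)
  # nutrients without requirement rows are omitted with a warning
  expect_warning(nutrient_gaps(mk(1)), "omitted")
})

test_that("replacement multiplier solves the closed form", {
  # donor supplies 50% of requirement, removed group the other 50%
  req_year <- 2.4 * 1e6 * 365
  mk2 <- function(donor_share, removed_share, other_share = 0) {
    shares <- c(meat = removed_share, dairy = donor_share,
                cereals = other_share)
    prod <- shares * req_year / (1e4 * 1)   # 1 ug B12 per 100 g each
    bal <- rbind(balance_row("meat", "ruminant_meat", prod[["meat"]]),
                 balance_row("dairy", "dairy", prod[["dairy"]]),
                 balance_row("cereals", "cereals", prod[["cereals"]]))
    nb_bundle(
      balances = bal,
      composition = comp_grid(meat = c(vitamin_b12 = 1),
                              dairy = c(vitamin_b12 = 1),
                              cereals = c(vitamin_b12 = 1)),
      fractions = empty_fractions(),
      population = data.frame(region_id = "GLOBAL", year = 2018,
                              headcount = 1e6),
      requirements = data.frame(nutrient_id = "vitamin_b12",
                                per_capita_daily = 2.4))
  }
  m <- replacement_multiplier(mk2(0.5, 0.5), "dairy", "ruminant_meat",
                              "vitamin_b12")
  expect_equal(m, 2, tolerance = 1e-12)
  # removed group supplied nothing and baseline is sufficient: m = 1
  m <- replacement_multiplier(mk2(1, 0), "dairy", "ruminant_meat",
                              "vitamin_b12")
  expect_equal(m, 1)
  # donor supplies none of the nutrient: cannot close
  b <- mk2(0.5, 0.5)
  b$composition$amount[b$composition$commodity_id == "dairy"] <- 0
  expect_warning(m <- replacement_multiplier(b, "dairy", "ruminant_meat",
                                             "vitamin_b12"),
                 "cannot be closed")
  expect_identical(m, Inf)
  expect_error(replacement_multiplier(mk2(1, 0), "dairy", "dairy",
                                      "vitamin_b12"), "also be removed")
})

test_that("the tuned world needs a tripling of dairy, and it closes the gap", {
  b <- make_replacement_world()
  m <- replacement_multiplier(b, "dairy", "ruminant_meat", "vitamin_b12")
  expect_equal(m, 3, tolerance = 1e-9)
  after <- apply_scenario(b, scenario_spec(removals = "ruminant_meat",
                                           scalings = c(dairy = m)))
  g <- suppressWarnings(nutrient_gaps(after))
  expect_lte(g$gap_percent[g$nutrient_id == "vitamin_b12"], 1e-9)
})

test_that("removal never increases availability; scaling is linear", {
  b <- generate_world(world_config(seed = 51, n_commodities = 12,
                                   n_groups = 8))
  base <- suppressWarnings(nb_model(b))
  base_tot <- tapply(base$group_totals$effective,
                     base$group_totals$nutrient_id, sum)
  for (g in c("pig_meat", "cereals")) {
    cut <- suppressWarnings(nb_model(
      apply_scenario(b, scenario_spec(removals = g))))
    cut_tot <- tapply(cut$group_totals$effective,
                      cut$group_totals$nutrient_id, sum)
    expect_true(all(cut_tot <= base_tot[names(cut_tot)] + 1e-9))
  }
  # availability is linear in a group multiplier (three points)
  pick <- function(mult) {
    m <- suppressWarnings(nb_model(
      apply_scenario(b, scenario_spec(scalings = c(dairy = mult)))))
    tot <- m$group_totals
    sum(tot$effective[tot$group_id == "dairy" &
                        tot$nutrient_id == "protein"])
  }
  y1 <- pick(1); y2 <- pick(2); y3 <- pick(3)
  expect_equal(y2 - y1, y3 - y2, tolerance = 1e-9)
  expect_equal(y2, 2 * y1, tolerance = 1e-9)
})
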