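test_that("net supply is the ledger arithmetic, clamped at zero", {
  expect_equal(net_supply(balance_row("a", "g", 100, feed = 3, losses = 2)),
               c(a = 95))
  # 333 at the farm gate with a 95% food fraction leaves 316.35
  expect_equal(net_supply(balance_row("meat", "g", 333, losses = 16.65)),
               c(meat = 316.35))
  expect_equal(net_supply(balance_row("a", "g", 50, imports = 10,
                                      exports = 10)),
               c(a = 50))
  expect_warning(out <- net_supply(balance_row("a", "g", 10, feed = 20)),
                 "clamped")
  expect_equal(out, c(a = 0))
})

test_that("strict trade netting accepts balanced worlds, rejects imbalance", {
  for (seed in 1:5) {
    b <- generate_world(world_config(seed = seed, n_commodities = 8,
                                     n_groups = 7))
    bal <- b$balances
    expect_silent(net_supply(bal, trade_mode = "strict_zero"))
    bal$imports[3] <- bal$imports[3] + 0.01 * bal$production[3]
    expect_error(net_supply(bal, trade_mode = "strict_zero"),
                 bal$commodity_id[3], fixed = TRUE)
  }
})

test_that("processing distributes parent mass to children by extraction rate", {
  bal <- rbind(
    balance_row("animal", "pig_meat", 100, processing_input = 100),
    balance_row("meat", "pig_meat", 0),
    balance_row("offal", "offal_and_fats", 0),
    balance_row("fat", "offal_and_fats", 0))
  rules <- data.frame(parent_id = "animal",
                      child_id = c("meat", "offal", "fat"),
                      extraction_rate = c(0.6, 0.07, 0.02))
  out <- apply_processing(bal, rules)
  gains <- out$production - bal$production
  expect_equal(gains, c(0, 60, 7, 2))
  # mass conservation: gains + residual = input
  expect_equal(sum(gains) + (1 - sum(rules$extraction_rate)) * 100, 100)

  # no rules: identity
  expect_identical(apply_processing(bal, bal[0, 0]), bal)

  # two-level chain composes as the product of rates
  chain <- rbind(
    balance_row("animal", "pig_meat", 100, processing_input = 100),
    balance_row("carcass", "pig_meat", 0, processing_input = 70),
    balance_row("cuts", "pig_meat", 0))
  rules2 <- data.frame(parent_id = c("animal", "carcass"),
                       child_id = c("carcass", "cuts"),
                       extraction_rate = c(0.7, 0.6))
  out2 <- apply_processing(chain, rules2)
  expect_equal(out2$production[out2$commodity_id == "cuts"], 100 * 0.7 * 0.6)
  # the intermediate nets to zero food: gained 70, processed 70
  expect_equal(unname(net_supply(out2)["carcass"]), 0)
})

test_that("processing rejects cycles and over-unity extraction", {
  bal <- rbind(balance_row("a", "g", 10, processing_input = 5),
               balance_row("b", "g", 10, processing_input = 5))
  expect_error(apply_processing(bal, data.frame(
    parent_id = c("a", "b"), child_id = c("b", "a"),
    extraction_rate = c(0.5, 0.5))), "cycle")
  expect_error(apply_processing(bal, data.frame(
    parent_id = "a", child_id = c("b", "b"),
    extraction_rate = c(0.6, 0.6))), "exceed")
})

test_that("inedible-then-waste adjustment reports conserved components", {
  r <- consumed_mass(100, 0.20, 0.10)
  expect_equal(r$consumed, 72)
  expect_equal(r$inedible_mass, 20)
  expect_equal(r$wasted_mass, 8)
  # poultry-like upper bound: 43% inedible
  expect_equal(consumed_mass(100, 0.43, 0)$edible_available, 57)
  # zero waste: consumed equals edible
  r <- consumed_mass(80, 0.1, 0)
  expect_identical(r$consumed, r$edible_available)
  expect_error(consumed_mass(10, 1.0, 0), "fractions")
  expect_error(consumed_mass(10, 0, -0.1), "fractions")
})

test_that("mass conservation and monotonicity hold over random inputs", {
  set.seed(42)
  av <- runif(200, 0, 1e6)
  ie <- runif(200, 0, 0.99)
  wa <- runif(200, 0, 0.99)
  r <- consumed_mass(av, ie, wa)
  expect_equal(r$available_as_food,
               (r$consumed + r$wasted_mass) + r$inedible_mass,
               tolerance = 1e-14)
  # for fractions below one half (the realistic food ranges) the identity
  # is exact to the bit in this summation order
  r2 <- consumed_mass(av, ie / 2, wa / 2)
  expect_identical(r2$available_as_food,
                   (r2$consumed + r2$wasted_mass) + r2$inedible_mass)
  expect_true(all(r$consumed >= 0 & r$wasted_mass >= 0 &
                    r$inedible_mass >= 0))
  # consumed non-increasing in fractions, non-decreasing in mass
  expect_true(all(consumed_mass(av, pmin(ie + 0.005, 0.999), wa)$consumed
                  <= r$consumed))
  expect_true(all(consumed_mass(av, ie, pmin(wa + 0.005, 0.999))$consumed
                  <= r$consumed))
  expect_true(all(consumed_mass(av * 1.1, ie, wa)$consumed >= r$consumed))
})

test_that("regional waste fractions aggregate by population weight", {
  b <- mini_bundle()
  b$population <- data.frame(
    region_id = c("GLOBAL", "north", "south"), year = 2018,
    headcount = c(1e6, 7.5e5, 2.5e5))
  b$fractions <- data.frame(
    kind = c("inedible", "waste", "waste"),
    commodity_id = "beef",
    region_id = c("GLOBAL", "north", "south"),
    fraction = c(0.2, 0.08, 0.04))
  fm <- food_mass(b)
  w <- (0.08 * 7.5e5 + 0.04 * 2.5e5) / 1e6   # 0.07
  beef <- fm[fm$commodity_id == "beef", ]
  expect_equal(beef$available_as_food, 100)
  expect_equal(beef$edible_available, 80)
  expect_equal(beef$consumed, 80 * (1 - w))
  # wheat has no fraction rows: consumed everything
  expect_equal(fm$consumed[fm$commodity_id == "wheat"], 300)
})
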