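test_that("integrated productivity evaluates the calorie-accounting formula", {
  spec1 <- grid_spec(1, 1, seed = 1)
  one <- make_stack(spec1, yield = 1e7, harvest_share = 1)
  expect_equal(integrated_productivity(one), 1e7)

  # two crops, shares (0.25, 0.75), loss 0.10, waste 0.17
  two <- make_stack(spec1, yield = c(8e6, 4e6),
                    harvest_share = matrix(c(0.25, 0.75), 1),
                    food_loss = 0.10, food_waste = 0.17)
  expect_equal(integrated_productivity(two), 3.735e6)

  # no-crop-data pixel gets zero; bad shares are rejected
  spec2 <- grid_spec(2, 1, seed = 1)
  mixed <- make_stack(spec2, yield = c(8e6, 4e6),
                      harvest_share = rbind(c(0.25, 0.75), c(0, 0)))
  expect_equal(integrated_productivity(mixed)[2], 0)
  bad <- make_stack(spec2, yield = c(8e6, 4e6),
                    harvest_share = rbind(c(0.25, 0.75), c(0.4, 0.3)))
  expect_error(integrated_productivity(bad), "sum to 0 or 1")
})

test_that("productivity never exceeds the best crop after deductions", {
  spec <- grid_spec(30, 30, seed = 15)
  stack <- generate_environment(spec)
  prod <- integrated_productivity(stack)
  cap <- max(stack$yield) * (1 - stack$food_loss) * (1 - stack$food_waste)
  expect_true(all(prod <= cap + 1e-9))
})

test_that("food potential is the per-pixel ledger in Pcal", {
  spec <- grid_spec(40, 25, seed = 1)  # 1,000 pixels x 9 ha
  prod <- rep(1e7, n_pixels(spec))
  expect_equal(food_potential(rep(TRUE, 1000), prod, spec), 0.09)
  expect_equal(food_potential(rep(FALSE, 1000), prod, spec), 0)

  # oracle equivalence on a random selection and additivity over a split
  set.seed(8)
  prod <- runif(1000, 0, 2e7)
  sel <- runif(1000) < 0.4
  manual <- sum(vapply(which(sel), function(i) prod[i] * 9, numeric(1))) / 1e12
  expect_equal(food_potential(sel, prod, spec), manual)
  part <- sel & (seq_len(1000) <= 500)
  rest <- sel & !part
  expect_equal(food_potential(part, prod, spec) +
                 food_potential(rest, prod, spec),
               food_potential(sel, prod, spec))
})

test_that("clearing emissions follow cover type, stoichiometry and horizon", {
  spec <- grid_spec(4, 1, seed = 1)
  stack <- make_stack(spec, yield = 1, harvest_share = rep(1, 4),
                      agb_rate = 2, biomass_stock = 10)
  final <- c(FOREST, GRASS, SHRUB, FOREST)
  ab_year <- c(2010L, 2005L, NA, 2020L)
  ce <- clearing_emission(stack, final, ab_year, horizon = 30,
                          final_year = 2020)
  expect_equal(ce$clear_emit[1], 2 * 10 * 44 / 12)       # regrowth: rate x years
  expect_equal(ce$clear_emit[2], 10 * 44 / 12)           # grass: stock
  expect_equal(ce$clear_emit[2], 36.667, tolerance = 1e-4)
  expect_equal(ce$clear_emit_rate[2], 1.222, tolerance = 1e-3)
  expect_true(is.na(ce$clear_emit[3]))
  expect_equal(ce$clear_emit[4], 0)                      # abandoned this year

  zero <- make_stack(spec, yield = 1, harvest_share = rep(1, 4))
  expect_equal(clearing_emission(zero, final, ab_year)$clear_emit[1:2],
               c(0, 0))
  expect_error(clearing_emission(stack, final, rep(2021L, 4),
                                 final_year = 2020),
               "negative")
})

test_that("instant and amortized clearing emissions are consistent totals", {
  # a 30-yr average of 156 MtCO2/yr amortizes an instant release of
  # 4.7 GtCO2 (2 significant figures)
  instant_gt <- 156 * 30 / 1000
  expect_equal(signif(instant_gt, 2), 4.7)
  # and the package's surfaces satisfy emit = rate * horizon exactly
  spec <- grid_spec(20, 20, seed = 3)
  sim <- simulate_study(spec, p_recult = 0)
  map <- detect_abandonment(temporal_filter(sim$series, 5))
  sf <- potential_surfaces(sim$stack, sim$series, map, horizon = 30)
  ok <- !is.na(sf$clear_emit)
  expect_equal(sf$clear_emit[ok], sf$clear_emit_rate[ok] * 30)
})

test_that("net mitigation is credit minus amortized debit", {
  # 1 Mha reforested at 11.5 MgCO2/yr/ha, nothing recultivated
  spec <- grid_spec(100, 1, pixel_area = 1e4, seed = 1)  # 100 x 10,000 ha
  sfc <- make_surfaces(rep(0, 100), rep(11.5, 100), rep(2, 100), spec)
  alloc <- list(reforest = rep(TRUE, 100), recultivate = rep(FALSE, 100))
  expect_equal(net_mitigation(alloc, sfc, spec), 11.5)
  none <- list(reforest = rep(FALSE, 100), recultivate = rep(FALSE, 100))
  expect_equal(net_mitigation(none, sfc, spec), 0)

  # brute-force per-pixel ledger on random allocations
  set.seed(31)
  spec9 <- grid_spec(50, 10, seed = 1)
  sfc9 <- make_surfaces(rep(0, 500), runif(500, 0, 20), runif(500, 0, 5),
                        spec9)
  for (rep_i in 1:5) {
    z <- sample(c("recultivate", "reforest", "unused"), 500, replace = TRUE)
    alloc <- list(recultivate = z == "recultivate", reforest = z == "reforest")
    manual <- (sum(sfc9$seq[alloc$reforest]) -
                 sum(sfc9$clear_emit_rate[alloc$recultivate])) * 9 / 1e6
    expect_equal(net_mitigation(alloc, sfc9, spec9), manual)
  }

  # with no clearing debit, adding reforested pixels never decreases it
  base <- list(reforest = rep(FALSE, 500), recultivate = rep(FALSE, 500))
  vals <- vapply(c(100, 200, 300, 400, 500), function(k) {
    base$reforest[seq_len(k)] <- TRUE
    net_mitigation(base, sfc9, spec9)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("identity levers leave the surfaces unchanged", {
  spec <- grid_spec(20, 20, seed = 5)
  sim <- simulate_study(spec, p_recult = 0)
  map <- detect_abandonment(temporal_filter(sim$series, 5))
  sf <- potential_surfaces(sim$stack, sim$series, map)
  sf2 <- apply_levers(sf, sim$stack, lever_set(1, 0, 1, 1))
  expect_equal(sf2$productivity, sf$productivity)
  expect_equal(sf2$seq, sf$seq)
})

test_that("halving waste and loss rescales productivity by the closed form", {
  n <- 50
  spec <- grid_spec(n, 1, seed = 1)
  stack <- make_stack(spec, yield = c(8e6, 4e6),
                      harvest_share = matrix(rep(c(0.5, 0.5), each = n), n),
                      food_loss = 0.2, food_waste = 0.17)
  map <- make_map(rep("abandoned", n), spec)
  series <- make_series(matrix(rep(trajectory(1992:2020, 2010, GRASS),
                                   each = n), n),
                        spec = spec)
  sf <- potential_surfaces(stack, series, map)
  sf2 <- apply_levers(sf, stack, lever_set(waste_loss_scaling = 0.5))
  factor_expected <- (1 - 0.1) * (1 - 0.085) / ((1 - 0.2) * (1 - 0.17))
  expect_equal(sf2$productivity / sf$productivity, rep(factor_expected, n))
})

test_that("active reforestation boosts sequestration outside protected areas only", {
  n <- 10
  spec <- grid_spec(n, 1, seed = 1)
  stack <- make_stack(spec, yield = 1, harvest_share = rep(1, n),
                      seq_rate = 10, protected = c(rep(TRUE, 4), rep(FALSE, 6)))
  sf <- make_surfaces(rep(0, n), stack$seq_rate, rep(0, n), spec)
  sf2 <- apply_levers(sf, stack, lever_set(
    active_reforestation_multiplier = 1.53))
  expect_equal(sf2$seq[1:4], rep(10, 4))
  expect_equal(sf2$seq[5:10], rep(15.3, 6))
})

test_that("irrigation and yield-gap levers move yields as configured", {
  spec <- grid_spec(1, 1, seed = 1)
  stack <- make_stack(spec, yield = 1e7, harvest_share = 1,
                      attainable_yield = 1.4e7)
  map <- make_map("abandoned", spec)
  series <- make_series(matrix(trajectory(1992:2020, 2010, GRASS), 1),
                        spec = spec)
  sf <- potential_surfaces(stack, series, map)
  # full gap closure from rain-fed: productivity hits the attainable yield
  sf_gap <- apply_levers(sf, stack, lever_set(yield_gap_closure = 1))
  expect_equal(sf_gap$productivity, 1.4e7)
  # irrigation beyond the attainable ceiling is never clawed back
  sf_irr <- apply_levers(sf, stack, lever_set(irrigation_multiplier = 1.62,
                                              yield_gap_closure = 1))
  expect_equal(sf_irr$productivity, 1.62e7)
  expect_error(lever_set(irrigation_multiplier = 0.5))
  expect_error(lever_set(yield_gap_closure = 1.2))
})
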