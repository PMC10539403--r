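# A small fully-specified landscape whose optimum can be enumerated:
# singles keep their only purpose, so the decision space is the 2^n
# split of the both-suitable pool.
toy_landscape <- function(n_both = 5, n_rec = 2, n_ref = 2, n_nei = 1,
                          seed = 1) {
  n <- n_both + n_rec + n_ref + n_nei
  spec <- grid_spec(n, 1, seed = 1)
  type <- c(rep("both", n_both), rep("recult_only", n_rec),
            rep("reforest_only", n_ref), rep("neither", n_nei))
  set.seed(seed)
  surfaces <- make_surfaces(runif(n, 1e6, 2e7), runif(n, 1, 20),
                            runif(n, 0, 4), spec)
  list(types = make_types(type, spec), surfaces = surfaces, spec = spec,
       both = seq_len(n_both))
}

# enumerate every allocation that uses all suitable pixels
enumerate_outcomes <- function(L, F_max, C_max) {
  n_both <- length(L$both)
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), n_both))
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    purpose <- rep(NA_character_, length(L$types$type))
    purpose[!is.na(L$types$type)] <- "unused"
    purpose[L$types$type == "recult_only"] <- "recultivate"
    purpose[L$types$type == "reforest_only"] <- "reforest"
    purpose[L$both] <- ifelse(unlist(grid[i, ]), "recultivate", "reforest")
    alloc <- structure(list(purpose = factor(purpose,
                                             levels = c("recultivate",
                                                        "reforest", "unused")),
                            spec = L$spec, scenario = "enumerated"),
                       class = "allocation")
    evaluate_allocation(alloc, L$surfaces, F_max, C_max, L$spec)
  }))
}

test_that("representative scenarios attain the enumerated optima", {
  for (seed in 1:3) {
    L <- toy_landscape(n_both = 5, seed = seed)
    mx <- landscape_maxima(L$types, L$surfaces, L$spec)
    all_out <- enumerate_outcomes(L, mx$F_max, mx$C_max)

    ev <- function(nm) {
      evaluate_allocation(representative_scenario(nm, L$types, L$surfaces),
                          L$surfaces, mx$F_max, mx$C_max, L$spec)
    }
    expect_equal(ev("max_food")$F, max(all_out$F))
    expect_equal(ev("max_climate")$C_net, max(all_out$C_net))
    expect_equal(ev("max_combined")$combined, max(all_out$combined))
  }
})

test_that("a 12-both-pixel landscape is still exactly optimal", {
  L <- toy_landscape(n_both = 12, n_rec = 3, n_ref = 3, n_nei = 2, seed = 4)
  mx <- landscape_maxima(L$types, L$surfaces, L$spec)
  all_out <- enumerate_outcomes(L, mx$F_max, mx$C_max)
  got <- evaluate_allocation(
    representative_scenario("max_combined", L$types, L$surfaces),
    L$surfaces, mx$F_max, mx$C_max, L$spec)
  expect_equal(got$combined, max(all_out$combined))
})

test_that("the combined-potential ranking places max_combined on top", {
  for (seed in 4:6) {
    L <- toy_landscape(n_both = 8, seed = seed)
    mx <- landscape_maxima(L$types, L$surfaces, L$spec)
    combined <- vapply(c("max_food", "max_climate", "equal_allocation",
                         "max_combined"), function(nm) {
      evaluate_allocation(representative_scenario(nm, L$types, L$surfaces),
                          L$surfaces, mx$F_max, mx$C_max, L$spec)$combined
    }, numeric(1))
    expect_true(all(combined["max_combined"] >= combined + (-1e-9)))
  }
})

test_that("every allocation respects suitability and single purpose", {
  L <- toy_landscape(n_both = 6, seed = 7)
  for (nm in c("max_food", "max_climate", "equal_allocation",
               "max_combined")) {
    alloc <- representative_scenario(nm, L$types, L$surfaces)
    rec <- !is.na(alloc$purpose) & alloc$purpose == "recultivate"
    ref <- !is.na(alloc$purpose) & alloc$purpose == "reforest"
    expect_true(all(L$types$recult_suitable[rec]))
    expect_true(all(L$types$reforest_suitable[ref]))
    expect_false(any(rec & ref))
    # abandoned pixels all get exactly one label
    expect_false(any(is.na(alloc$purpose[!is.na(L$types$type)])))
  }
  expect_error(representative_scenario("maximize_profit", L$types,
                                       L$surfaces), "unknown scenario")
})

test_that("equal allocation balances the two purposes to within one pixel", {
  L <- toy_landscape(n_both = 9, n_rec = 2, n_ref = 4, seed = 8)
  alloc <- representative_scenario("equal_allocation", L$types, L$surfaces)
  n_rec <- sum(alloc$purpose == "recultivate", na.rm = TRUE)
  n_ref <- sum(alloc$purpose == "reforest", na.rm = TRUE)
  expect_lte(abs(n_rec - n_ref), 1)
})

test_that("without a both-suitable pool all scenarios coincide", {
  L <- toy_landscape(n_both = 0, n_rec = 3, n_ref = 3, seed = 9)
  allocs <- lapply(c("max_food", "max_climate", "equal_allocation",
                     "max_combined"), function(nm) {
    representative_scenario(nm, L$types, L$surfaces)$purpose
  })
  for (a in allocs[-1]) expect_identical(a, allocs[[1]])
})

test_that("percent-of-maximum indicators reproduce the scenario-table rows", {
  s1 <- potential_shares(363, 290, 363, 1080)
  expect_equal(unname(s1["A"]), 100)
  expect_equal(round(unname(s1["B"])), 27)
  expect_equal(round(unname(s1["combined"])), 127)
  expect_equal(unname(s1["combined"]), unname(s1["A"] + s1["B"]))

  s2 <- potential_shares(295, 667, 363, 1080)
  expect_equal(round(unname(s2["A"])), 81)
  expect_equal(round(unname(s2["B"])), 62)
  expect_equal(round(unname(s2["combined"])), 143)

  s3 <- potential_shares(29, 1066, 363, 1080)
  expect_equal(round(unname(s3["A"])), 8)
  expect_equal(round(unname(s3["B"])), 99)
  expect_equal(round(unname(s3["combined"])), 107)

  s4 <- potential_shares(269, 508, 363, 1080)
  expect_equal(round(unname(s4["combined"])), 121)
})

test_that("an empty allocation evaluates to zero everywhere", {
  L <- toy_landscape(n_both = 4, seed = 10)
  purpose <- rep(NA_character_, length(L$types$type))
  purpose[!is.na(L$types$type)] <- "unused"
  empty <- structure(list(purpose = factor(purpose,
                                           levels = c("recultivate",
                                                      "reforest", "unused")),
                          spec = L$spec, scenario = "empty"),
                     class = "allocation")
  out <- evaluate_allocation(empty, L$surfaces, 100, 100, L$spec)
  expect_equal(out$F, 0)
  expect_equal(out$C_net, 0)
  expect_equal(out$combined, 0)
})

test_that("whole-pool sweeps coincide across strategies and respect seeds", {
  spec <- grid_spec(50, 50, seed = 3)
  sim <- simulate_study(spec, p_abandon = 0.2, p_recult = 0.3)
  f <- temporal_filter(sim$series, 5)
  map <- detect_abandonment(f)
  fit <- fit_recultivation_suitability(detect_recultivation_presence(f),
                                       sim$stack, seed = 1)
  types <- classify_suitability(predict(fit, sim$stack, tau = 0.5),
                                sim$stack, map)
  sf <- potential_surfaces(sim$stack, sim$series, map)
  fr <- c(0.25, 1)
  pri <- fraction_sweep(types, sf, "recultivate", fr, "prioritized")
  rnd <- fraction_sweep(types, sf, "recultivate", fr, "randomized", seed = 5)
  rnd2 <- fraction_sweep(types, sf, "recultivate", fr, "randomized", seed = 5)
  # at f = 1 the whole suitable pool is selected either way
  expect_equal(pri$F[2], rnd$F[2])
  expect_identical(rnd, rnd2)
  # large fractions exhaust the suitable pool and are flagged
  expect_true(pri$shortfall[2])
  expect_false(pri$shortfall[1])
})

test_that("prioritized selection matches the analytic high-tier sum", {
  # two-valued productivity: half the suitable pool at 2e7, half at 5e6
  n <- 40
  spec <- grid_spec(n, 1, seed = 1)
  types <- make_types(rep("recult_only", n), spec)
  prod <- c(rep(2e7, 20), rep(5e6, 20))
  sf <- make_surfaces(prod, rep(1, n), rep(0, n), spec)
  sw <- fraction_sweep(types, sf, "recultivate", 0.5, "prioritized",
                       F_max = 1, C_max = 1)
  expect_equal(sw$F, 20 * 2e7 * 9 / 1e12)
})

test_that("prioritization dominates randomized selection on gradients", {
  spec <- grid_spec(50, 50, seed = 12)
  sim <- simulate_study(spec, p_abandon = 0.2, p_recult = 0.3)
  f <- temporal_filter(sim$series, 5)
  map <- detect_abandonment(f)
  fit <- fit_recultivation_suitability(detect_recultivation_presence(f),
                                       sim$stack, seed = 1)
  types <- classify_suitability(predict(fit, sim$stack, tau = 0.5),
                                sim$stack, map)
  sf <- potential_surfaces(sim$stack, sim$series, map)
  fr <- c(0.1, 0.3, 0.5)
  pri_f <- fraction_sweep(types, sf, "recultivate", fr, "prioritized")
  pri_c <- fraction_sweep(types, sf, "reforest", fr, "prioritized")
  for (seed in 1:5) {
    rnd_f <- fraction_sweep(types, sf, "recultivate", fr, "randomized", seed)
    rnd_c <- fraction_sweep(types, sf, "reforest", fr, "randomized", seed)
    expect_true(all(pri_f$F >= rnd_f$F))
    expect_true(all(pri_c$C_net >= rnd_c$C_net))
  }
})

test_that("prioritization benefit is zero without heterogeneity", {
  n <- 30
  spec <- grid_spec(n, 1, seed = 1)
  types <- make_types(rep("recult_only", n), spec)
  sf <- make_surfaces(rep(1e7, n), rep(1, n), rep(0, n), spec)
  fr <- c(0.2, 0.5, 0.9)
  pri <- fraction_sweep(types, sf, "recultivate", fr, "prioritized",
                        F_max = 1, C_max = 1)
  rnd <- fraction_sweep(types, sf, "recultivate", fr, "randomized",
                        seed = 2, F_max = 1, C_max = 1)
  ben <- prioritization_benefit(pri, rnd)
  expect_equal(ben$uplift_F_pct, rep(0, 3))
  # identical sweeps trivially give zero uplift
  ben0 <- prioritization_benefit(pri, pri)
  expect_equal(ben0$uplift_F_pct, rep(0, 3))
  expect_equal(ben0$area_saved_mha, rep(0, 3))
  # unpaired fractions are rejected
  rnd_bad <- fraction_sweep(types, sf, "recultivate", c(0.2, 0.5),
                            "randomized", seed = 2, F_max = 1, C_max = 1)
  expect_error(prioritization_benefit(pri, rnd_bad), "share fractions")
})

test_that("prioritization benefit decays as the used fraction grows", {
  # steep two-tier gradient: uplift is largest at small fractions and
  # vanishes at f = 1
  n <- 100
  spec <- grid_spec(n, 1, seed = 1)
  types <- make_types(rep("recult_only", n), spec)
  prod <- seq(1e6, 2e7, length.out = n)
  sf <- make_surfaces(prod, rep(1, n), rep(0, n), spec)
  fr <- c(0.1, 0.5, 1)
  pri <- fraction_sweep(types, sf, "recultivate", fr, "prioritized",
                        F_max = 1, C_max = 1)
  up <- vapply(1:20, function(seed) {
    rnd <- fraction_sweep(types, sf, "recultivate", fr, "randomized",
                          seed = seed, F_max = 1, C_max = 1)
    prioritization_benefit(pri, rnd)$uplift_F_pct
  }, numeric(3))
  mean_up <- rowMeans(up)
  expect_gt(mean_up[1], mean_up[2])
  expect_gt(mean_up[2], mean_up[3])
  expect_equal(mean_up[3], 0)
})
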