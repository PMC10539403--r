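years <- 1992:2020

test_that("the FAO fallow rule classifies canonical trajectories", {
  cls <- rbind(
    trajectory(years, 2010, GRASS),                  # abandoned to end
    trajectory(years, 2010, GRASS, until = 2015),    # recultivated 2016
    rep(CROP, length(years)),                        # stable cropland
    rep(GRASS, length(years)),                       # never cropland
    trajectory(years, 2010, BUILT),                  # settlement conversion
    trajectory(years, 2018, GRASS),                  # too recent: 3-yr run
    trajectory(years, 2000, SHRUB, until = 2002)     # short-term fallow only
  )
  map <- detect_abandonment(make_series(cls))
  expect_identical(as.character(map$status),
                   c("abandoned", "recultivated_excluded", "stable_cropland",
                     "never_cropland", "converted_excluded",
                     "stable_cropland", "stable_cropland"))
  expect_identical(map$abandon_year[1], 2010L)
  expect_identical(map$fallow_run_length[1], 11L)
  expect_true(all(is.na(map$abandon_year[-1])))
})

test_that("excluded destinations dominate even after an abandonment-like run", {
  # grass run then drifts into built-up: settlement conversion wins
  cls <- rbind(
    ifelse(years < 2005, CROP, ifelse(years < 2015, GRASS, BUILT)),
    ifelse(years < 2005, CROP, ifelse(years < 2015, GRASS, WETLAND))
  )
  map <- detect_abandonment(make_series(cls))
  expect_true(all(map$status == "converted_excluded"))
})

test_that("both cropland codes count as cropland before the rules", {
  # alternating cropland types through the stable window, then grass
  cls <- matrix(ifelse(years < 2010,
                       ifelse(years %% 2 == 0, CROP, CROP2), GRASS),
                nrow = 1)
  map <- detect_abandonment(make_series(cls))
  expect_identical(as.character(map$status), "abandoned")
})

test_that("recultivation presence follows the fallow-then-cropland rule", {
  cls <- rbind(
    trajectory(years, 2010, GRASS, until = 2015),   # 6-yr run, crop after
    trajectory(years, 2010, GRASS),                 # abandoned to end
    trajectory(years, 2010, GRASS, until = 2012),   # 3-yr run only
    rep(CROP, length(years))
  )
  pres <- detect_recultivation_presence(make_series(cls))
  expect_identical(pres, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("noise-free detection reproduces the generator's event table exactly", {
  spec <- grid_spec(60, 60, seed = 9)
  s <- generate_landcover_series(spec, p_abandon = 0.15, p_recult = 0.2,
                                 p_convert = 0.03, noise_rate = 0)
  map <- detect_abandonment(temporal_filter(s, 5))
  expect_identical(as.character(map$status), truth_as_status(s$truth))
  ab <- s$truth$status == "abandoned"
  expect_identical(map$abandon_year[ab], s$truth$abandon_year[ab])
  expect_identical(map$fallow_run_length[ab], s$truth$fallow_run_length[ab])
  # recultivation presence layer matches injected recultivations
  pres <- detect_recultivation_presence(temporal_filter(s, 5))
  expect_identical(pres, s$truth$status == "recultivated")
})

test_that("statuses partition the pixels", {
  spec <- grid_spec(40, 40, seed = 17)
  s <- generate_landcover_series(spec, p_abandon = 0.2, p_recult = 0.2,
                                 noise_rate = 0.03)
  map <- detect_abandonment(temporal_filter(s, 5))
  expect_false(any(is.na(map$status)))
  expect_identical(sum(table(map$status)), n_pixels(spec))
  # abandon_year set iff abandoned; fallow run honours the minimum
  ab <- map$status == "abandoned"
  expect_identical(!is.na(map$abandon_year), ab)
  expect_true(all(map$fallow_run_length[ab] >= 5))
})

test_that("abandoned pixels never revisit cropland or excluded classes after the break", {
  spec <- grid_spec(40, 40, seed = 23)
  s <- generate_landcover_series(spec, p_abandon = 0.2, p_recult = 0.1,
                                 noise_rate = 0.03)
  f <- temporal_filter(s, 5)
  agg <- aggregate_cropland(f)
  map <- detect_abandonment(f)
  excl <- agg$codebook$code[agg$codebook$class %in% c("built_up", "wetland")]
  for (p in which(map$status == "abandoned")) {
    tail_classes <- agg$classes[p, agg$years >= map$abandon_year[p]]
    expect_false(any(tail_classes == 1L))
    expect_false(any(tail_classes %in% excl))
  }
})

test_that("raising the fallow requirement never adds abandoned pixels", {
  spec <- grid_spec(50, 50, seed = 31)
  s <- generate_landcover_series(spec, p_abandon = 0.25, p_recult = 0.15,
                                 noise_rate = 0)
  f <- temporal_filter(s, 5)
  counts <- vapply(4:9, function(mf) {
    sum(detect_abandonment(
      f, abandonment_params(min_fallow_years = mf))$status == "abandoned")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the temporal filter improves noisy event recovery", {
  for (seed in c(101, 202, 303)) {
    spec <- grid_spec(50, 50, seed = seed)
    s <- generate_landcover_series(spec, p_abandon = 0.15, p_recult = 0.1,
                                   noise_rate = 0.03)
    truth_ab <- s$truth$status == "abandoned"
    f1_of <- function(series) {
      got <- detect_abandonment(series)$status == "abandoned"
      tp <- sum(got & truth_ab)
      if (tp == 0) return(0)
      ua <- tp / sum(got)
      pa <- tp / sum(truth_ab)
      2 * ua * pa / (ua + pa)
    }
    expect_gt(f1_of(temporal_filter(s, 5)), f1_of(s))
  }
})

test_that("abandonment rate is area over period length", {
  expect_equal(area_rate(101, 1992, 2020), 101 / 28)
  expect_equal(round(area_rate(101, 1992, 2020), 1), 3.6)
  expect_equal(area_rate(28, 1992, 2020), 1)
  expect_error(area_rate(10, 2000, 2000), "zero-length")

  # empty map and a map-based rate agree with the pixel ledger
  spec <- grid_spec(10, 10, seed = 2)
  s <- generate_landcover_series(spec, p_abandon = 0, p_recult = 0,
                                 noise_rate = 0)
  map <- detect_abandonment(temporal_filter(s, 5))
  expect_equal(abandonment_rate(map), 0)
})
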