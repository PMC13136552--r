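test_that("carbon cost is mass times carbon fraction, inputs validated", {
  expect_identical(carbon_cost(10, 0.5), 5)
  expect_identical(carbon_cost(10, 0.4), 4)
  expect_error(carbon_cost(0, 0.5), "positive")
  expect_error(carbon_cost(10, 1), "0, 1")
})

test_that("amortisation matches closed forms", {
  ab <- const_branch_series(1)
  expect_identical(amortisation_time(ab, 0, as.Date("2021-04-25"))$days, 0L)
  am <- amortisation_time(ab, 30, as.Date("2021-04-25"))
  expect_identical(am$days, 30L)
  expect_false(am$never_amortised)
  # cost falling exactly on a day boundary counts that day
  expect_identical(amortisation_time(ab, 1, as.Date("2021-04-25"))$days, 1L)
  expect_error(amortisation_time(ab, -1, as.Date("2021-04-25")), "nonnegative")
})

test_that("amortisation agrees exactly with a brute-force cumulative scan", {
  set.seed(31)
  for (i in 1:100) {
    peak <- runif(1, 0.2, 2)
    ab <- seasonal_branch_series(peak = peak, winter = runif(1, -0.2, 0))
    start <- as.Date("2021-01-01") + sample(90:200, 1)
    cost <- runif(1, 0, 1.5) * sum(pmax(ab$value, 0))
    allow_loop <- i %% 2 == 0
    got <- amortisation_time(ab, cost, start, allow_loop = allow_loop)
    want <- oracle_amortisation(ab$value, match(start, ab$date), cost,
                                allow_loop)
    if (is.na(want)) expect_true(got$never_amortised)
    else expect_identical(got$days, as.integer(want))
  }
})

test_that("looping past the year end re-uses the same annual series", {
  # uptake only in autumn before the start date: looping is required
  dates <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  vals <- ifelse(format(dates, "%m") %in% c("03", "04"), 1, 0)
  ab <- assimilation_series(dates, vals, basis = "branch", leaf_area = 1)
  no_loop <- amortisation_time(ab, 10, as.Date("2021-06-01"))
  expect_true(no_loop$never_amortised)
  looped <- amortisation_time(ab, 10, as.Date("2021-06-01"), allow_loop = TRUE)
  expect_false(looped$never_amortised)
  expect_identical(looped$looped_years, 1L)
  # oracle agreement on the looped path
  want <- oracle_amortisation(ab$value, match(as.Date("2021-06-01"), ab$date),
                              10, TRUE)
  expect_identical(looped$days, as.integer(want))
  # a carbon-negative branch hits the loop cap
  neg <- const_branch_series(-0.01)
  capped <- amortisation_time(neg, 5, as.Date("2021-06-01"), allow_loop = TRUE)
  expect_true(capped$never_amortised)
})

test_that("amortisation time is nondecreasing in cost", {
  ab <- seasonal_branch_series(peak = 1.5)
  start <- as.Date("2021-04-25")
  costs <- seq(0, 60, by = 5)
  days <- sapply(costs, function(cc)
    amortisation_time(ab, cc, start, allow_loop = TRUE)$days)
  expect_true(all(diff(days) >= 0))
})

test_that("RCC follows its closed forms over the deciduous window", {
  ab <- const_branch_series(1)
  win <- list(type = "deciduous", start = as.Date("2021-04-25"),
              end = as.Date("2021-04-25") + 199)  # 200 days inclusive
  r <- relative_carbon_cost(ab, 30, win)
  expect_equal(r$rcc_pct, 15)
  expect_equal(r$lifetime_uptake_g, 200)
  expect_equal(relative_carbon_cost(ab, 200, win)$rcc_pct, 100)
  # linear in cost; halves when the series doubles
  expect_equal(relative_carbon_cost(ab, 60, win)$rcc_pct, 30)
  doubled <- assimilation_series(ab$date, ab$value * 2, basis = "branch",
                                 leaf_area = 1)
  expect_equal(relative_carbon_cost(doubled, 30, win)$rcc_pct, 7.5)
  # endpoints inclusive: a one-day window sums exactly that day
  one_day <- list(type = "deciduous", start = as.Date("2021-06-01"),
                  end = as.Date("2021-06-01"))
  expect_equal(relative_carbon_cost(ab, 1, one_day)$rcc_pct, 100)
})

test_that("evergreen RCC denominator spans lifespan_years looped annual cycles", {
  ab <- seasonal_branch_series(peak = 1)
  annual <- sum(ab$value)
  win <- list(type = "evergreen", start = as.Date("2021-05-03"),
              lifespan_years = 5L)
  r <- relative_carbon_cost(ab, 10, win)
  expect_equal(r$lifetime_uptake_g, 5 * annual, tolerance = 1e-12)
  expect_equal(r$rcc_pct, 100 * 10 / (5 * annual))
  win3 <- list(type = "evergreen", start = as.Date("2021-05-03"),
               lifespan_years = 3L)
  expect_equal(relative_carbon_cost(ab, 10, win3)$lifetime_uptake_g,
               3 * annual, tolerance = 1e-12)
})

test_that("a carbon-negative branch flags RCC as undefined", {
  neg <- const_branch_series(-0.01)
  win <- list(type = "deciduous", start = as.Date("2021-04-25"),
              end = as.Date("2021-10-25"))
  r <- relative_carbon_cost(neg, 5, win)
  expect_true(r$undefined)
  expect_true(is.na(r$rcc_pct))
})

test_that("branch evaluation composes costs, amortisation and RCC coherently", {
  dates <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  an <- assimilation_series(dates, rep(2, length(dates)), basis = "leaf_area")
  rec <- branch_record("t1", "sp", "sun", leaf_area_m2 = 0.25,
                       leaf_mass_g = 10, twig_mass_g = 5, leaf_c_frac = 0.48,
                       twig_c_frac = 0.48, budbreak = as.Date("2021-04-25"),
                       discoloration = as.Date("2021-10-25"),
                       habit = "deciduous")
  res <- evaluate_branch(rec, an)
  # A_Branch = 0.5 g/d; C_F = 4.8 -> 10 days; C_F + C_T = 7.2 -> 15 days
  expect_identical(res$leaf_amortisation_days, 10L)
  expect_identical(res$total_amortisation_days, 15L)
  expect_gte(res$total_amortisation_days, res$leaf_amortisation_days)
  # RCC over 184 inclusive days at 0.5 g/d = 92 g lifetime uptake
  expect_equal(res$lifetime_uptake_g, 92)
  expect_equal(res$total_rcc_pct, 100 * 7.2 / 92)
  expect_equal(res$leaf_rcc_pct + res$twig_rcc_pct, res$total_rcc_pct)

  # identical inputs -> identical result (pure function)
  expect_identical(res, evaluate_branch(rec, an))

  # doubling leaf area at fixed costs weakly shortens amortisation
  rec2 <- rec
  rec2$leaf_area_m2 <- 0.5
  res2 <- evaluate_branch(rec2, an)
  expect_lte(res2$leaf_amortisation_days, res$leaf_amortisation_days)
  expect_lte(res2$total_amortisation_days, res$total_amortisation_days)

  # vanishing twig mass: total amortisation approaches leaf amortisation
  rec3 <- rec
  rec3$twig_mass_g <- 1e-9
  res3 <- evaluate_branch(rec3, an)
  expect_identical(res3$total_amortisation_days, res3$leaf_amortisation_days)
})

test_that("branch record validation enforces phenology and habit rules", {
  bb <- as.Date("2021-04-25")
  expect_error(
    branch_record("t", "s", "sun", 0.1, 5, 3, 0.5, 0.5, bb, bb - 1,
                  habit = "deciduous"),
    "discoloration")
  expect_error(
    branch_record("t", "s", "sun", 0.1, 5, 3, 0.5, 0.5, bb,
                  habit = "evergreen"),
    "lifespan_years")
  expect_s3_class(
    branch_record("t", "s", "sun", 0.1, 5, 3, 0.5, 0.5, bb,
                  habit = "evergreen", lifespan_years = 5),
    "branch_record")
})
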