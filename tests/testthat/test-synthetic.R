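test_that("light series have one value per 15-min step of the calendar year", {
  sc <- scenario_config(seed = 3, year = 2021)
  sun <- generate_light_series(sc, "broadleaf", "sun")
  expect_identical(nrow(sun), 35040L)
  leap <- scenario_config(seed = 3, year = 2020)
  expect_identical(nrow(generate_light_series(leap, "broadleaf", "sun")),
                   35136L)
  expect_true(all(sun$ppfd >= 0))
  # night steps are exactly zero (solar elevation below horizon)
  hours <- as.numeric(format(sun$timestamp, "%H"))
  expect_true(all(sun$ppfd[hours %in% c(0, 1, 2, 23)] == 0))
  expect_true(any(sun$ppfd > 0))
})

test_that("shade equals relative irradiance times sun when sensor noise is off", {
  sc <- scenario_config(seed = 4)
  sun <- generate_light_series(sc, "broadleaf", "sun")
  shade <- generate_light_series(sc, "broadleaf", "shade")
  expect_equal(shade$ppfd, 0.3 * sun$ppfd, tolerance = 1e-12)
  day <- sun$ppfd > 0
  expect_equal(mean(shade$ppfd[day] / sun$ppfd[day]), 0.3, tolerance = 0.01)

  # RI = 1 with no noise reproduces the sun series identically
  sp <- default_species_params()
  sp$broadleaf$ri <- 1
  sc1 <- scenario_config(seed = 4, species = sp)
  expect_identical(generate_light_series(sc1, "broadleaf", "shade")$ppfd,
                   generate_light_series(sc1, "broadleaf", "sun")$ppfd)

  # multiplicative noise preserves the ratio in expectation
  scn <- scenario_config(seed = 4, light_noise_sd = 0.2)
  shaden <- generate_light_series(scn, "broadleaf", "shade")
  expect_equal(mean(shaden$ppfd[day] / sun$ppfd[day]), 0.3, tolerance = 0.01)
})

test_that("generators are bit-identical under a fixed seed and differ across seeds", {
  sc <- scenario_config(seed = 11)
  expect_identical(generate_light_series(sc, "conifer", "sun"),
                   generate_light_series(sc, "conifer", "sun"))
  expect_identical(generate_temperature_series(sc),
                   generate_temperature_series(sc))
  expect_identical(generate_branch_records(sc), generate_branch_records(sc))
  sc2 <- scenario_config(seed = 12)
  expect_false(identical(generate_light_series(sc2, "conifer", "sun")$ppfd,
                         generate_light_series(sc, "conifer", "sun")$ppfd))
  expect_false(identical(generate_temperature_series(sc2)$temp_c,
                         generate_temperature_series(sc)$temp_c))
})

test_that("generators leave the caller's RNG state untouched", {
  sc <- scenario_config(seed = 11)
  set.seed(99)
  before <- .Random.seed
  invisible(generate_light_series(sc, "conifer", "sun"))
  invisible(generate_temperature_series(sc))
  expect_identical(.Random.seed, before)
})

test_that("temperature series follow the calendar and degenerate cleanly", {
  sc <- scenario_config(seed = 5)
  temp <- generate_temperature_series(sc)
  expect_identical(nrow(temp), 8760L)
  leap <- scenario_config(seed = 5, year = 2020)
  expect_identical(nrow(generate_temperature_series(leap)), 8784L)
  # zero amplitudes and noise give a constant series at the configured mean
  flat <- scenario_config(seed = 5, mean_temp = 15,
                          temp_seasonal_amplitude = 0,
                          temp_diurnal_amplitude = 0, temp_noise_sd = 0)
  expect_identical(unique(generate_temperature_series(flat)$temp_c), 15)
  # default annual mean tracks the site-climatology configuration value
  expect_equal(mean(temp$temp_c), 9.6, tolerance = 0.1)
})

test_that("noiseless gas-exchange observations satisfy the model exactly", {
  truth <- canonical_lrc()
  levels <- c(0, 50, 200, 800, 1500)
  obs <- generate_lrc_observations(truth, levels, 0)
  expect_identical(obs$pn, predict_net_photosynthesis(levels, truth))
  expect_identical(obs$pn[1], -truth$rd)
  expect_equal(obs$pn[5], truth$pgmax - truth$rd, tolerance = 1e-3)
  expect_identical(attr(obs, "true_params"), truth)
  expect_warning(generate_lrc_observations(truth, c(0, 100), 0),
                 "underdetermined")
})

test_that("branch records respect the configured morphology identities", {
  sc <- scenario_config(seed = 8, n_trees = 4)
  recs <- generate_branch_records(sc)
  expect_length(recs, 2 * 2 * 4)  # species x positions x trees
  for (r in recs) {
    expect_gt(r$leaf_area_m2, 0)
    expect_gt(r$twig_mass_g, 0)
    expect_true(r$leaf_c_frac > 0 && r$leaf_c_frac < 1)
  }
  # trees differ in morphology ratios, not just in scale
  broad_sun <- Filter(function(r) r$species == "broadleaf" &&
                        r$position == "sun", recs)
  slas <- sapply(broad_sun, function(r) r$leaf_area_m2 / r$leaf_mass_g)
  expect_gt(length(unique(round(slas, 9))), 1L)
})

test_that("invalid scenario configurations are rejected", {
  sp <- default_species_params()
  sp$broadleaf$ri <- 0
  expect_error(scenario_config(species = sp), "relative irradiance")
  sp <- default_species_params()
  sp$broadleaf$leaf_c_frac_sun <- 1.2
  expect_error(scenario_config(species = sp), "C fractions")
  sp <- default_species_params()
  sp$broadleaf$discoloration_shade <- sp$broadleaf$budbreak_shade - 1
  expect_error(scenario_config(species = sp), "budbreak")
  # starch window must fall inside the scenario year
  sp <- default_species_params()
  sp$broadleaf$starch_buildup_days <- 300
  sc <- scenario_config(species = sp)
  expect_error(generate_starch_dynamics(sc, "broadleaf", "sun"),
               "outside the scenario year")
})
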