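test_that("lux to PPFD conversion is the sensor relationship", {
  expect_identical(lux_to_ppfd(120), 1)
  expect_identical(lux_to_ppfd(0), 0)
  expect_identical(lux_to_ppfd(1200), 10)
  expect_error(lux_to_ppfd(-1), "nonnegative")
})

test_that("temperature multiplier matches the broad-optimum trapezoid", {
  # anchor values and derived interpolations
  expect_equal(temperature_multiplier(c(-2, 4, 10, 20, 30, 36, 42)),
               c(0, 0.5, 1, 1, 1, 0.5, 0))
  # zero outside the viable range, bounded in [0, 1], continuous/piecewise linear
  expect_equal(temperature_multiplier(c(-40, -2.0001, 42.0001, 60)),
               c(0, 0, 0, 0), tolerance = 1e-3)
  tt <- seq(-10, 50, by = 0.25)
  m <- temperature_multiplier(tt)
  expect_true(all(m >= 0 & m <= 1))
  # slopes are constant within each linear segment
  ramp_up <- temperature_multiplier(seq(-2, 10, by = 0.5))
  expect_equal(diff(ramp_up), rep(0.5 / 12, 24))
})

test_that("Q10 respiration correction follows the exact exponential law", {
  expect_identical(correct_respiration(1, 25), 1)
  expect_identical(correct_respiration(1, 35), 2)
  expect_identical(correct_respiration(1, 15), 0.5)
  set.seed(5)
  temps <- runif(50, -20, 45)
  expect_equal(correct_respiration(1.7, temps + 10),
               2 * correct_respiration(1.7, temps))
  r3 <- correct_respiration(1, 35, q10 = 3)
  expect_identical(r3, 3)
})

test_that("sub-daily series composes light response and temperature correction", {
  p <- canonical_lrc()
  # dark at 25 C: net is exactly -Rd every step
  sub <- compute_subdaily_series(flat_light(0), flat_temp(25), p)
  expect_equal(sub$net, rep(-1, 96))
  # freezing day: multiplier 0, only Q10-corrected respiration remains
  sub <- compute_subdaily_series(flat_light(800), flat_temp(-5), p)
  expect_equal(sub$pg, rep(0, 96))
  expect_equal(sub$net, rep(-2^((-5 - 25) / 10), 96))
  # hand-composed single value: I=200, T=20
  sub <- compute_subdaily_series(flat_light(200), flat_temp(20), p)
  expect_equal(sub$net[1], 6.3212056 * 1 - 2^(-0.5), tolerance = 1e-6)
  # uncovered timesteps raise a gap error naming dates
  short_temp <- flat_temp(20)
  short_temp <- temperature_series(short_temp$timestamp[1:12],
                                   short_temp$temp_c[1:12])
  expect_error(compute_subdaily_series(flat_light(200), short_temp, p),
               "uncovered date")
})

test_that("hourly temperature is applied as a step function within each hour", {
  p <- canonical_lrc()
  temp <- flat_temp(25)
  temp$temp_c <- seq(0, 23)  # a different temperature each hour
  sub <- compute_subdaily_series(flat_light(0), temp, p)
  expect_equal(sub$temp_c, rep(0:23, each = 4))
})

test_that("daily integration matches its closed forms and a step-sum oracle", {
  p <- canonical_lrc()
  # net == -1 umol m-2 s-1 around the clock
  sub <- compute_subdaily_series(flat_light(0), flat_temp(25), p)
  an <- daily_net_assimilation(sub)
  expect_equal(an$value, -1.0368, tolerance = 1e-12)
  # net == +2 for 12 h, 0 for 12 h
  sub2 <- data.frame(timestamp = flat_light(0)$timestamp,
                     net = rep(c(2, 0), each = 48))
  expect_equal(daily_net_assimilation(sub2)$value, 1.0368, tolerance = 1e-12)
  # brute-force oracle: accumulate gram increments step by step
  set.seed(11)
  for (rep_i in 1:10) {
    nets <- rnorm(96 * 3, sd = 4)
    sub3 <- data.frame(timestamp = flat_light(0, days = 3)$timestamp, net = nets)
    got <- daily_net_assimilation(sub3)$value
    oracle <- sapply(0:2, function(d) {
      total <- 0
      for (k in 1:96) total <- total + nets[d * 96 + k] * 900 * 12e-6
      total
    })
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("partial days are excluded with a warning, never extrapolated", {
  t0 <- as.POSIXct("2021-06-01 12:00:00", tz = "UTC")
  sub <- data.frame(timestamp = t0 + 900 * (0:(96 + 47)), net = 1)
  expect_warning(an <- daily_net_assimilation(sub), "partial day")
  expect_identical(nrow(an), 1L)
  expect_equal(an$date, as.Date("2021-06-02"))
})

test_that("averaging is a pointwise mean over aligned series", {
  a <- const_branch_series(1)
  b <- const_branch_series(3)
  expect_equal(average_assimilation(list(a))$value, a$value)
  expect_equal(average_assimilation(list(a, b))$value, rep(2, nrow(a)))
  expect_equal(average_assimilation(list(a, a, a))$value, a$value)
  shifted <- assimilation_series(a$date + 1, a$value, basis = "branch",
                                 leaf_area = 1)
  expect_error(average_assimilation(list(a, shifted)), "mismatched dates")
})

test_that("branch scaling is linear in leaf area", {
  dates <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  an <- assimilation_series(dates, rep(2, length(dates)), basis = "leaf_area")
  expect_equal(branch_assimilation(an, 1)$value, an$value)
  expect_equal(branch_assimilation(an, 0.25)$value, rep(0.5, length(dates)))
  expect_equal(branch_assimilation(an, 2)$value,
               2 * branch_assimilation(an, 1)$value)
  expect_error(branch_assimilation(an, 0), "positive")
})

test_that("more light never yields less daily assimilation", {
  p <- canonical_lrc()
  temp <- flat_temp(18, days = 4)
  set.seed(23)
  base <- runif(96 * 4, 0, 1200)
  l1 <- light_series(flat_light(0, days = 4)$timestamp, base)
  l2 <- light_series(l1$timestamp, base * runif(96 * 4, 0.2, 1))
  an1 <- daily_net_assimilation(compute_subdaily_series(l1, temp, p))
  an2 <- daily_net_assimilation(compute_subdaily_series(l2, temp, p))
  expect_true(all(an1$value >= an2$value))
})

test_that("alternative temperature responses preserve the structural identities", {
  # a narrower optimum changes A_N but not the anchor/Q10/integration identities
  p <- canonical_lrc()
  alt <- c(0, 15, 25, 38)
  expect_equal(temperature_multiplier(alt, anchors = alt), c(0, 1, 1, 0))
  sub_def <- compute_subdaily_series(flat_light(500), flat_temp(12), p)
  sub_alt <- compute_subdaily_series(flat_light(500), flat_temp(12), p,
                                     anchors = alt)
  expect_false(isTRUE(all.equal(sub_def$net, sub_alt$net)))
  expect_equal(sub_alt$pg - (sub_alt$net + sub_alt$rd), rep(0, 96))
})
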