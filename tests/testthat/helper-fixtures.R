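# Shared fixtures, all built in code at test time.

# A one-year daily branch-basis assimilation series with a given value pattern.
const_branch_series <- function(value, year = 2021, leaf_area = 1) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  assimilation_series(dates, rep(value, length(dates)), basis = "branch",
                      leaf_area = leaf_area)
}

# A smooth seasonal daily branch series: peak mid-year, negative in winter.
seasonal_branch_series <- function(peak = 1, winter = -0.05, year = 2021,
                                   leaf_area = 1) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  doy <- as.numeric(format(dates, "%j"))
  shape <- pmax(0, sin(pi * (doy - 100) / 180))  # >0 roughly Apr-Sep
  vals <- winter + (peak - winter) * shape
  assimilation_series(dates, vals, basis = "branch", leaf_area = leaf_area)
}

# Tiny flat light/temperature fixtures covering n complete days.
flat_light <- function(ppfd, days = 1, year = 2021) {
  t0 <- as.POSIXct(sprintf("%d-06-01 00:00:00", year), tz = "UTC")
  light_series(t0 + 900 * (seq_len(96 * days) - 1), rep(ppfd, 96 * days))
}

flat_temp <- function(temp_c, days = 1, year = 2021) {
  t0 <- as.POSIXct(sprintf("%d-06-01 00:00:00", year), tz = "UTC")
  temperature_series(t0 + 3600 * (seq_len(24 * days) - 1),
                     rep(temp_c, 24 * days))
}

# Independent brute-force cumulative-scan amortisation oracle: walks the
# looped daily series one day at a time.
oracle_amortisation <- function(values, start_idx, cost, allow_loop,
                                max_loops = 10) {
  if (cost == 0) return(0L)
  total <- 0
  day <- 0L
  i <- start_idx
  n <- length(values)
  loops <- 0L
  repeat {
    if (i > n) {
      if (!allow_loop) return(NA_integer_)
      loops <- loops + 1L
      if (loops > max_loops) return(NA_integer_)
      i <- 1L
    }
    total <- total + values[i]
    day <- day + 1L
    if (total >= cost) return(day)
    i <- i + 1L
  }
}

canonical_lrc <- function() lrc_params(pgmax = 10, rd = 1, phi0 = 0.05)

# Calibrated default scenario used by the end-to-end checks.
demo_scenario <- function(seed = 1) scenario_config(seed = seed)

# Scenario with no sun/shade contrast at all (RI = 1, identical traits).
no_contrast_scenario <- function(seed = 1) {
  sp <- default_species_params()
  for (nm in names(sp)) {
    s <- sp[[nm]]
    s$ri <- 1
    for (f in c("lrc", "sla", "leaf_mass", "la_bdw", "leaf_c_frac",
                "twig_c_frac", "budbreak", "discoloration",
                "needle_mass_1yr", "starch_amplitude")) {
      s[[paste0(f, "_shade")]] <- s[[paste0(f, "_sun")]]
    }
    sp[[nm]] <- s
  }
  scenario_config(seed = seed, lrc_noise_sd = 0, species = sp)
}

# Species-mean branch_inputs pair (shade, sun) for one scenario species,
# using the true LRC parameters (no fitting noise).
mean_inputs_pair <- function(scenario, species_name) {
  sp <- scenario$species[[species_name]]
  make <- function(pos) {
    tr <- sp[[paste0("lrc_", pos)]]
    branch_inputs(
      light = generate_light_series(scenario, species_name, pos),
      lrc = lrc_params(tr[["pgmax"]], tr[["rd"]], tr[["phi0"]]),
      sla_m2_kg = sp[[paste0("sla_", pos)]],
      leaf_mass_g = sp[[paste0("leaf_mass_", pos)]],
      la_bdw_m2_kg = sp[[paste0("la_bdw_", pos)]],
      leaf_c_frac = sp[[paste0("leaf_c_frac_", pos)]],
      twig_c_frac = sp[[paste0("twig_c_frac_", pos)]],
      budbreak = sp[[paste0("budbreak_", pos)]],
      discoloration = sp[[paste0("discoloration_", pos)]],
      habit = sp$habit, lifespan_years = sp$lifespan_years,
      species = species_name, position = pos
    )
  }
  list(shade = make("shade"), sun = make("sun"))
}
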