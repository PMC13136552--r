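# Synthetic scenario generator: every input the pipeline consumes, with known
# ground truth. Emulates the structure the analysis assumes (diurnal/seasonal
# light with multiplicative shade attenuation, seasonal temperature,
# model-generated gas-exchange points, sun/shade trait contrasts, seasonal
# starch dynamics) -- it is a statistical stand-in, not a site model.

# Independent, reproducible RNG substream per generator stage. The global RNG
# state is saved and restored so generators never perturb user code.
stream_seed <- function(seed, id) {
  ints <- utf8ToInt(id)
  h <- sum(ints * seq_along(ints))
  as.integer((abs(as.numeric(seed)) * 31 + h * 131 + 7) %% 2147483629)
}

with_stream <- function(seed, id, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(stream_seed(seed, id))
  expr
}

md_date <- function(year, month, day) as.Date(sprintf("%d-%02d-%02d", year, month, day))

#' Default synthetic species parameter sets
#'
#' Two contrasting species emulating the trait structure of temperate
#' canopies: a deciduous broadleaf (beech-like) and an evergreen conifer
#' (spruce-like, 5-year needle lifespan). Contrasts follow the typical
#' sun/shade acclimation pattern: shade branches receive a fixed fraction of
#' top-of-crown light (relative irradiance ~0.2-0.3), have lower Pgmax and
#' dark respiration, slightly higher quantum yield, and roughly double the
#' SLA (conifers adjust SLA much less).
#'
#' @param year Calendar year used to place phenology dates.
#' @return Named list of per-species parameter lists.
#' @export
default_species_params <- function(year = 2021) {
  list(
    broadleaf = list(
      name = "broadleaf", habit = "deciduous", ri = 0.30,
      lrc_sun = c(pgmax = 14, rd = 1.5, phi0 = 0.045),
      lrc_shade = c(pgmax = 10, rd = 0.7, phi0 = 0.055),
      sla_sun = 10, sla_shade = 25,            # m2 kg-1
      leaf_mass_sun = 8, leaf_mass_shade = 4,  # g per current-year branch
      la_bdw_sun = 20, la_bdw_shade = 40,      # m2 kg-1
      leaf_c_frac_sun = 0.49, leaf_c_frac_shade = 0.48,
      twig_c_frac_sun = 0.48, twig_c_frac_shade = 0.475,
      budbreak_sun = md_date(year, 4, 22), budbreak_shade = md_date(year, 4, 25),
      discoloration_sun = md_date(year, 10, 28),
      discoloration_shade = md_date(year, 10, 25),
      lifespan_years = NA_integer_,
      needle_mass_1yr_sun = NA_real_, needle_mass_1yr_shade = NA_real_,
      starch_amplitude_sun = 0.03, starch_amplitude_shade = 0.03,
      starch_buildup_days = 60
    ),
    conifer = list(
      name = "conifer", habit = "evergreen", ri = 0.20,
      lrc_sun = c(pgmax = 10, rd = 1.3, phi0 = 0.040),
      lrc_shade = c(pgmax = 7, rd = 0.6, phi0 = 0.050),
      sla_sun = 4, sla_shade = 6,
      leaf_mass_sun = 10, leaf_mass_shade = 8,
      la_bdw_sun = 8, la_bdw_shade = 10,
      leaf_c_frac_sun = 0.51, leaf_c_frac_shade = 0.50,
      twig_c_frac_sun = 0.50, twig_c_frac_shade = 0.495,
      budbreak_sun = md_date(year, 5, 3), budbreak_shade = md_date(year, 5, 6),
      discoloration_sun = as.Date(NA), discoloration_shade = as.Date(NA),
      lifespan_years = 5L,
      needle_mass_1yr_sun = 9, needle_mass_1yr_shade = 7,
      starch_amplitude_sun = 0.10, starch_amplitude_shade = 0.10,
      starch_buildup_days = 40
    )
  )
}

#' Synthetic scenario configuration
#'
#' Defines one self-contained study scenario: calendar year, site geometry
#' (latitude for the solar-elevation light model), climate parameters, noise
#' levels, replication, and per-species sun/shade trait contrasts.
#'
#' @param seed Integer seed from which every generator substream is derived.
#' @param year Calendar year (leap years supported; series lengths follow
#'   the calendar).
#' @param latitude Site latitude in degrees north, used for day length and
#'   solar elevation.
#' @param ppfd_max Top-of-crown PPFD at solar elevation 90 degrees under a
#'   clear sky, µmol m^-2 s^-1; the default 1600 folds sensor orientation
#'   and within-crown self-shading into the clear-sky maximum.
#' @param cloud_median,cloud_sd Median and log-scale SD of the per-day
#'   cloudiness multiplier (log-normal, capped at 1; applied equally to sun
#'   and shade, which share the same sky).
#' @param light_noise_sd Log-scale SD of the multiplicative, mean-1 sensor
#'   noise on the shade series; 0 (default) keeps the shade/sun ratio
#'   exactly at the configured relative irradiance.
#' @param mean_temp,temp_seasonal_amplitude,temp_diurnal_amplitude,temp_noise_sd
#'   Hourly temperature model, degrees C: annual mean (default 9.6, a
#'   temperate-site climatology), seasonal and diurnal half-amplitudes, and
#'   iid Gaussian noise SD.
#' @param lrc_light_levels PPFD design for synthetic gas-exchange curves.
#' @param lrc_noise_sd Gaussian noise SD on synthetic P_N observations,
#'   µmol CO2 m^-2 s^-1.
#' @param n_trees Paired sun/shade branch records generated per species.
#' @param species Per-species parameter list; see [default_species_params()].
#' @return A list of class `scenario_config` (validated invariants:
#'   relative irradiance in (0, 1], positive masses, C fractions in (0, 1),
#'   budbreak before discoloration, non-empty starch windows).
#' @export
scenario_config <- function(seed = 1L, year = 2021L, latitude = 47.4,
                            ppfd_max = 1600, cloud_median = 0.5,
                            cloud_sd = 0.45, light_noise_sd = 0,
                            mean_temp = 9.6, temp_seasonal_amplitude = 9,
                            temp_diurnal_amplitude = 4, temp_noise_sd = 1.5,
                            lrc_light_levels = c(0, 25, 50, 100, 250, 500,
                                                 1000, 1500),
                            lrc_noise_sd = 0.3, n_trees = 5L,
                            species = default_species_params(year)) {
  if (year < 1900 || year > 2200) stop("invalid 'year'", call. = FALSE)
  if (abs(latitude) >= 66) stop("'latitude' must be below the polar circles",
                                call. = FALSE)
  for (sp in species) {
    if (!is.finite(sp$ri) || sp$ri <= 0 || sp$ri > 1)
      stop("relative irradiance must lie in (0, 1] (species '", sp$name, "')",
           call. = FALSE)
    masses <- c(sp$leaf_mass_sun, sp$leaf_mass_shade)
    if (any(!is.finite(masses)) || any(masses <= 0))
      stop("dry masses must be positive (species '", sp$name, "')",
           call. = FALSE)
    fr <- c(sp$leaf_c_frac_sun, sp$leaf_c_frac_shade,
            sp$twig_c_frac_sun, sp$twig_c_frac_shade)
    if (any(fr <= 0) || any(fr >= 1))
      stop("C fractions must lie in (0, 1) (species '", sp$name, "')",
           call. = FALSE)
    if (sp$habit == "deciduous" &&
        !(sp$budbreak_sun < sp$discoloration_sun &&
          sp$budbreak_shade < sp$discoloration_shade))
      stop("budbreak must precede discoloration (species '", sp$name, "')",
           call. = FALSE)
    if (!is.finite(sp$starch_buildup_days) || sp$starch_buildup_days < 1)
      stop("starch build-up window must be non-empty (species '", sp$name,
           "')", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), year = as.integer(year), latitude = latitude,
         ppfd_max = ppfd_max, cloud_median = cloud_median, cloud_sd = cloud_sd,
         light_noise_sd = light_noise_sd, mean_temp = mean_temp,
         temp_seasonal_amplitude = temp_seasonal_amplitude,
         temp_diurnal_amplitude = temp_diurnal_amplitude,
         temp_noise_sd = temp_noise_sd, lrc_light_levels = lrc_light_levels,
         lrc_noise_sd = lrc_noise_sd, n_trees = as.integer(n_trees),
         species = species),
    class = "scenario_config"
  )
}

days_in_year <- function(year) {
  as.integer(as.Date(sprintf("%d-12-31", year)) -
             as.Date(sprintf("%d-01-01", year))) + 1L
}

#' Generate a 15-min PPFD logger series
#'
#' Clear-sky irradiance follows the sine of solar elevation (declination
#' from day of year, hour angle from time of day, latitude from the config),
#' scaled by `ppfd_max` and by a per-day log-normal cloudiness multiplier.
#' The shade series is the sun series times the species' relative irradiance
#' and, optionally, multiplicative mean-1 log-normal sensor noise. Night
#' steps are exactly zero. Sun and shade share the identical cloud sequence,
#' so with zero sensor noise every shade value equals RI x the sun value.
#'
#' @param config A [scenario_config()].
#' @param species Species name in `config$species`.
#' @param position `"sun"` or `"shade"`.
#' @return A [light_series()] with one value per 15-min step of the year.
#' @export
generate_light_series <- function(config, species, position = c("sun", "shade")) {
  stopifnot(inherits(config, "scenario_config"))
  position <- match.arg(position)
  sp <- config$species[[species]]
  if (is.null(sp)) stop("unknown species '", species, "'", call. = FALSE)
  if (sp$ri <= 0) stop("relative irradiance must be positive", call. = FALSE)

  ndays <- days_in_year(config$year)
  n <- 96L * ndays
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", config$year), tz = "UTC")
  ts <- t0 + 900 * (seq_len(n) - 1)
  step <- seq_len(n) - 1L
  doy <- step %/% 96L + 1L
  hour <- (step %% 96L) / 4 + 0.125  # midpoint of the 15-min step

  lat <- config$latitude * pi / 180
  decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365.25)
  sinel <- sin(lat) * sin(decl) +
    cos(lat) * cos(decl) * cos(pi * (hour - 12) / 12)
  clear <- config$ppfd_max * pmax(sinel, 0)

  cloud <- with_stream(config$seed, paste0("light-", species), {
    pmin(1, stats::rlnorm(ndays, log(config$cloud_median), config$cloud_sd))
  })
  sun <- clear * cloud[doy]

  ppfd <- if (position == "sun") sun else {
    shade <- sp$ri * sun
    if (config$light_noise_sd > 0) {
      sd <- config$light_noise_sd
      noise <- with_stream(config$seed, paste0("shade-noise-", species), {
        stats::rlnorm(n, -sd^2 / 2, sd)  # mean exactly 1
      })
      shade <- shade * noise
    }
    shade
  }
  light_series(ts, ppfd, sensor = paste0(species, "-", position),
               species = species, position = position)
}

#' Generate an hourly air-temperature series
#'
#' Seasonal sinusoid (peak around day 200) plus a diurnal cycle (peak around
#' 14:00) plus iid Gaussian noise, all configurable; with both amplitudes
#' and the noise at zero the series is constant at `mean_temp`.
#'
#' @param config A [scenario_config()].
#' @return A [temperature_series()] with one value per hour of the year.
#' @export
generate_temperature_series <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  ndays <- days_in_year(config$year)
  n <- 24L * ndays
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", config$year), tz = "UTC")
  ts <- t0 + 3600 * (seq_len(n) - 1)
  hr <- seq_len(n) - 1L
  doy <- hr %/% 24L + 1L
  hod <- hr %% 24L
  temp <- config$mean_temp +
    config$temp_seasonal_amplitude * cos(2 * pi * (doy - 200) / 365.25) +
    config$temp_diurnal_amplitude * cos(2 * pi * (hod - 14) / 24)
  if (config$temp_noise_sd > 0) {
    temp <- temp + with_stream(config$seed, "temperature", {
      stats::rnorm(n, 0, config$temp_noise_sd)
    })
  }
  temperature_series(ts, temp)
}

#' Generate synthetic gas-exchange observations from known LRC parameters
#'
#' P_N observations are the exponential-model prediction at each light level
#' plus Gaussian noise; the generating parameters are retained as the
#' `true_params` attribute for recovery tests.
#'
#' @param true_params The generating [lrc_params()].
#' @param light_levels PPFD design points (nonnegative; at least 4 distinct
#'   levels recommended).
#' @param noise_sd Gaussian noise SD on P_N (>= 0).
#' @param species,position,curve_id Metadata labels.
#' @return A [gas_exchange_curve()] with attribute `true_params`.
#' @export
generate_lrc_observations <- function(true_params, light_levels, noise_sd = 0,
                                      species = NA_character_,
                                      position = NA_character_,
                                      curve_id = NA_character_) {
  stopifnot(inherits(true_params, "lrc_params"))
  if (any(light_levels < 0))
    stop("'light_levels' must be nonnegative", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative", call. = FALSE)
  if (length(unique(light_levels)) < 3L)
    warning("fewer than 3 distinct light levels: the 3-parameter fit is ",
            "underdetermined", call. = FALSE)
  pn <- predict_net_photosynthesis(light_levels, true_params)
  if (noise_sd > 0) pn <- pn + stats::rnorm(length(pn), 0, noise_sd)
  out <- gas_exchange_curve(light_levels, pn, species = species,
                            position = position, curve_id = curve_id)
  attr(out, "true_params") <- true_params
  out
}

#' Generate paired sun/shade branch records for each synthetic tree
#'
#' Per tree and crown position, the branch leaf dry mass (CV ~ 15%), SLA and
#' LA:BDW (CV ~ 8% each) vary log-normally and independently around the
#' species x position means; leaf area follows as leaf mass x SLA and twig
#' mass as leaf area / LA:BDW, so trees differ in both size and morphology
#' ratios.
#'
#' @param config A [scenario_config()].
#' @return A list of [branch_record()] objects (trees x species x positions).
#' @export
generate_branch_records <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  records <- list()
  for (sp in config$species) {
    jitter <- with_stream(config$seed, paste0("branch-", sp$name), {
      list(mass = matrix(stats::rlnorm(2L * config$n_trees, -0.15^2 / 2, 0.15),
                         nrow = config$n_trees),
           sla = matrix(stats::rlnorm(2L * config$n_trees, -0.08^2 / 2, 0.08),
                        nrow = config$n_trees),
           la_bdw = matrix(stats::rlnorm(2L * config$n_trees, -0.08^2 / 2, 0.08),
                           nrow = config$n_trees))
    })
    for (tree in seq_len(config$n_trees)) {
      for (k in 1:2) {
        pos <- c("sun", "shade")[k]
        leaf_mass <- sp[[paste0("leaf_mass_", pos)]] * jitter$mass[tree, k]
        leaf_area <- leaf_mass / 1000 *
          sp[[paste0("sla_", pos)]] * jitter$sla[tree, k]
        twig_mass <- leaf_area * 1000 /
          (sp[[paste0("la_bdw_", pos)]] * jitter$la_bdw[tree, k])
        records[[length(records) + 1L]] <- branch_record(
          tree_id = sprintf("%s-%02d", sp$name, tree),
          species = sp$name, position = pos,
          leaf_area_m2 = leaf_area, leaf_mass_g = leaf_mass,
          twig_mass_g = twig_mass,
          leaf_c_frac = sp[[paste0("leaf_c_frac_", pos)]],
          twig_c_frac = sp[[paste0("twig_c_frac_", pos)]],
          budbreak = sp[[paste0("budbreak_", pos)]],
          discoloration = sp[[paste0("discoloration_", pos)]],
          habit = sp$habit, lifespan_years = sp$lifespan_years
        )
      }
    }
  }
  records
}

#' Generate seasonal starch dynamics for one species x crown position
#'
#' Conifers accumulate starch in mature needles before budbreak: the window
#' ends at budbreak and starts `starch_buildup_days` earlier. Broadleaves
#' refill starch in branch wood during the first half of the growing season:
#' the window starts at budbreak and spans `starch_buildup_days`. A daily
#' concentration series rising linearly by exactly the configured amplitude
#' over the window is attached.
#'
#' @param config A [scenario_config()].
#' @param species Species name in `config$species`.
#' @param position `"sun"` or `"shade"`.
#' @return A [starch_dynamics()] object.
#' @export
generate_starch_dynamics <- function(config, species,
                                     position = c("sun", "shade")) {
  stopifnot(inherits(config, "scenario_config"))
  position <- match.arg(position)
  sp <- config$species[[species]]
  if (is.null(sp)) stop("unknown species '", species, "'", call. = FALSE)
  budbreak <- sp[[paste0("budbreak_", position)]]
  if (sp$habit == "evergreen") {
    window_end <- budbreak
    window_start <- budbreak - sp$starch_buildup_days
    basis <- "conifer_needles_1yr"
    tissue_mass <- sp[[paste0("needle_mass_1yr_", position)]]
  } else {
    window_start <- budbreak
    window_end <- budbreak + sp$starch_buildup_days
    basis <- "broadleaf_wood_3to5yr"
    leaf_area <- sp[[paste0("leaf_mass_", position)]] / 1000 *
      sp[[paste0("sla_", position)]]
    tissue_mass <- leaf_area / sp[[paste0("la_bdw_", position)]] * 1000
  }
  year_start <- as.Date(sprintf("%d-01-01", config$year))
  year_end <- as.Date(sprintf("%d-12-31", config$year))
  if (window_start < year_start || window_end > year_end)
    stop("starch build-up window falls outside the scenario year",
         call. = FALSE)
  dates <- seq(year_start, year_end, by = "day")
  base <- 0.01
  conc <- ifelse(dates < window_start, base,
                 ifelse(dates > window_end, base + sp[[paste0("starch_amplitude_", position)]],
                        base + sp[[paste0("starch_amplitude_", position)]] *
                          as.numeric(dates - window_start) /
                          max(1, as.numeric(window_end - window_start))))
  starch_dynamics(
    amplitude = sp[[paste0("starch_amplitude_", position)]],
    window_start = window_start, window_end = window_end, basis = basis,
    tissue_mass_g = tissue_mass, species = species, position = position,
    concentration = data.frame(date = dates, conc_g_g = conc)
  )
}
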