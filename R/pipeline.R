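#' Pipeline constants
#'
#' The fixed constants of the carbon-balance calculation, gathered in one
#' validated block: the lux-to-PPFD divisor (120), the molecular weight of
#' carbon (12 g mol^-1), the Q10 respiration coefficient (2) with its 25
#' degrees C reference, the photosynthesis temperature anchors
#' (-2, 10, 30, 42 degrees C), the C fraction of starch (0.4), the branch
#' biomass upscaling parameters (5 years, 2 shoots per parent shoot), and
#' the amortisation loop cap (10 years).
#'
#' @param lux_divisor,mw_carbon,q10,t_ref,anchors,starch_c_fraction
#'   See description.
#' @param upscale_years,upscale_shoots,max_loops See description.
#' @return A list of class `pipeline_constants`.
#' @export
pipeline_constants <- function(lux_divisor = 120, mw_carbon = 12, q10 = 2,
                               t_ref = 25, anchors = c(-2, 10, 30, 42),
                               starch_c_fraction = 0.4, upscale_years = 5,
                               upscale_shoots = 2, max_loops = 10) {
  for (v in c(lux_divisor, mw_carbon, q10, starch_c_fraction, upscale_years,
              upscale_shoots, max_loops))
    if (!is.finite(v) || v <= 0)
      stop("all pipeline constants must be positive", call. = FALSE)
  structure(list(lux_divisor = lux_divisor, mw_carbon = mw_carbon, q10 = q10,
                 t_ref = t_ref, anchors = anchors,
                 starch_c_fraction = starch_c_fraction,
                 upscale_years = upscale_years,
                 upscale_shoots = upscale_shoots, max_loops = max_loops),
            class = "pipeline_constants")
}

# Mean of fitted LRC parameter objects (species x position aggregation).
mean_lrc_params <- function(fits) {
  lrc_params(mean(vapply(fits, `[[`, 0, "pgmax")),
             mean(vapply(fits, `[[`, 0, "rd")),
             mean(vapply(fits, `[[`, 0, "phi0")))
}

# branch_inputs built from the species x position config means and the mean
# fitted LRC parameters.
config_inputs <- function(sp, position, light, lrc) {
  branch_inputs(
    light = light, lrc = lrc,
    sla_m2_kg = sp[[paste0("sla_", position)]],
    leaf_mass_g = sp[[paste0("leaf_mass_", position)]],
    la_bdw_m2_kg = sp[[paste0("la_bdw_", position)]],
    leaf_c_frac = sp[[paste0("leaf_c_frac_", position)]],
    twig_c_frac = sp[[paste0("twig_c_frac_", position)]],
    budbreak = sp[[paste0("budbreak_", position)]],
    discoloration = sp[[paste0("discoloration_", position)]],
    habit = sp$habit, lifespan_years = sp$lifespan_years,
    species = sp$name, position = position
  )
}

#' Run the branch carbon-balance pipeline end to end on a synthetic scenario
#'
#' Orchestrates every stage: generates the scenario inputs (light,
#' temperature, gas-exchange curves, branch records, starch dynamics), fits
#' the light-response curves (two per species x crown position), builds
#' temperature-corrected daily assimilation series and averages them per
#' species x position, evaluates amortisation times and relative carbon
#' costs for every branch record, runs the eight-factor sensitivity analysis
#' per species, and computes the relative cost of seasonal starch build-up
#' per species x position. Deterministic given the scenario seed.
#'
#' @param scenario A [scenario_config()].
#' @param out_dir Output directory; when non-`NULL`, all result tables are
#'   written as CSV together with a JSON run manifest.
#' @param constants A [pipeline_constants()] block.
#' @return (Invisibly) a list with elements `lrc_fits` (data frame),
#'   `assimilation` (data frame of daily mean A_N per species x position),
#'   `mean_an` (named list of [assimilation_series()]), `costs` (data
#'   frame, one row per branch record), `sensitivity` (data frame),
#'   `starch` (data frame), and `manifest`.
#' @export
run_pipeline <- function(scenario, out_dir = NULL,
                         constants = pipeline_constants()) {
  stopifnot(inherits(scenario, "scenario_config"))
  temp <- generate_temperature_series(scenario)
  positions <- c("sun", "shade")

  lrc_rows <- list(); an_rows <- list(); mean_an <- list()
  mean_fit <- list(); lights <- list()

  for (sp in scenario$species) {
    for (pos in positions) {
      key <- paste(sp$name, pos, sep = ".")
      light <- generate_light_series(scenario, sp$name, pos)
      lights[[key]] <- light
      truth <- sp[[paste0("lrc_", pos)]]
      true_params <- lrc_params(truth[["pgmax"]], truth[["rd"]], truth[["phi0"]])
      fits <- list()
      for (i in 1:2) {
        curve <- with_stream(scenario$seed,
                             paste("lrc", sp$name, pos, i, sep = "-"), {
          generate_lrc_observations(true_params, scenario$lrc_light_levels,
                                    scenario$lrc_noise_sd, species = sp$name,
                                    position = pos,
                                    curve_id = paste(sp$name, pos, i, sep = "-"))
        })
        fit <- fit_lrc(curve)
        fits[[i]] <- fit
        lrc_rows[[length(lrc_rows) + 1L]] <- data.frame(
          curve_id = attr(curve, "curve_id"), species = sp$name,
          position = pos, pgmax = fit$pgmax, rd = fit$rd, phi0 = fit$phi0,
          rss = fit$rss, converged = fit$converged
        )
      }
      mean_fit[[key]] <- mean_lrc_params(fits)
      # one daily A_N per fitted LRC x logger (one logger per position here),
      # then the species x position mean
      daily <- lapply(seq_along(fits), function(i) {
        sub <- compute_subdaily_series(light, temp, fits[[i]],
                                       t_ref = constants$t_ref,
                                       q10 = constants$q10,
                                       anchors = constants$anchors)
        daily_net_assimilation(sub, mw_carbon = constants$mw_carbon,
                               provenance = paste0("lrc", i, " x ",
                                                   attr(light, "sensor")))
      })
      m <- average_assimilation(daily)
      mean_an[[key]] <- m
      an_rows[[length(an_rows) + 1L]] <- data.frame(
        species = sp$name, position = pos, date = m$date, an_g_m2_d = m$value
      )
    }
  }

  records <- generate_branch_records(scenario)
  cost_rows <- lapply(records, function(r) {
    res <- evaluate_branch(r, mean_an[[paste(r$species, r$position, sep = ".")]],
                           max_loops = constants$max_loops)
    data.frame(tree_id = res$tree_id, species = res$species,
               position = res$position, c_f_g = res$c_f_g, c_t_g = res$c_t_g,
               leaf_amortisation_days = res$leaf_amortisation_days,
               total_amortisation_days = res$total_amortisation_days,
               leaf_rcc_pct = res$leaf_rcc_pct, twig_rcc_pct = res$twig_rcc_pct,
               total_rcc_pct = res$total_rcc_pct,
               lifetime_uptake_g = res$lifetime_uptake_g,
               looped_years = res$looped_years,
               never_amortised = res$never_amortised)
  })

  sens_rows <- lapply(scenario$species, function(sp) {
    shade <- config_inputs(sp, "shade", lights[[paste(sp$name, "shade", sep = ".")]],
                           mean_fit[[paste(sp$name, "shade", sep = ".")]])
    sun <- config_inputs(sp, "sun", lights[[paste(sp$name, "sun", sep = ".")]],
                         mean_fit[[paste(sp$name, "sun", sep = ".")]])
    res <- run_sensitivity(shade, sun, temp, t_ref = constants$t_ref,
                           q10 = constants$q10, anchors = constants$anchors,
                           max_loops = constants$max_loops)
    cbind(species = sp$name, as.data.frame(res))
  })

  starch_rows <- list()
  for (sp in scenario$species) {
    for (pos in positions) {
      key <- paste(sp$name, pos, sep = ".")
      dyn <- generate_starch_dynamics(scenario, sp$name, pos)
      starch_c <- starch_build_up_carbon(dyn,
                                         c_fraction = constants$starch_c_fraction,
                                         years = constants$upscale_years,
                                         shoots = constants$upscale_shoots)
      # assimilating leaf area over the build-up window: 1-year-old needles
      # for conifers (pre-budbreak build-up), the current-year branch for
      # broadleaves
      leaf_area <- if (sp$habit == "evergreen")
        sp[[paste0("needle_mass_1yr_", pos)]] / 1000 * sp[[paste0("sla_", pos)]]
      else
        sp[[paste0("leaf_mass_", pos)]] / 1000 * sp[[paste0("sla_", pos)]]
      a_branch <- branch_assimilation(mean_an[[key]], leaf_area)
      cost <- starch_relative_cost(starch_c, a_branch, dyn$window_start,
                                   dyn$window_end)
      starch_rows[[length(starch_rows) + 1L]] <- data.frame(
        species = sp$name, position = pos, basis = dyn$basis,
        amplitude_g_per_g = dyn$amplitude, tissue_mass_g = dyn$tissue_mass_g,
        starch_c_g = starch_c, window_start = format(dyn$window_start),
        window_end = format(dyn$window_end),
        window_uptake_g = cost$window_uptake_g,
        relative_cost_pct = cost$relative_cost_pct,
        negative_uptake = cost$negative_uptake
      )
    }
  }

  add_provenance <- function(df, stage) {
    cbind(df, scenario_seed = scenario$seed, scenario_year = scenario$year,
          stage = stage)
  }
  results <- list(
    lrc_fits = add_provenance(do.call(rbind, lrc_rows), "fit-lrc"),
    assimilation = add_provenance(do.call(rbind, an_rows), "assimilate"),
    mean_an = mean_an,
    costs = add_provenance(do.call(rbind, cost_rows), "costs"),
    sensitivity = add_provenance(do.call(rbind, sens_rows), "sensitivity"),
    starch = add_provenance(do.call(rbind, starch_rows), "starch"),
    manifest = list(
      package = "branchcarbon",
      version = as.character(utils::packageVersion("branchcarbon")),
      seed = scenario$seed, year = scenario$year,
      species = names(scenario$species),
      n_trees = scenario$n_trees,
      constants = unclass(constants)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results$lrc_fits, file.path(out_dir, "lrc_fits.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(results$assimilation,
                     file.path(out_dir, "assimilation.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(results$costs, file.path(out_dir, "costs.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(results$sensitivity,
                     file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(results$starch, file.path(out_dir, "starch_costs.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(results$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(results)
}
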