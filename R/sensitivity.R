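#' The eight replaceable factors of the sensitivity analysis
#'
#' @return Character vector of the eight factors, in reporting order:
#'   incident light, Pgmax, Rd, phi0, SLA, the leaf-area-to-branch-dry-weight
#'   ratio (LA:BDW), tissue C concentration, and season length.
#' @export
sensitivity_factors <- function() {
  c("incident_light", "pgmax", "rd", "phi0", "sla", "la_bdw",
    "tissue_c_concentration", "season_length")
}

#' Aggregated branch-level inputs for one species x crown position
#'
#' The species x position mean quantities from which the whole RCC pipeline
#' can be re-run: the incident light series, the (mean fitted) LRC
#' parameters, morphology ratios, tissue chemistry and phenology. Leaf area
#' and twig mass are derived at evaluation time as
#' `leaf_area = leaf_mass/1000 * SLA` and
#' `twig_mass = leaf_area / LA:BDW * 1000`, so that replacing SLA rescales
#' leaf area at fixed leaf mass and replacing LA:BDW rescales twig mass at
#' fixed leaf area.
#'
#' @param light A [light_series()] for the position.
#' @param lrc An [lrc_params()] object.
#' @param sla_m2_kg Specific leaf area, m^2 per kg leaf dry mass.
#' @param leaf_mass_g Branch leaf dry mass, g.
#' @param la_bdw_m2_kg Leaf area : branch (twig) dry weight ratio,
#'   m^2 per kg.
#' @param leaf_c_frac,twig_c_frac Tissue carbon fractions in (0, 1).
#' @param budbreak Date of 50% budbreak.
#' @param discoloration Date of 50% discoloration (deciduous).
#' @param habit `"deciduous"` or `"evergreen"`.
#' @param lifespan_years Needle lifespan, whole years (evergreen).
#' @param species Species label.
#' @param position `"sun"` or `"shade"`.
#' @return A list of class `branch_inputs`.
#' @export
branch_inputs <- function(light, lrc, sla_m2_kg, leaf_mass_g, la_bdw_m2_kg,
                          leaf_c_frac, twig_c_frac, budbreak,
                          discoloration = as.Date(NA),
                          habit = c("deciduous", "evergreen"),
                          lifespan_years = NA_integer_,
                          species = NA_character_, position = NA_character_) {
  habit <- match.arg(habit)
  stopifnot(inherits(lrc, "lrc_params"))
  if (sla_m2_kg <= 0 || leaf_mass_g <= 0 || la_bdw_m2_kg <= 0)
    stop("SLA, leaf mass and LA:BDW must be positive", call. = FALSE)
  structure(
    list(light = light, lrc = lrc, sla_m2_kg = sla_m2_kg,
         leaf_mass_g = leaf_mass_g, la_bdw_m2_kg = la_bdw_m2_kg,
         leaf_c_frac = leaf_c_frac, twig_c_frac = twig_c_frac,
         budbreak = as.Date(budbreak), discoloration = as.Date(discoloration),
         habit = habit, lifespan_years = lifespan_years,
         species = species, position = position),
    class = "branch_inputs"
  )
}

#' Derive the branch record implied by aggregated inputs
#'
#' @param inputs A [branch_inputs()] object.
#' @param tree_id Identifier for the derived record.
#' @return A [branch_record()] with leaf area and twig mass derived from
#'   leaf mass, SLA and LA:BDW.
#' @export
inputs_to_record <- function(inputs, tree_id = "aggregate") {
  leaf_area <- inputs$leaf_mass_g / 1000 * inputs$sla_m2_kg
  twig_mass <- leaf_area / inputs$la_bdw_m2_kg * 1000
  branch_record(
    tree_id = tree_id, species = inputs$species, position = inputs$position,
    leaf_area_m2 = leaf_area, leaf_mass_g = inputs$leaf_mass_g,
    twig_mass_g = twig_mass, leaf_c_frac = inputs$leaf_c_frac,
    twig_c_frac = inputs$twig_c_frac, budbreak = inputs$budbreak,
    discoloration = inputs$discoloration, habit = inputs$habit,
    lifespan_years = inputs$lifespan_years
  )
}

#' Run the full RCC pipeline for one set of aggregated branch inputs
#'
#' Re-runs light-to-assimilation and cost accounting end to end: sub-daily
#' temperature-corrected series, daily A_N, branch scaling, carbon costs and
#' the whole-branch (leaf + twig) relative carbon cost.
#'
#' @param inputs A [branch_inputs()] object.
#' @param temp A [temperature_series()] covering the light series.
#' @param t_ref,q10,anchors,max_loops Pipeline constants; see
#'   [compute_subdaily_series()] and [amortisation_time()].
#' @return The [evaluate_branch()] `cost_result` for the derived aggregate
#'   branch.
#' @export
evaluate_inputs <- function(inputs, temp, t_ref = 25, q10 = 2,
                            anchors = c(-2, 10, 30, 42), max_loops = 10) {
  sub <- compute_subdaily_series(inputs$light, temp, inputs$lrc,
                                 t_ref = t_ref, q10 = q10, anchors = anchors)
  an <- daily_net_assimilation(sub)
  evaluate_branch(inputs_to_record(inputs), an, max_loops = max_loops)
}

#' Replace one shade-input factor with its sun-crown value
#'
#' Substitution rules, exactly one component per factor:
#' `incident_light` swaps the light series; `pgmax`, `rd`, `phi0` swap that
#' single LRC parameter; `sla` swaps SLA (leaf area follows at fixed leaf
#' mass); `la_bdw` swaps the LA:BDW ratio (twig mass follows at fixed leaf
#' area); `tissue_c_concentration` swaps both tissue C fractions;
#' `season_length` swaps the phenology window (budbreak and, for deciduous
#' species, discoloration; evergreens have no season end, so only budbreak).
#'
#' @param shade,sun [branch_inputs()] for the two crown positions of one
#'   species.
#' @param factor One of [sensitivity_factors()].
#' @return The shade inputs with the single factor substituted.
#' @export
replace_factor <- function(shade, sun, factor) {
  stopifnot(inherits(shade, "branch_inputs"), inherits(sun, "branch_inputs"))
  if (!factor %in% sensitivity_factors())
    stop("unknown sensitivity factor: '", factor, "'", call. = FALSE)
  out <- shade
  switch(factor,
    incident_light = { out$light <- sun$light },
    pgmax = { out$lrc <- lrc_params(sun$lrc$pgmax, shade$lrc$rd, shade$lrc$phi0) },
    rd = { out$lrc <- lrc_params(shade$lrc$pgmax, sun$lrc$rd, shade$lrc$phi0) },
    phi0 = { out$lrc <- lrc_params(shade$lrc$pgmax, shade$lrc$rd, sun$lrc$phi0) },
    sla = { out$sla_m2_kg <- sun$sla_m2_kg },
    la_bdw = { out$la_bdw_m2_kg <- sun$la_bdw_m2_kg },
    tissue_c_concentration = {
      out$leaf_c_frac <- sun$leaf_c_frac
      out$twig_c_frac <- sun$twig_c_frac
    },
    season_length = {
      out$budbreak <- sun$budbreak
      if (shade$habit == "deciduous") out$discoloration <- sun$discoloration
    }
  )
  out
}

#' One-at-a-time sensitivity analysis of the shade-branch RCC
#'
#' Recomputes the whole-branch (leaf + twig) relative carbon cost of the
#' shaded lower-crown branch while replacing, one factor at a time, each of
#' the eight input factors with its value from the sun-exposed upper crown.
#' The full pipeline (sub-daily series, daily integration, costs, RCC) is
#' re-run for every replacement; no shortcut formulas. For each factor the
#' relative change is `(replaced - initial) / initial`.
#'
#' @param shade,sun [branch_inputs()] for the two crown positions.
#' @param temp Shared [temperature_series()] (vertical temperature gradients
#'   are treated as negligible).
#' @param ... Passed to [evaluate_inputs()].
#' @return A data frame of class `sensitivity_result` with columns `factor`,
#'   `rcc_initial`, `rcc_replaced`, `rel_change`. Attribute
#'   `initial_undefined` is `TRUE` when the initial RCC is not positive, in
#'   which case `rel_change` is `NA`.
#' @export
run_sensitivity <- function(shade, sun, temp, ...) {
  initial <- evaluate_inputs(shade, temp, ...)$total_rcc_pct
  undefined <- !is.finite(initial) || initial <= 0
  rows <- lapply(sensitivity_factors(), function(f) {
    replaced <- evaluate_inputs(replace_factor(shade, sun, f), temp, ...)$total_rcc_pct
    data.frame(factor = f, rcc_initial = initial, rcc_replaced = replaced,
               rel_change = if (undefined) NA_real_
                            else (replaced - initial) / initial)
  })
  out <- do.call(rbind, rows)
  attr(out, "initial_undefined") <- undefined
  attr(out, "sla_convention") <- "SLA replacement holds leaf mass fixed; LA:BDW replacement holds leaf area fixed"
  class(out) <- c("sensitivity_result", "data.frame")
  out
}
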