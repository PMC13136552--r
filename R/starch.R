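#' Upscale current-year branch biomass to an older branch system
#'
#' Assuming constant annual biomass increment and on average `shoots` new
#' shoots growing on each previous one, the biomass of a `years`-old branch
#' system supplied by one current-year branch is
#' \deqn{Biomass_{years} = Biomass_1 \times \sum_{i=1}^{years} i /
#'   shoots^{\,i-1}.}
#' With the defaults (5 years, 2 shoots per parent) the factor is exactly
#' 3.5625.
#'
#' @param biomass1 Current-year branch dry mass (wood + bark), g (> 0).
#' @param years Branch system age in years (>= 1).
#' @param shoots Mean number of new shoots per previous-year shoot (> 0).
#' @return Upscaled biomass, g.
#' @export
#' @examples
#' upscale_branch_biomass(1, 5)   # 3.5625
#' upscale_branch_biomass(1, 2)   # 2
upscale_branch_biomass <- function(biomass1, years = 5, shoots = 2) {
  if (any(!is.finite(biomass1)) || any(biomass1 <= 0))
    stop("'biomass1' must be positive", call. = FALSE)
  if (!is.numeric(years) || length(years) != 1L || years < 1 ||
      years != round(years))
    stop("'years' must be a whole number >= 1", call. = FALSE)
  if (shoots <= 0) stop("'shoots' must be positive", call. = FALSE)
  i <- seq_len(years)
  biomass1 * sum(i / shoots^(i - 1))
}

#' Seasonal starch dynamics of one branch tissue
#'
#' Summarises the within-year starch concentration dynamics by their
#' amplitude (minimum-to-maximum concentration) and the calendar window over
#' which the build-up happens, together with the dry-mass basis of the
#' tissue in which starch was measured: mature needles on 1-year-old
#' segments for conifers, or 3-5-year-old wood for broadleaves (represented
#' by the upscaled current-year twig mass).
#'
#' @param amplitude Seasonal concentration amplitude, g starch per g dry
#'   mass (>= 0).
#' @param window_start,window_end Dates delimiting the build-up window
#'   (inclusive); `window_start <= window_end` required.
#' @param basis `"conifer_needles_1yr"` or `"broadleaf_wood_3to5yr"`.
#' @param tissue_mass_g Dry mass of the measured tissue, g: 1-year-old
#'   needle mass for conifers, current-year twig (wood + bark) mass for
#'   broadleaves (upscaling to the 5-year branch system happens in
#'   [starch_build_up_carbon()]).
#' @param species,position Metadata labels.
#' @param concentration Optional daily concentration series (data frame with
#'   `date`, `conc_g_g`) from which amplitude/window were derived.
#' @return A list of class `starch_dynamics`.
#' @export
starch_dynamics <- function(amplitude, window_start, window_end,
                            basis = c("conifer_needles_1yr",
                                      "broadleaf_wood_3to5yr"),
                            tissue_mass_g, species = NA_character_,
                            position = NA_character_, concentration = NULL) {
  basis <- match.arg(basis)
  if (!is.finite(amplitude) || amplitude < 0)
    stop("'amplitude' must be nonnegative", call. = FALSE)
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (is.na(window_start) || is.na(window_end) || window_start > window_end)
    stop("starch build-up window must be non-empty (start <= end)", call. = FALSE)
  if (!is.finite(tissue_mass_g) || tissue_mass_g <= 0)
    stop("'tissue_mass_g' must be positive", call. = FALSE)
  structure(
    list(amplitude = amplitude, window_start = window_start,
         window_end = window_end, basis = basis,
         tissue_mass_g = tissue_mass_g, species = species,
         position = position, concentration = concentration),
    class = "starch_dynamics"
  )
}

#' Carbon in the seasonal starch build-up
#'
#' Total starch built up over the season, converted to grams of carbon:
#' concentration amplitude x tissue dry mass x the C fraction of starch
#' (0.4). For the broadleaf wood basis the current-year twig mass is first
#' upscaled to the 5-year-old branch system via [upscale_branch_biomass()].
#'
#' @param dynamics A [starch_dynamics()] object.
#' @param c_fraction C fraction of starch; default 0.4 g C per g starch.
#' @param years,shoots Upscaling parameters for the broadleaf wood basis.
#' @return Starch carbon, g C.
#' @export
#' @examples
#' d <- starch_dynamics(0.05, as.Date("2021-04-25"), as.Date("2021-06-24"),
#'                      basis = "broadleaf_wood_3to5yr", tissue_mass_g = 2)
#' starch_build_up_carbon(d)   # 0.05 * (2 * 3.5625) * 0.4 = 0.1425
starch_build_up_carbon <- function(dynamics, c_fraction = 0.4, years = 5,
                                   shoots = 2) {
  stopifnot(inherits(dynamics, "starch_dynamics"))
  if (c_fraction <= 0 || c_fraction > 1)
    stop("'c_fraction' must lie in (0, 1]", call. = FALSE)
  mass <- if (dynamics$basis == "broadleaf_wood_3to5yr")
    upscale_branch_biomass(dynamics$tissue_mass_g, years = years,
                           shoots = shoots)
  else dynamics$tissue_mass_g
  dynamics$amplitude * mass * c_fraction
}

#' Relative carbon cost of the seasonal starch build-up
#'
#' Starch carbon expressed as a percentage of the branch net carbon uptake
#' over the build-up window (endpoints inclusive):
#' `100 * starch_C / sum(A_Branch over window)`. Conifer windows lie before
#' budbreak; since the annual series is re-used periodically, the window's
#' calendar days are drawn from the same single-year series.
#'
#' @param starch_c Starch carbon, g C (>= 0).
#' @param a_branch Branch-basis [assimilation_series()] covering the window.
#' @param window_start,window_end Build-up window dates (inclusive).
#' @return A list of class `starch_cost` with `relative_cost_pct` (signed,
#'   not clipped), `window_uptake_g` and `negative_uptake` (flag set when
#'   the window net uptake is <= 0, i.e. the build-up exceeds concurrent
#'   supply).
#' @export
starch_relative_cost <- function(starch_c, a_branch, window_start,
                                 window_end) {
  if (!is.finite(starch_c) || starch_c < 0)
    stop("'starch_c' must be nonnegative", call. = FALSE)
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  keep <- a_branch$date >= window_start & a_branch$date <= window_end
  if (!any(keep))
    stop("assimilation series does not cover the starch build-up window",
         call. = FALSE)
  uptake <- sum(a_branch$value[keep])
  structure(
    list(relative_cost_pct = 100 * starch_c / uptake,
         window_uptake_g = uptake,
         negative_uptake = uptake <= 0),
    class = "starch_cost"
  )
}
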