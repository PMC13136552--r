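#' Branch morphology, chemistry and phenology record
#'
#' One current-year branch: leaf and twig (wood + bark) dry masses, tissue C
#' fractions, total branch leaf area, and the phenology that delimits the
#' foliage lifespan (50% budbreak; 50% discoloration for deciduous species;
#' an assumed needle lifespan in whole years for evergreens).
#'
#' @param tree_id,species,position Identifiers; `position` is `"sun"` or
#'   `"shade"`.
#' @param leaf_area_m2 Total branch leaf area, m^2 (> 0).
#' @param leaf_mass_g,twig_mass_g Dry masses, g (> 0).
#' @param leaf_c_frac,twig_c_frac Carbon fractions, g C per g dry mass, in
#'   (0, 1).
#' @param budbreak Date of 50% budbreak.
#' @param discoloration Date of 50% leaf discoloration (deciduous only;
#'   `NA` for evergreens).
#' @param habit `"deciduous"` or `"evergreen"`.
#' @param lifespan_years Needle lifespan in whole years (evergreen only;
#'   typically 3 or 5).
#' @return A list of class `branch_record`.
#' @export
branch_record <- function(tree_id, species, position, leaf_area_m2,
                          leaf_mass_g, twig_mass_g, leaf_c_frac, twig_c_frac,
                          budbreak, discoloration = as.Date(NA),
                          habit = c("deciduous", "evergreen"),
                          lifespan_years = NA_integer_) {
  habit <- match.arg(habit)
  for (m in c(leaf_area_m2, leaf_mass_g, twig_mass_g))
    if (!is.finite(m) || m <= 0)
      stop("masses and leaf area must be positive", call. = FALSE)
  for (f in c(leaf_c_frac, twig_c_frac))
    if (!is.finite(f) || f <= 0 || f >= 1)
      stop("carbon fractions must lie in (0, 1)", call. = FALSE)
  budbreak <- as.Date(budbreak)
  discoloration <- as.Date(discoloration)
  if (habit == "deciduous") {
    if (is.na(discoloration) || discoloration <= budbreak)
      stop("deciduous records need a discoloration date after budbreak",
           call. = FALSE)
  } else {
    if (!is.finite(lifespan_years) || lifespan_years < 1)
      stop("evergreen records need lifespan_years >= 1", call. = FALSE)
  }
  structure(
    list(tree_id = tree_id, species = species, position = position,
         leaf_area_m2 = leaf_area_m2, leaf_mass_g = leaf_mass_g,
         twig_mass_g = twig_mass_g, leaf_c_frac = leaf_c_frac,
         twig_c_frac = twig_c_frac, budbreak = budbreak,
         discoloration = discoloration, habit = habit,
         lifespan_years = as.integer(lifespan_years)),
    class = "branch_record"
  )
}

#' Carbon cost of a tissue from dry mass and C fraction
#'
#' The carbon cost of a tissue is the total carbon in its dry biomass:
#' `dry_mass * c_fraction`, in grams C. This deliberately excludes the
#' respiration costs of biosynthesis.
#'
#' @param dry_mass Tissue dry mass, g (> 0).
#' @param c_fraction Carbon fraction, g C per g dry mass, in (0, 1).
#' @return Carbon cost, g C.
#' @export
carbon_cost <- function(dry_mass, c_fraction) {
  if (any(!is.finite(dry_mass)) || any(dry_mass <= 0))
    stop("'dry_mass' must be positive", call. = FALSE)
  if (any(!is.finite(c_fraction)) || any(c_fraction <= 0) || any(c_fraction >= 1))
    stop("'c_fraction' must lie in (0, 1)", call. = FALSE)
  dry_mass * c_fraction
}

# Daily branch assimilation laid out from the budbreak day onwards, looping
# the single-year series back to 1 January when allowed. Returns up to
# (max_loops + 1) years of daily values starting at `start`.
looped_values <- function(a_branch, start, max_loops = 10) {
  dates <- a_branch$date
  idx0 <- match(as.Date(start), dates)
  if (is.na(idx0))
    stop("series does not contain the start date ", format(start), call. = FALSE)
  c(a_branch$value[idx0:length(dates)],
    rep(a_branch$value, max_loops))
}

#' Amortisation time of a carbon cost
#'
#' The number of days a branch needs to assimilate the carbon invested in its
#' tissues: the smallest `n >= 0` such that the cumulative daily branch
#' assimilation from the budbreak day (day 1 = budbreak itself) reaches
#' `cost`. Negative winter days enter the cumulative sum as they stand. When
#' the cumulation passes 31 December and `allow_loop` is `TRUE` (the
#' evergreen-conifer rule), the same single-year series restarts from its
#' 1 January; after `max_loops` re-used years without reaching the cost the
#' branch is flagged `never_amortised`.
#'
#' @param a_branch Branch-basis [assimilation_series()] covering one full
#'   calendar year that contains `start`.
#' @param cost Carbon cost to amortise, g C (>= 0).
#' @param start Budbreak date (day 1 of the count).
#' @param allow_loop Loop past the year end? Default `FALSE`.
#' @param max_loops Maximum number of looped years before giving up.
#' @return A list of class `amortisation` with elements `days` (integer; `NA`
#'   when never amortised), `looped_years`, and `never_amortised`.
#' @export
amortisation_time <- function(a_branch, cost, start, allow_loop = FALSE,
                              max_loops = 10) {
  if (!is.numeric(cost) || length(cost) != 1L || !is.finite(cost) || cost < 0)
    stop("'cost' must be a single nonnegative number (g C)", call. = FALSE)
  if (cost == 0)
    return(structure(list(days = 0L, looped_years = 0L, never_amortised = FALSE),
                     class = "amortisation"))
  vals <- looped_values(a_branch, start, max_loops = if (allow_loop) max_loops else 0)
  cum <- cumsum(vals)
  hit <- which(cum >= cost)
  n_year1 <- sum(a_branch$date >= as.Date(start))
  if (length(hit) == 0L || (!allow_loop && hit[1L] > n_year1)) {
    if (!allow_loop && length(hit) > 0L)
      return(structure(list(days = NA_integer_, looped_years = 0L,
                            never_amortised = TRUE), class = "amortisation"))
    return(structure(list(days = NA_integer_,
                          looped_years = if (allow_loop) as.integer(max_loops) else 0L,
                          never_amortised = TRUE), class = "amortisation"))
  }
  days <- hit[1L]
  looped <- if (days <= n_year1) 0L
            else as.integer((days - n_year1 - 1L) %/% nrow(a_branch) + 1L)
  structure(list(days = as.integer(days), looped_years = looped,
                 never_amortised = FALSE), class = "amortisation")
}

#' @export
print.amortisation <- function(x, ...) {
  if (x$never_amortised) cat("never amortised (cap reached)\n")
  else cat(sprintf("amortised after %d day(s)%s\n", x$days,
                   if (x$looped_years > 0)
                     sprintf(" (%d looped year(s))", x$looped_years) else ""))
  invisible(x)
}

#' Foliage lifespan window of a branch
#'
#' Deciduous: the budbreak-to-discoloration window, endpoints inclusive.
#' Evergreen: `lifespan_years` annual cycles of the single-year series,
#' looped, starting at budbreak.
#'
#' @param record A [branch_record()].
#' @return A list with `type` (`"deciduous"`/`"evergreen"`) and either
#'   `start`/`end` dates or `start`/`lifespan_years`.
#' @export
lifespan_window <- function(record) {
  stopifnot(inherits(record, "branch_record"))
  if (record$habit == "deciduous")
    list(type = "deciduous", start = record$budbreak, end = record$discoloration)
  else
    list(type = "evergreen", start = record$budbreak,
         lifespan_years = record$lifespan_years)
}

# Cumulative branch assimilation over a lifespan window (denominator of RCC).
window_uptake <- function(a_branch, window) {
  if (window$type == "deciduous") {
    keep <- a_branch$date >= window$start & a_branch$date <= window$end
    if (!any(keep))
      stop("lifespan window not covered by the assimilation series", call. = FALSE)
    sum(a_branch$value[keep])
  } else {
    n_year <- nrow(a_branch)
    vals <- looped_values(a_branch, window$start,
                          max_loops = window$lifespan_years)
    sum(vals[seq_len(window$lifespan_years * n_year)])
  }
}

#' Relative carbon cost (RCC) of a tissue
#'
#' Carbon cost expressed as a percentage of the cumulative branch
#' assimilation over the whole lifespan of the foliage:
#' `100 * cost / sum(A_Branch over window)`.
#'
#' @param a_branch Branch-basis [assimilation_series()] covering one full
#'   calendar year.
#' @param cost Carbon cost, g C (>= 0).
#' @param window A [lifespan_window()] specification.
#' @return A list of class `rcc` with `rcc_pct`, `lifetime_uptake_g`, and
#'   `undefined` (TRUE when lifetime uptake <= 0, i.e. a carbon-negative
#'   branch; `rcc_pct` is then `NA`).
#' @export
relative_carbon_cost <- function(a_branch, cost, window) {
  if (!is.numeric(cost) || cost < 0)
    stop("'cost' must be nonnegative", call. = FALSE)
  uptake <- window_uptake(a_branch, window)
  if (uptake <= 0)
    return(structure(list(rcc_pct = NA_real_, lifetime_uptake_g = uptake,
                          undefined = TRUE), class = "rcc"))
  structure(list(rcc_pct = 100 * cost / uptake, lifetime_uptake_g = uptake,
                 undefined = FALSE), class = "rcc")
}

#' Evaluate the full cost accounting of one branch
#'
#' Scales the species x position mean daily assimilation (A_N) to the branch
#' (A_Branch = leaf area x A_N), computes foliage and twig carbon costs
#' (C_F, C_T), amortisation times for C_F and C_F + C_T counted from
#' budbreak (evergreens may loop past the year end), and the leaf, twig and
#' total relative carbon costs over the foliage lifespan.
#'
#' @param record A [branch_record()].
#' @param an Leaf-area basis mean [assimilation_series()] for the record's
#'   species and crown position, covering one full calendar year.
#' @param max_loops Loop cap for evergreen amortisation.
#' @return A list of class `cost_result` with elements `c_f_g`, `c_t_g`,
#'   `leaf_amortisation_days`, `total_amortisation_days`, `leaf_rcc_pct`,
#'   `twig_rcc_pct`, `total_rcc_pct`, `lifetime_uptake_g`, `looped_years`,
#'   `never_amortised`, plus the identifying fields of the record.
#' @export
evaluate_branch <- function(record, an, max_loops = 10) {
  stopifnot(inherits(record, "branch_record"))
  a_branch <- branch_assimilation(an, record$leaf_area_m2)
  c_f <- carbon_cost(record$leaf_mass_g, record$leaf_c_frac)
  c_t <- carbon_cost(record$twig_mass_g, record$twig_c_frac)
  allow_loop <- record$habit == "evergreen"
  leaf_am <- amortisation_time(a_branch, c_f, record$budbreak,
                               allow_loop = allow_loop, max_loops = max_loops)
  total_am <- amortisation_time(a_branch, c_f + c_t, record$budbreak,
                                allow_loop = allow_loop, max_loops = max_loops)
  win <- lifespan_window(record)
  leaf_rcc <- relative_carbon_cost(a_branch, c_f, win)
  twig_rcc <- relative_carbon_cost(a_branch, c_t, win)
  total_rcc <- relative_carbon_cost(a_branch, c_f + c_t, win)
  structure(
    list(tree_id = record$tree_id, species = record$species,
         position = record$position,
         c_f_g = c_f, c_t_g = c_t,
         leaf_amortisation_days = leaf_am$days,
         total_amortisation_days = total_am$days,
         leaf_rcc_pct = leaf_rcc$rcc_pct,
         twig_rcc_pct = twig_rcc$rcc_pct,
         total_rcc_pct = total_rcc$rcc_pct,
         lifetime_uptake_g = total_rcc$lifetime_uptake_g,
         looped_years = total_am$looped_years,
         never_amortised = leaf_am$never_amortised || total_am$never_amortised),
    class = "cost_result"
  )
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("Branch %s (%s, %s)\n", x$tree_id, x$species, x$position))
  cat(sprintf("  costs: leaf %.3f g C, twig %.3f g C\n", x$c_f_g, x$c_t_g))
  cat(sprintf("  amortisation: leaf %s d, total %s d%s\n",
              format(x$leaf_amortisation_days), format(x$total_amortisation_days),
              if (x$never_amortised) " [never amortised]" else ""))
  cat(sprintf("  RCC: leaf %.2f%%, twig %.2f%%, total %.2f%%\n",
              x$leaf_rcc_pct, x$twig_rcc_pct, x$total_rcc_pct))
  invisible(x)
}
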