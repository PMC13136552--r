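#' Convert illuminance (lux) to PPFD
#'
#' Empirical sensor conversion for HOBO-type pendant light loggers:
#' PPFD = lux / 120.
#'
#' @param lux Illuminance values (nonnegative).
#' @param divisor Conversion divisor; default 120 lux per µmol m^-2 s^-1.
#' @return PPFD, µmol photons m^-2 s^-1.
#' @export
lux_to_ppfd <- function(lux, divisor = 120) {
  if (any(!is.finite(lux)) || any(lux < 0))
    stop("'lux' must be finite and nonnegative", call. = FALSE)
  if (!is.numeric(divisor) || divisor <= 0)
    stop("'divisor' must be positive", call. = FALSE)
  lux / divisor
}

#' 15-min irradiance logger series
#'
#' @param timestamp POSIXct timestamps, strictly increasing, uniform 15-min
#'   spacing (local standard time; no DST shifts).
#' @param ppfd PPFD values, µmol m^-2 s^-1, nonnegative.
#' @param sensor,species,position Metadata labels; `position` is `"sun"` or
#'   `"shade"`.
#' @return Data frame of class `light_series`.
#' @export
light_series <- function(timestamp, ppfd, sensor = NA_character_,
                         species = NA_character_, position = NA_character_) {
  if (length(timestamp) != length(ppfd))
    stop("'timestamp' and 'ppfd' must have the same length", call. = FALSE)
  if (!inherits(timestamp, "POSIXct"))
    stop("'timestamp' must be POSIXct", call. = FALSE)
  dt <- diff(as.numeric(timestamp))
  if (length(dt) && any(dt <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (length(dt) && any(dt != 900))
    stop("light series must have uniform 15-min spacing; gap(s) at ",
         paste(utils::head(format(timestamp[which(dt != 900) + 1L]), 3),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(ppfd)) || any(ppfd < 0))
    stop("'ppfd' must be finite and nonnegative", call. = FALSE)
  out <- data.frame(timestamp = timestamp, ppfd = as.numeric(ppfd))
  attr(out, "sensor") <- sensor
  attr(out, "species") <- species
  attr(out, "position") <- position
  class(out) <- c("light_series", "data.frame")
  out
}

#' Hourly air-temperature series
#'
#' @param timestamp POSIXct timestamps, strictly increasing, uniform hourly
#'   spacing.
#' @param temp_c Air temperature, degrees Celsius.
#' @return Data frame of class `temperature_series`.
#' @export
temperature_series <- function(timestamp, temp_c) {
  if (length(timestamp) != length(temp_c))
    stop("'timestamp' and 'temp_c' must have the same length", call. = FALSE)
  if (!inherits(timestamp, "POSIXct"))
    stop("'timestamp' must be POSIXct", call. = FALSE)
  dt <- diff(as.numeric(timestamp))
  if (length(dt) && any(dt != 3600))
    stop("temperature series must have uniform hourly spacing", call. = FALSE)
  if (any(!is.finite(temp_c)))
    stop("'temp_c' must be finite", call. = FALSE)
  out <- data.frame(timestamp = timestamp, temp_c = as.numeric(temp_c))
  class(out) <- c("temperature_series", "data.frame")
  out
}

#' Temperature multiplier for gross photosynthesis
#'
#' Piecewise-linear response assuming a broad photosynthetic optimum between
#' 10 and 30 degrees C, declining linearly to zero at -2 and +42 degrees C:
#' 0 for T <= -2; (T+2)/12 on (-2, 10); 1 on \[10, 30\]; (42-T)/12 on
#' (30, 42); 0 for T >= 42.
#'
#' @param temp_c Air temperature(s), degrees Celsius (any finite value).
#' @param anchors Length-4 vector of anchor temperatures
#'   (zero, optimum-start, optimum-end, zero); default `c(-2, 10, 30, 42)`.
#' @return Dimensionless multiplier in \[0, 1\].
#' @export
temperature_multiplier <- function(temp_c, anchors = c(-2, 10, 30, 42)) {
  if (length(anchors) != 4L || any(diff(anchors) <= 0))
    stop("'anchors' must be 4 strictly increasing temperatures", call. = FALSE)
  stats::approx(x = anchors, y = c(0, 1, 1, 0), xout = temp_c, rule = 2)$y
}

#' Temperature-correct dark respiration with a Q10 law
#'
#' \eqn{R_d(T) = R_{d,ref} \cdot Q_{10}^{(T - T_{ref})/10}}.
#'
#' @param rd_ref Respiration rate at the reference temperature (>= 0).
#' @param temp_c Temperature(s) at which to evaluate, degrees C.
#' @param t_ref Reference temperature; default 25 degrees C, the gas-exchange
#'   chamber setpoint at which the LRCs are measured.
#' @param q10 Temperature coefficient (> 0); default 2.
#' @return Corrected respiration rate(s), same units as `rd_ref`.
#' @export
correct_respiration <- function(rd_ref, temp_c, t_ref = 25, q10 = 2) {
  if (any(rd_ref < 0)) stop("'rd_ref' must be nonnegative", call. = FALSE)
  if (q10 <= 0) stop("'q10' must be positive", call. = FALSE)
  rd_ref * q10^((temp_c - t_ref) / 10)
}

#' Temperature-corrected sub-daily assimilation series
#'
#' Combines a 15-min light series, an hourly temperature series and fitted
#' LRC parameters into 15-min series of temperature-corrected gross
#' photosynthesis, dark respiration and their difference (net assimilation).
#' Each hourly temperature is applied as a step function to the four 15-min
#' steps within its hour. Per step:
#' `pg = gross_photosynthesis(I) * temperature_multiplier(T)` and
#' `rd = correct_respiration(Rd, T, t_ref, q10)`.
#'
#' @param light A [light_series()].
#' @param temp A [temperature_series()] covering every hour of `light`.
#' @param params An [lrc_params()] object.
#' @param t_ref,q10 Respiration correction constants; see
#'   [correct_respiration()].
#' @param anchors Photosynthesis temperature anchors; see
#'   [temperature_multiplier()].
#' @return Data frame of class `subdaily_series` with columns `timestamp`,
#'   `ppfd`, `temp_c`, `pg`, `rd`, `net` (all rates µmol CO2 m^-2 s^-1).
#' @export
compute_subdaily_series <- function(light, temp, params, t_ref = 25, q10 = 2,
                                    anchors = c(-2, 10, 30, 42)) {
  stopifnot(inherits(params, "lrc_params"))
  if (!all(c("timestamp", "ppfd") %in% names(light)))
    stop("'light' must have columns 'timestamp' and 'ppfd'", call. = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(temp)))
    stop("'temp' must have columns 'timestamp' and 'temp_c'", call. = FALSE)
  ts_num <- as.numeric(light$timestamp)
  hour_start <- ts_num - ts_num %% 3600
  idx <- match(hour_start, as.numeric(temp$timestamp))
  if (anyNA(idx)) {
    missing_days <- unique(as.Date(light$timestamp[is.na(idx)], tz = "UTC"))
    stop("temperature series does not cover all light timesteps; ",
         "uncovered date(s): ",
         paste(utils::head(format(missing_days), 5), collapse = ", "),
         call. = FALSE)
  }
  tc <- temp$temp_c[idx]
  pg <- gross_photosynthesis(light$ppfd, params) * temperature_multiplier(tc, anchors)
  rd <- correct_respiration(params$rd, tc, t_ref = t_ref, q10 = q10)
  out <- data.frame(timestamp = light$timestamp, ppfd = light$ppfd,
                    temp_c = tc, pg = pg, rd = rd, net = pg - rd)
  class(out) <- c("subdaily_series", "data.frame")
  out
}

#' Daily assimilation series constructor
#'
#' @param date Date vector, one entry per calendar day.
#' @param value Daily assimilation: g C m^-2 d^-1 on the leaf-area basis, or
#'   g C branch^-1 d^-1 on the branch basis.
#' @param basis `"leaf_area"` or `"branch"`.
#' @param provenance Free-text provenance (which LRC x logger, or
#'   "mean of k series").
#' @param leaf_area Branch leaf area in m^2 (required for `basis = "branch"`).
#' @return Data frame of class `assimilation_series`.
#' @export
assimilation_series <- function(date, value, basis = c("leaf_area", "branch"),
                                provenance = NA_character_, leaf_area = NA_real_) {
  basis <- match.arg(basis)
  if (length(date) != length(value))
    stop("'date' and 'value' must have the same length", call. = FALSE)
  if (!inherits(date, "Date")) stop("'date' must be of class Date", call. = FALSE)
  if (anyDuplicated(date)) stop("one value per calendar day required", call. = FALSE)
  if (basis == "branch" && (!is.finite(leaf_area) || leaf_area <= 0))
    stop("branch-basis series requires a positive 'leaf_area' provenance",
         call. = FALSE)
  out <- data.frame(date = date, value = as.numeric(value))
  attr(out, "basis") <- basis
  attr(out, "provenance") <- provenance
  attr(out, "leaf_area") <- leaf_area
  class(out) <- c("assimilation_series", "data.frame")
  out
}

#' Integrate a sub-daily net series to daily net carbon assimilation
#'
#' Sums the 15-min net assimilation rates over each complete calendar day
#' and converts µmol CO2 m^-2 to grams of carbon:
#' `A_N(day) = sum(net) * 900 s * 12 g mol-1 * 1e-6 mol µmol-1`,
#' in g C m^-2 d^-1. Winter days may legitimately be negative. Partial days
#' at the series edges are dropped with a warning, never extrapolated.
#'
#' @param subdaily A `subdaily_series` from [compute_subdaily_series()], or
#'   any data frame with columns `timestamp` and `net`.
#' @param mw_carbon Molecular weight of carbon; default 12 g mol^-1.
#' @param provenance Provenance string carried onto the result.
#' @return An [assimilation_series()] on the leaf-area basis.
#' @export
daily_net_assimilation <- function(subdaily, mw_carbon = 12,
                                   provenance = NA_character_) {
  if (!all(c("timestamp", "net") %in% names(subdaily)))
    stop("'subdaily' must have columns 'timestamp' and 'net'", call. = FALSE)
  day <- as.Date(subdaily$timestamp, tz = "UTC")
  steps <- table(day)
  complete <- names(steps)[steps == 96L]
  if (length(complete) < length(steps))
    warning(sum(steps != 96L), " partial day(s) excluded from daily integration",
            call. = FALSE)
  keep <- day %in% as.Date(complete)
  if (!any(keep))
    stop("no complete days available for daily integration", call. = FALSE)
  sums <- tapply(subdaily$net[keep], droplevels(factor(day[keep])), sum)
  assimilation_series(
    date = as.Date(names(sums)),
    value = as.numeric(sums) * 900 * mw_carbon * 1e-6,
    basis = "leaf_area", provenance = provenance
  )
}

#' Average daily assimilation series within a species x position group
#'
#' Pointwise arithmetic mean of aligned daily series (e.g. the 2 LRCs x 1-4
#' loggers of one species and crown position).
#'
#' @param series_list A list of [assimilation_series()] with identical dates
#'   and identical basis.
#' @return An [assimilation_series()] whose provenance records the number of
#'   members averaged.
#' @export
average_assimilation <- function(series_list) {
  if (!is.list(series_list) || length(series_list) < 1L)
    stop("'series_list' must be a non-empty list of assimilation series",
         call. = FALSE)
  ref <- series_list[[1L]]
  for (s in series_list) {
    if (!identical(as.integer(s$date), as.integer(ref$date)))
      stop("cannot average assimilation series with mismatched dates",
           call. = FALSE)
    if (!identical(attr(s, "basis"), attr(ref, "basis")))
      stop("cannot average series with different bases", call. = FALSE)
  }
  vals <- rowMeans(do.call(cbind, lapply(series_list, `[[`, "value")))
  assimilation_series(
    date = ref$date, value = vals, basis = attr(ref, "basis"),
    provenance = sprintf("mean of %d series", length(series_list)),
    leaf_area = attr(ref, "leaf_area")
  )
}

#' Scale a leaf-area assimilation series to the whole branch
#'
#' `A_Branch(d) = leaf_area * A_N(d)`, g C branch^-1 d^-1.
#'
#' @param an An [assimilation_series()] on the leaf-area basis
#'   (g C m^-2 d^-1).
#' @param leaf_area Total branch leaf area, m^2 (> 0).
#' @return An [assimilation_series()] on the branch basis.
#' @export
branch_assimilation <- function(an, leaf_area) {
  if (!inherits(an, "assimilation_series") || attr(an, "basis") != "leaf_area")
    stop("'an' must be a leaf-area basis assimilation series", call. = FALSE)
  if (!is.numeric(leaf_area) || length(leaf_area) != 1L ||
      !is.finite(leaf_area) || leaf_area <= 0)
    stop("'leaf_area' must be a single positive number (m^2)", call. = FALSE)
  assimilation_series(
    date = an$date, value = an$value * leaf_area, basis = "branch",
    provenance = attr(an, "provenance"), leaf_area = leaf_area
  )
}
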