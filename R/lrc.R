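#' Photosynthetic light-response curve (LRC) parameters
#'
#' Container for the three parameters of the exponential saturation model of
#' net photosynthesis,
#' \deqn{P_N(I) = P_{gmax}\,(1 - e^{-\phi_0 I / P_{gmax}}) - R_d,}
#' where \eqn{I} is PPFD (µmol photons m^-2 s^-1), \eqn{P_{gmax}} the
#' asymptotic maximum gross assimilation rate (µmol CO2 m^-2 s^-1),
#' \eqn{R_d} dark respiration (stored as a positive magnitude and subtracted),
#' and \eqn{\phi_0} the quantum yield at \eqn{I = 0}
#' (µmol CO2 per µmol photons).
#'
#' @param pgmax Maximum gross assimilation rate, must be > 0.
#' @param rd Dark respiration rate (positive magnitude), must be >= 0.
#' @param phi0 Quantum yield at zero light, must be > 0.
#' @param rss Residual sum of squares of the fit (NA for hand-built params).
#' @param converged Logical convergence flag (NA for hand-built params).
#' @return An object of class `lrc_params`.
#' @seealso [predict_net_photosynthesis()], [fit_lrc()]
#' @export
#' @examples
#' p <- lrc_params(pgmax = 10, rd = 1, phi0 = 0.05)
#' predict_net_photosynthesis(c(0, 200, 1500), p)
lrc_params <- function(pgmax, rd, phi0, rss = NA_real_, converged = NA) {
  if (!is.numeric(pgmax) || length(pgmax) != 1L || !is.finite(pgmax) || pgmax <= 0)
    stop("'pgmax' must be a single positive number", call. = FALSE)
  if (!is.numeric(rd) || length(rd) != 1L || !is.finite(rd) || rd < 0)
    stop("'rd' must be a single nonnegative number (positive magnitude convention)",
         call. = FALSE)
  if (!is.numeric(phi0) || length(phi0) != 1L || !is.finite(phi0) || phi0 <= 0)
    stop("'phi0' must be a single positive number", call. = FALSE)
  structure(
    list(pgmax = as.numeric(pgmax), rd = as.numeric(rd), phi0 = as.numeric(phi0),
         rss = as.numeric(rss), converged = converged),
    class = "lrc_params"
  )
}

#' @export
print.lrc_params <- function(x, ...) {
  cat("Light-response curve parameters (exponential saturation model)\n")
  cat(sprintf("  Pgmax: %.4f umol CO2 m-2 s-1\n", x$pgmax))
  cat(sprintf("  Rd:    %.4f umol CO2 m-2 s-1\n", x$rd))
  cat(sprintf("  phi0:  %.5f umol CO2 / umol photons\n", x$phi0))
  if (is.finite(x$rss))
    cat(sprintf("  RSS: %.5g  converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' Gross photosynthesis predicted by the exponential LRC
#'
#' \eqn{P_g(I) = P_{gmax}(1 - e^{-\phi_0 I / P_{gmax}})}. Satisfies
#' \eqn{P_g(0) = 0} and \eqn{0 \le P_g < P_{gmax}}.
#'
#' @param ppfd Photosynthetic photon flux density, µmol m^-2 s^-1 (vectorised,
#'   must be nonnegative).
#' @param params An [lrc_params()] object.
#' @return Gross assimilation rate(s), µmol CO2 m^-2 s^-1.
#' @export
gross_photosynthesis <- function(ppfd, params) {
  stopifnot(inherits(params, "lrc_params"))
  if (any(!is.finite(ppfd)) || any(ppfd < 0))
    stop("'ppfd' must be finite and nonnegative", call. = FALSE)
  params$pgmax * (1 - exp(-params$phi0 * ppfd / params$pgmax))
}

#' Net photosynthesis predicted by the exponential LRC
#'
#' \eqn{P_N(I) = P_g(I) - R_d}; the curve passes through \eqn{-R_d} at zero
#' light, is strictly increasing in \eqn{I} for \eqn{\phi_0 > 0}, and
#' saturates at \eqn{P_{gmax} - R_d}.
#'
#' @inheritParams gross_photosynthesis
#' @return Net assimilation rate(s), µmol CO2 m^-2 s^-1.
#' @export
predict_net_photosynthesis <- function(ppfd, params) {
  gross_photosynthesis(ppfd, params) - params$rd
}

#' Gas-exchange observations for one light-response curve
#'
#' @param ppfd Incident PPFD of each observation (nonnegative).
#' @param pn Measured net photosynthesis, µmol CO2 m^-2 s^-1.
#' @param species Species label.
#' @param position Crown position, `"sun"` or `"shade"`.
#' @param curve_id Curve identifier.
#' @return A data frame of class `gas_exchange_curve` with columns
#'   `ppfd`, `pn` and metadata attributes.
#' @export
gas_exchange_curve <- function(ppfd, pn, species = NA_character_,
                               position = NA_character_,
                               curve_id = NA_character_) {
  if (length(ppfd) != length(pn))
    stop("'ppfd' and 'pn' must have the same length", call. = FALSE)
  if (any(!is.finite(ppfd)) || any(ppfd < 0))
    stop("all 'ppfd' values must be finite and nonnegative", call. = FALSE)
  out <- data.frame(ppfd = as.numeric(ppfd), pn = as.numeric(pn))
  attr(out, "species") <- species
  attr(out, "position") <- position
  attr(out, "curve_id") <- curve_id
  class(out) <- c("gas_exchange_curve", "data.frame")
  out
}

#' Fit the exponential light-response model to one gas-exchange curve
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints, via
#' \pkg{minpack.lm}) of the exponential saturation model to observed
#' (PPFD, P_N) pairs. Each curve is fitted individually; any pooling across
#' curves happens downstream of fitting.
#'
#' Starting values: \eqn{R_{d,0} = \max(0, -\min P_N)},
#' \eqn{P_{gmax,0} = \max(P_N) + R_{d,0}}, and \eqn{\phi_{0,0}} from the slope
#' of the two lowest-light observations. Box bounds keep the optimiser in a
#' physiological region and are configurable.
#'
#' @param curve A [gas_exchange_curve()] (or a data frame with columns
#'   `ppfd` and `pn`). At least 3 observations spanning at least 2 distinct
#'   light levels are required; a design including a near-zero light level is
#'   strongly recommended for identifiability of `rd` and `phi0`.
#' @param lower,upper Named bounds for `pgmax`, `rd`, `phi0`.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return An [lrc_params()] object with `rss` and `converged` filled in.
#'   Non-convergence is flagged (`converged = FALSE`), never silent.
#' @export
#' @examples
#' truth <- lrc_params(10, 1, 0.05)
#' obs <- generate_lrc_observations(truth, c(0, 50, 100, 250, 500, 1500), 0)
#' fit_lrc(obs)
fit_lrc <- function(curve,
                    lower = c(pgmax = 1e-6, rd = 0, phi0 = 1e-6),
                    upper = c(pgmax = 100, rd = 20, phi0 = 0.2),
                    maxiter = 500) {
  if (!is.data.frame(curve) || !all(c("ppfd", "pn") %in% names(curve)))
    stop("'curve' must be a data frame with columns 'ppfd' and 'pn'",
         call. = FALSE)
  df <- data.frame(ppfd = as.numeric(curve$ppfd), pn = as.numeric(curve$pn))
  if (nrow(df) < 3L)
    stop("at least 3 observations are required to fit the 3-parameter LRC",
         call. = FALSE)
  if (length(unique(df$ppfd)) < 2L)
    stop("observations at a single light level cannot identify the LRC",
         call. = FALSE)

  rd0 <- max(0, -min(df$pn))
  pgmax0 <- max(df$pn) + rd0
  ord <- order(df$ppfd)
  lo <- df[ord[1:2], ]
  phi00 <- if (diff(lo$ppfd) > 0) (lo$pn[2] - lo$pn[1]) / (lo$ppfd[2] - lo$ppfd[1]) else 0.03
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  start <- list(
    pgmax = clamp(pgmax0, lower[["pgmax"]] * 2, upper[["pgmax"]] * 0.99),
    rd = clamp(rd0, lower[["rd"]], upper[["rd"]] * 0.99),
    phi0 = clamp(phi00, 1e-4, upper[["phi0"]] * 0.99)
  )

  fit <- tryCatch(
    minpack.lm::nlsLM(
      pn ~ pgmax * (1 - exp(-phi0 * ppfd / pgmax)) - rd,
      data = df, start = start,
      lower = lower[c("pgmax", "rd", "phi0")],
      upper = upper[c("pgmax", "rd", "phi0")],
      control = minpack.lm::nls.lm.control(
        maxiter = maxiter, ftol = .Machine$double.eps,
        ptol = .Machine$double.eps, gtol = 0)
    ),
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    out <- lrc_params(start$pgmax, start$rd, start$phi0,
                      rss = Inf, converged = FALSE)
    attr(out, "message") <- conditionMessage(fit)
    return(out)
  }

  cf <- stats::coef(fit)
  info <- fit$convInfo
  lrc_params(cf[["pgmax"]], cf[["rd"]], cf[["phi0"]],
             rss = sum(stats::residuals(fit)^2),
             converged = isTRUE(info$isConv) || is.null(info))
}
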