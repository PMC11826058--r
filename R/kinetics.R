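#' Specific growth rate by forward differences
#'
#' Estimates the per-hour specific growth rate at each sampling time from
#' consecutive OD600 readings,
#' \deqn{\mu(t) = \frac{OD(t+\Delta t) - OD(t)}{\Delta t \cdot OD(t)},}
#' assigning each rate to the left endpoint \eqn{t}. Non-uniform time grids
#' are supported; no smoothing is applied — the estimator is deliberately the
#' raw forward difference.
#'
#' @param series A [well_series()].
#' @return A data.frame with columns `time_h` (left endpoints, length m-1)
#'   and `mu` (per hour).
#' @export
specific_growth_rate <- function(series) {
  stopifnot(inherits(series, "well_series"))
  od <- series$od600
  if (length(od) < 2L)
    bs_insufficient_data_error("specific_growth_rate needs at least 2 time points")
  if (any(od <= 0))
    bs_data_quality_error(sprintf("well '%s': OD600 must be positive (blank-correct first)",
                                  series$well_id))
  dt <- diff(series$times)
  m <- length(od)
  data.frame(time_h = series$times[-m],
             mu = diff(od) / (dt * od[-m]))
}

# Shift a fluorescence series earlier by the maturation delay, in whole
# samples: k = round(maturation_time / median dt). The k trailing points lost
# to the shift are dropped, not extrapolated.
maturation_shift <- function(flu, times, maturation_time) {
  m <- length(flu)
  dt <- diff(times)
  med <- stats::median(dt)
  if (maturation_time < 0) bs_usage_error("maturation_time must be >= 0")
  if (max(abs(dt - med)) > 0.1 * med)
    warning("time grid spacing varies by more than 10%; maturation shift uses the median interval")
  k <- as.integer(round(maturation_time / med))
  if (k >= m - 1L)
    bs_insufficient_data_error("maturation shift consumes all usable points")
  list(flu = flu[(1L + k):m], k = k)
}

#' Specific production rate of the reporter
#'
#' Estimates the per-biomass reporter synthesis rate by forward differences of
#' fluorescence normalized by OD600 at the left endpoint,
#' \deqn{\rho_H(t) = \frac{flu(t+\Delta t) - flu(t)}{\Delta t \cdot OD(t)}.}
#'
#' Slowly maturing fluorophores report synthesis that happened earlier; the
#' fluorescence curve is first shifted back in time by
#' `round(maturation_time / median dt)` whole samples (e.g. a 1 h RFP
#' maturation at 15-min sampling shifts by 4 points). GFPmut3 matures in
#' ~4 min, faster than typical sampling, so GFP channels default to no shift.
#'
#' @param series A [well_series()].
#' @param channel Fluorescence channel name.
#' @param maturation_time Maturation delay in hours (>= 0).
#' @return A data.frame with columns `time_h` and `rho_h`
#'   (fluorescence units per OD per hour), on the forward-difference grid of
#'   the shifted series.
#' @export
specific_production_rate <- function(series, channel, maturation_time = 0) {
  stopifnot(inherits(series, "well_series"))
  flu <- series$fluorescence[[channel]]
  if (is.null(flu))
    bs_format_error(sprintf("well '%s' has no fluorescence channel '%s'",
                            series$well_id, channel))
  od <- series$od600
  if (any(od <= 0))
    bs_data_quality_error(sprintf("well '%s': OD600 must be positive", series$well_id))
  sh <- maturation_shift(flu, series$times, maturation_time)
  mm <- length(sh$flu)            # samples remaining after the shift
  t_left <- series$times[seq_len(mm)]
  dt <- diff(series$times)[seq_len(mm - 1L)]
  data.frame(time_h = t_left[-mm],
             rho_h = diff(sh$flu) / (dt * od[seq_len(mm - 1L)]))
}

#' Heterologous-fraction proxy
#'
#' The ratio of fluorescence to optical density,
#' \eqn{\varphi_H(t) = flu(t) / OD_{600}(t)}, is the experimental proxy for
#' the proteome fraction occupied by the reporter (fluorescence is taken as
#' proportional to reporter mass, OD to total protein mass).
#'
#' @inheritParams specific_production_rate
#' @return A data.frame with columns `time_h` and `phi_h` on the original
#'   sample grid.
#' @export
heterologous_fraction <- function(series, channel) {
  stopifnot(inherits(series, "well_series"))
  flu <- series$fluorescence[[channel]]
  if (is.null(flu))
    bs_format_error(sprintf("well '%s' has no fluorescence channel '%s'",
                            series$well_id, channel))
  if (any(series$od600 <= 0))
    bs_data_quality_error(sprintf("well '%s': OD600 must be positive", series$well_id))
  data.frame(time_h = series$times, phi_h = flu / series$od600)
}

#' All derived rate series for one well
#'
#' Bundles the specific growth rate, the (maturation-corrected) specific
#' production rate and the heterologous-fraction proxy for one well. `mu` and
#' `rho_h` share one forward-difference grid (truncated to the shorter of the
#' two when a maturation shift drops trailing points); `phi_h` lives on the
#' original sample grid.
#'
#' @inheritParams specific_production_rate
#' @return An object of class `rate_series`: list with `well_id`, `channel`,
#'   `rates` (data.frame `time_h`, `mu`, `rho_h`) and `phi` (data.frame
#'   `time_h`, `phi_h`).
#' @export
rate_series <- function(series, channel, maturation_time = 0) {
  mu <- specific_growth_rate(series)
  rho <- specific_production_rate(series, channel, maturation_time)
  n <- min(nrow(mu), nrow(rho))
  structure(list(well_id = series$well_id, channel = channel,
                 rates = data.frame(time_h = mu$time_h[seq_len(n)],
                                    mu = mu$mu[seq_len(n)],
                                    rho_h = rho$rho_h[seq_len(n)]),
                 phi = heterologous_fraction(series, channel)),
            class = "rate_series")
}

#' Tidy rate table for a set of wells
#'
#' @param wells A `plate_data`, `condition_group`, or list of [well_series()].
#' @inheritParams specific_production_rate
#' @return A data.frame with columns `well`, `time_h`, `mu_per_h`, `rho_h`,
#'   `phi_h` (one row per forward-difference interval; `phi_h` is the value at
#'   the interval's left endpoint).
#' @export
rates_table <- function(wells, channel, maturation_time = 0) {
  ws_list <- if (inherits(wells, "plate_data")) {
    unlist(lapply(wells$groups, `[[`, "series"), recursive = FALSE, use.names = FALSE)
  } else if (inherits(wells, "condition_group")) wells$series
  else if (inherits(wells, "well_series")) list(wells) else wells
  do.call(rbind, lapply(ws_list, function(ws) {
    rs <- rate_series(ws, channel, maturation_time)
    n <- nrow(rs$rates)
    data.frame(well = ws$well_id, time_h = rs$rates$time_h,
               mu_per_h = rs$rates$mu, rho_h = rs$rates$rho_h,
               phi_h = rs$phi$phi_h[seq_len(n)],
               stringsAsFactors = FALSE)
  }))
}
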