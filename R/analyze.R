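#' Characterize one biosensor titration with both methods
#'
#' Convenience wrapper over the full analysis chain for a single strain and
#' inducer: per-concentration maximum-method and slope-method expression
#' fractions, the two dose-response tables, their Hill fits, and the
#' method-comparison record.
#'
#' @param pd A `plate_data` whose groups all belong to one strain/inducer
#'   titration.
#' @param channel Fluorescence channel.
#' @param window_h Maximum-method search window (hours).
#' @param alpha Growth-phase t-test level.
#' @param min_points Slope-fit trimming floor.
#' @param slope_model `"free_intercept"` or `"through_origin"`.
#' @param hill_form `"reduced"` or `"full"`.
#' @param r2_floor Slope-fit quality floor.
#' @param maturation_time Reporter maturation shift in hours.
#' @return A list: `max_fractions`, `slope_fits`, `dr_max`, `dr_slope`,
#'   `hill_max`, `hill_slope`, `comparison`.
#' @export
analyze_titration <- function(pd, channel, window_h = 10, alpha = 0.05,
                              min_points = 4,
                              slope_model = c("free_intercept", "through_origin"),
                              hill_form = c("reduced", "full"),
                              r2_floor = 0.9, maturation_time = 0) {
  slope_model <- match.arg(slope_model)
  hill_form <- match.arg(hill_form)
  mf <- suppressWarnings(
    lapply(pd$groups, find_phi_max, channel = channel, window_h = window_h))
  sf <- suppressWarnings(
    lapply(pd$groups, fit_slope, channel = channel, model = slope_model,
           min_points = min_points, maturation_time = maturation_time,
           alpha = alpha))
  dr_max <- max_dose_response(mf)
  dr_slope <- suppressWarnings(slope_dose_response(sf, r2_floor = r2_floor))
  hill_max <- suppressWarnings(fit_hill(dr_max, form = hill_form))
  hill_slope <- suppressWarnings(fit_hill(dr_slope, form = hill_form))
  list(max_fractions = mf, slope_fits = sf, dr_max = dr_max,
       dr_slope = dr_slope, hill_max = hill_max, hill_slope = hill_slope,
       comparison = compare_methods(hill_max, hill_slope))
}
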