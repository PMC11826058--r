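#' Expression fraction by the maximum method
#'
#' At an interior maximum of a proteome fraction its time derivative vanishes,
#' so the fraction equals its expression fraction at that instant. The maximum
#' method therefore estimates the expression fraction \eqn{f_H} as the peak of
#' the heterologous-fraction proxy \eqn{\varphi_H = flu/OD} within an early
#' culture window (default the first 10 h), taken per replicate and then
#' averaged across replicates. The per-replicate-then-average order matters:
#' replicate time shifts would bias the maximum of an averaged curve.
#'
#' If a replicate's maximum falls on the last in-window sample there is no
#' evidence of an interior maximum (continuously accumulating reporters, e.g.
#' MerR-driven RFP, never peak); when more than half of the replicates peak at
#' the window edge the result carries a boundary warning flag and the slope
#' method should be preferred.
#'
#' @param group A [condition_group()].
#' @param channel Fluorescence channel name.
#' @param window_h Search window in hours, measured from induction at t = 0.
#' @return An object of class `max_fraction`: per-replicate maxima and their
#'   times, their mean (the \eqn{f_H} estimate, fluorescence/OD units) and
#'   sample variance, replicate count, window, and boundary flag.
#' @export
find_phi_max <- function(group, channel, window_h = 10) {
  stopifnot(inherits(group, "condition_group"))
  per_rep <- lapply(group$series, function(ws) {
    ph <- heterologous_fraction(ws, channel)
    inside <- which(ph$time_h <= window_h)
    if (!length(inside))
      bs_insufficient_data_error(sprintf("well '%s': no samples inside the %g h window",
                                         ws$well_id, window_h))
    i <- inside[which.max(ph$phi_h[inside])]   # earliest index wins ties
    list(phi_max = ph$phi_h[i], t_max = ph$time_h[i],
         boundary = i == inside[length(inside)])
  })
  phi_max <- vapply(per_rep, `[[`, 0, "phi_max")
  t_max <- vapply(per_rep, `[[`, 0, "t_max")
  boundary <- vapply(per_rep, `[[`, NA, "boundary")
  res <- structure(list(
    strain = group$strain, inducer = group$inducer,
    concentration = group$concentration, conc_unit = group$conc_unit,
    phi_max = phi_max, t_max = t_max,
    phi_max_mean = mean(phi_max),
    phi_max_var = if (length(phi_max) > 1L) stats::var(phi_max) else NA_real_,
    n_replicates = length(phi_max), window_h = window_h,
    boundary_fraction = mean(boundary),
    boundary_flag = mean(boundary) > 0.5), class = "max_fraction")
  if (res$boundary_flag)
    warning(sprintf(
      "condition (%s, %s, %g): boundary maximum in %d/%d replicates; no interior maximum detected",
      group$strain, group$inducer, group$concentration, sum(boundary), length(boundary)))
  res
}

#' @export
print.max_fraction <- function(x, ...) {
  cat(sprintf("<max_fraction> %s / %s / %g %s: phi_max = %.4g (var %.3g, N = %d)%s\n",
              x$strain, x$inducer, x$concentration, x$conc_unit,
              x$phi_max_mean, x$phi_max_var, x$n_replicates,
              if (x$boundary_flag) " [boundary maximum]" else ""))
  invisible(x)
}

#' Assemble a maximum-method dose-response table
#'
#' Collects [find_phi_max()] results for one strain/inducer across inducer
#' concentrations into the table fed to the Hill fit: one row per
#' concentration with the \eqn{f_H} estimate, its across-replicate sample
#' variance (which becomes the inverse-variance weight) and the replicate
#' count.
#'
#' @param results List of `max_fraction` objects for a single strain and
#'   inducer.
#' @return A `dose_response` data.frame sorted by concentration, with
#'   attributes `strain`, `inducer`, `conc_unit` and `method = "maximum"`.
#' @export
max_dose_response <- function(results) {
  if (inherits(results, "max_fraction")) results <- list(results)
  strains <- unique(vapply(results, `[[`, "", "strain"))
  inducers <- unique(vapply(results, `[[`, "", "inducer"))
  if (length(strains) > 1L || length(inducers) > 1L)
    bs_usage_error("max_dose_response expects results from a single strain and inducer")
  conc <- vapply(results, `[[`, 0, "concentration")
  if (anyDuplicated(conc))
    bs_duplication_error(sprintf("duplicate concentration %g for strain '%s'",
                                 conc[duplicated(conc)][1L], strains))
  if (length(unique(conc)) < 3L)
    bs_insufficient_data_error("dose-response needs at least 3 distinct concentrations")
  ord <- order(conc)
  dose_response(
    data.frame(concentration = conc[ord],
               f_h = vapply(results, `[[`, 0, "phi_max_mean")[ord],
               variance = vapply(results, `[[`, 0, "phi_max_var")[ord],
               n = vapply(results, `[[`, 0L, "n_replicates")[ord],
               t_max_mean = vapply(results, function(r) mean(r$t_max), 0)[ord],
               boundary_flag = vapply(results, `[[`, NA, "boundary_flag")[ord]),
    strain = strains, inducer = inducers,
    conc_unit = unique(vapply(results, `[[`, "", "conc_unit"))[1L],
    method = "maximum")
}
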