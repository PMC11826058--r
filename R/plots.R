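#' Diagnostic plot: heterologous fraction over time
#'
#' One panel per (strain, inducer), one curve per well, colored by
#' concentration, with each replicate's in-window maximum marked. The visual
#' check behind the maximum method: an interior peak means the expression
#' fraction was read at a well-defined instant.
#'
#' @param pd A `plate_data` object.
#' @param channel Fluorescence channel.
#' @param window_h Maximum-method search window (marked maxima are restricted
#'   to it).
#' @return A ggplot object.
#' @export
plot_phi_timecourse <- function(pd, channel, window_h = 10) {
  rows <- list(); marks <- list()
  for (g in pd$groups) {
    for (ws in g$series) {
      ph <- heterologous_fraction(ws, channel)
      rows[[length(rows) + 1L]] <- data.frame(
        panel = paste(g$strain, g$inducer), well = ws$well_id,
        concentration = g$concentration, time_h = ph$time_h, phi_h = ph$phi_h,
        stringsAsFactors = FALSE)
      inside <- which(ph$time_h <= window_h)
      i <- inside[which.max(ph$phi_h[inside])]
      marks[[length(marks) + 1L]] <- data.frame(
        panel = paste(g$strain, g$inducer), well = ws$well_id,
        concentration = g$concentration, time_h = ph$time_h[i],
        phi_h = ph$phi_h[i], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows); mk <- do.call(rbind, marks)
  ggplot2::ggplot(df, ggplot2::aes(x = time_h, y = phi_h,
                                   group = well,
                                   colour = factor(concentration))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(data = mk, shape = 21, fill = "white", size = 2) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time after induction (h)", y = "fluorescence / OD600",
                  colour = "inducer conc.") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot: production rate vs growth rate
#'
#' The slope-method plane: specific production rate against specific growth
#' rate, one panel per (strain, inducer), colored by concentration. Points
#' outside the fitted window (trimmed hook points or outside the detected
#' growth phase) are greyed; the fitted regression line is dashed.
#'
#' @param pd A `plate_data` object.
#' @param channel Fluorescence channel.
#' @param maturation_time Hours; maturation shift used for the rates.
#' @param alpha Growth-phase t-test level.
#' @param model Slope model.
#' @param min_points Trimming floor.
#' @return A ggplot object.
#' @export
plot_rate_plane <- function(pd, channel, maturation_time = 0, alpha = 0.05,
                            model = "free_intercept", min_points = 4) {
  pts <- list(); lines <- list()
  for (g in pd$groups) {
    fit <- suppressWarnings(
      fit_slope(g, channel = channel, model = model, min_points = min_points,
                maturation_time = maturation_time, alpha = alpha))
    mask <- fit$growth_phase
    for (ws in g$series) {
      rs <- rate_series(ws, channel, maturation_time)
      n <- nrow(rs$rates)
      inc <- mask$included[seq_len(n)] &
        rs$rates$time_h >= fit$window_start_h & rs$rates$time_h <= fit$window_end_h
      pts[[length(pts) + 1L]] <- data.frame(
        panel = paste(g$strain, g$inducer), concentration = g$concentration,
        mu = rs$rates$mu, rho_h = rs$rates$rho_h, fitted = inc,
        stringsAsFactors = FALSE)
    }
    lines[[length(lines) + 1L]] <- data.frame(
      panel = paste(g$strain, g$inducer), concentration = g$concentration,
      slope = fit$slope, intercept = fit$intercept, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, pts); ln <- do.call(rbind, lines)
  ggplot2::ggplot(df, ggplot2::aes(x = mu, y = rho_h)) +
    ggplot2::geom_point(data = df[!df$fitted, ], colour = "grey70", size = 1) +
    ggplot2::geom_point(data = df[df$fitted, ],
                        ggplot2::aes(colour = factor(concentration)), size = 1.2) +
    ggplot2::geom_abline(data = ln,
                         ggplot2::aes(slope = slope, intercept = intercept,
                                      colour = factor(concentration)),
                         linetype = "dashed") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = expression(mu ~ (h^-1)),
                  y = expression(rho[H] ~ (flu %.% OD^-1 %.% h^-1)),
                  colour = "inducer conc.") +
    ggplot2::theme_minimal()
}
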