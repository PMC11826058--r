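# Programmatic fixtures shared across the suite. Everything is generated in
# code so tests are self-contained and seeds are explicit.

# Exponentially growing well: OD = A*exp(mu0*t); fluorescence accumulates as
# flu = kappa_fh*(OD - OD0), which makes rho_h = kappa_fh * mu exactly under
# the forward-difference estimators.
make_exp_series <- function(well = "W1", mu0 = 0.6, dt = 0.25, t_end = 4,
                            A = 0.1, kappa_fh = 2000) {
  times <- seq(0, t_end, by = dt)
  od <- A * exp(mu0 * times)
  flu <- kappa_fh * (od - od[1])
  well_series(well, times, od, list(gfp = flu))
}

make_exp_group <- function(n_rep = 4, concentration = 50, strain = "toy",
                           kappa_fh = 2000, ...) {
  series <- lapply(seq_len(n_rep), function(r)
    make_exp_series(well = sprintf("W%d", r), kappa_fh = kappa_fh, ...))
  condition_group(strain, "IPTG", concentration, series)
}

# Logistic growth so the forward-difference mu varies over time (an
# exponential gives constant mu: a degenerate regression design). Since
# flu = kappa_fh*(OD - OD0), rho_h = kappa_fh * mu holds exactly for any
# growth shape.
make_logistic_group <- function(n_rep = 4, concentration = 50, strain = "toy",
                                kappa_fh = 2000, r = 0.8, K = 2, A = 0.1,
                                dt = 0.25, t_end = 8) {
  times <- seq(0, t_end, by = dt)
  od <- K / (1 + (K - A) / A * exp(-r * times))
  series <- lapply(seq_len(n_rep), function(rep)
    well_series(sprintf("W%d", rep), times, od,
                list(gfp = kappa_fh * (od - od[1]))))
  condition_group(strain, "IPTG", concentration, series)
}

# Group whose phi_h(t) = flu/OD peaks at prescribed per-replicate heights
# (triangular peak at t = 2 h, OD held at 1 so phi_h is the flu trace).
make_peak_group <- function(peaks, concentration = 50, strain = "toy",
                            t_peak = 2, t_end = 5, dt = 0.25) {
  times <- seq(0, t_end, by = dt)
  series <- lapply(seq_along(peaks), function(r) {
    shape <- pmax(0, 1 - abs(times - t_peak) / t_peak)
    well_series(sprintf("W%d", r), times, rep(1, length(times)),
                list(gfp = peaks[r] * shape))
  })
  condition_group(strain, "IPTG", concentration, series)
}

# Noise-free simulator configuration for oracle comparisons.
sim_quiet <- function(n_replicates = 2, ...) {
  sim_config(noise_od = 0, noise_flu = 0, n_replicates = n_replicates, ...)
}

# Tidy + layout data.frames for a factorial design with synthetic growth
# curves (cheap closed forms, no ODE integration).
make_factorial_frames <- function(n_strain = 5, n_conc = 6, n_rep = 4,
                                  n_time = 64, dt = 0.25) {
  times <- seq(0, by = dt, length.out = n_time)
  data_rows <- list(); layout_rows <- list()
  for (s in seq_len(n_strain)) for (ci in seq_len(n_conc)) for (r in seq_len(n_rep)) {
    wid <- sprintf("S%dC%dR%d", s, ci, r)
    od <- 0.1 * exp(0.5 * times)
    flu <- ci * 100 * (od - od[1])
    df <- data.frame(time_h = times, well = wid, od600 = od, flu_gfp = flu,
                     stringsAsFactors = FALSE)
    data_rows[[length(data_rows) + 1L]] <- df
    layout_rows[[length(layout_rows) + 1L]] <- data.frame(
      well = wid, strain = sprintf("strain%d", s), inducer = "IPTG",
      concentration = c(0, 10, 25, 50, 100, 250)[ci], conc_unit = "uM",
      replicate = r, is_blank = FALSE, stringsAsFactors = FALSE)
  }
  list(data = do.call(rbind, data_rows), layout = do.call(rbind, layout_rows))
}
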