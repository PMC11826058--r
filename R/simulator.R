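#' Configure the proteome-allocation batch-culture simulator
#'
#' The simulator realizes a coarse-grained biosynthesis-allocation model of a
#' batch microtiter culture. Total protein is partitioned into four proteome
#' fractions: ribosomal/biomass producers (`phi_R`), nutrient fixators
#' (`phi_C`), constant structural proteins (`phi_Q`) and the heterologous
#' reporter (`phi_H`). Nutrient `S` is fixed into anabolic precursor `x` by
#' the fixator fraction at Monod rate `Y*phi_C*S/(K_S+S)`; precursor drives
#' total biosynthesis at rate `rho = k_rho*phi_R*x/(K_x+x)`. Every fraction
#' obeys
#' \deqn{d\varphi_i/dt = \rho\,(f_i - \varphi_i),}
#' where the expression fractions \eqn{f_i} encode regulation: precursor
#' stimulates ribosomal expression and represses fixator expression (the
#' remainder \eqn{1 - f_Q - f_H} is split by \eqn{a = x/(alloc_{Kx}+x)}),
#' \eqn{f_Q} is constant, and \eqn{f_H(I)} follows a reduced Hill law in the
#' internal inducer concentration. Growth equals biosynthesis
#' (\eqn{\mu \equiv \rho}; protein is taken proportional to biomass), so the
#' simplex \eqn{\sum_i \varphi_i = 1} is conserved.
#'
#' Optional features reproduce the qualitative failure modes the analysis
#' methods must cope with: a first-order inducer-import lag
#' (`equilibration_tau > 0`) produces the early curved "hook" in
#' production-vs-growth plots, and a nutrient-coupled production arrest
#' (`arrest_S > 0` linearly ramps \eqn{f_H} to zero as S falls below the
#' threshold) makes production cease before growth does, yielding a positive
#' x-axis intercept `b` and an interior maximum of \eqn{\varphi_H}.
#'
#' Default rate constants give a culture that ramps out of a short lag
#' (inoculum precursor `x0` is low, as for cells resuspended from a starved
#' overnight culture), grows at about 0.6/h, and exhausts its nutrient within
#' roughly 7-9 h of the 16 h run — the regime in which both estimation
#' methods are defined.
#'
#' @param f_Q Constant structural expression fraction (0-1).
#' @param hill_H,hill_kI,hill_n Ground-truth Hill parameters of
#'   \eqn{f_H(I)} on the fraction scale (`hill_H + f_Q <= 1`); `hill_kI` in
#'   the same unit as the inducer concentrations (default uM).
#' @param Y Nutrient fixation rate constant (precursor per hour per unit
#'   `phi_C` at saturating S).
#' @param K_S Nutrient half-saturation.
#' @param k_rho Maximal biosynthesis rate (per hour per unit `phi_R`).
#' @param K_x Precursor half-saturation of biosynthesis.
#' @param alloc_Kx Precursor level at which ribosomal and fixator expression
#'   split the non-Q, non-H remainder equally.
#' @param S0 Initial nutrient (sized so exhaustion occurs mid-run).
#' @param M0 Initial biomass (OD-proportional model units).
#' @param x0 Initial precursor per unit biomass.
#' @param c_od OD units per biomass unit.
#' @param kappa_flu Fluorescence units per (phi_H x biomass).
#' @param maturation_time Reporter maturation time constant in hours
#'   (first-order convolution of the signal; 0 = instantaneous).
#' @param noise_od,noise_flu Multiplicative lognormal sigma applied per
#'   observation (plate-reader noise scales with signal).
#' @param dt_sample Sampling interval in hours (default 15 min).
#' @param t_end Culture duration in hours.
#' @param n_replicates Replicate wells per condition.
#' @param seed Base RNG seed for observation noise.
#' @param equilibration_tau Inducer import lag time constant in hours (0
#'   disables the hook).
#' @param arrest_S Nutrient threshold under which reporter expression ramps
#'   off (0 disables; produces CymR-like early production arrest).
#' @param n_substeps RK4 substeps per sampling interval.
#' @param phi0 Optional named vector `c(R=,C=,Q=,H=)` of initial fractions
#'   (must sum to 1); by default `phi_Q = f_Q`, `phi_H = 0` and the remainder
#'   is split by the allocation rule at `x0`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(f_Q = 0.45, hill_H = 0.12, hill_kI = 50, hill_n = 2.5,
                       Y = 5, K_S = 0.25, k_rho = 2.5, K_x = 0.3,
                       alloc_Kx = 0.3, S0 = 10, M0 = 0.1, x0 = 0.05,
                       c_od = 1, kappa_flu = 8e4, maturation_time = 0,
                       noise_od = 0.01, noise_flu = 0.02,
                       dt_sample = 0.25, t_end = 16, n_replicates = 4,
                       seed = 1, equilibration_tau = 0, arrest_S = 0,
                       n_substeps = 10, phi0 = NULL) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  if (f_Q <= 0 || f_Q >= 1) bs_usage_error("f_Q must lie strictly between 0 and 1")
  if (hill_H <= 0 || hill_H + f_Q > 1)
    bs_usage_error("hill_H must be positive with hill_H + f_Q <= 1")
  for (p in c("Y", "K_S", "k_rho", "K_x", "alloc_Kx", "S0", "M0", "c_od",
              "kappa_flu", "dt_sample"))
    if (cfg[[p]] <= 0) bs_usage_error(sprintf("%s must be > 0", p))
  if (dt_sample > t_end) bs_usage_error("dt_sample must not exceed t_end")
  if (!is.null(phi0)) {
    if (!all(c("R", "C", "Q", "H") %in% names(phi0)) ||
        abs(sum(phi0) - 1) > 1e-9 || any(phi0 < 0))
      bs_usage_error("phi0 must be a named non-negative vector c(R=,C=,Q=,H=) summing to 1")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> f_Q = %g, f_H(I): Hill(H = %g, k_I = %g, n = %g)\n",
                     "  S0 = %g, M0 = %g, sampling %g h over %g h, %d replicates, seed %g\n"),
              x$f_Q, x$hill_H, x$hill_kI, x$hill_n, x$S0, x$M0,
              x$dt_sample, x$t_end, as.integer(x$n_replicates), x$seed))
  invisible(x)
}

# Effective expression fraction of the reporter, including inducer import lag
# and nutrient-coupled production arrest.
sim_f_H <- function(cfg, I, I_int, S) {
  f <- hill_eval(I * I_int, cfg$hill_H, cfg$hill_kI, cfg$hill_n, form = "reduced")
  if (cfg$arrest_S > 0) f <- f * min(1, max(0, S) / cfg$arrest_S)
  f
}

# State vector layout: M, S, x, phi_R, phi_C, phi_Q, phi_H, I_int, G
sim_init_state <- function(cfg, I) {
  I_int0 <- if (cfg$equilibration_tau > 0) 0 else 1
  if (is.null(cfg$phi0)) {
    fH0 <- sim_f_H(cfg, I, I_int0, cfg$S0)
    a <- cfg$x0 / (cfg$alloc_Kx + cfg$x0)
    rem <- 1 - cfg$f_Q - 0        # phi_H starts at 0; remainder split by a
    phi <- c(R = rem * a, C = rem * (1 - a), Q = cfg$f_Q, H = 0)
  } else phi <- cfg$phi0[c("R", "C", "Q", "H")]
  c(M = cfg$M0, S = cfg$S0, x = cfg$x0,
    phi_R = unname(phi[["R"]]), phi_C = unname(phi[["C"]]),
    phi_Q = unname(phi[["Q"]]), phi_H = unname(phi[["H"]]),
    I_int = I_int0, G = cfg$kappa_flu * phi[["H"]] * cfg$M0)
}

sim_deriv <- function(y, cfg, I) {
  M <- y[1L]; S <- max(y[2L], 0); x <- max(y[3L], 0)
  phi_R <- y[4L]; phi_C <- y[5L]; phi_Q <- y[6L]; phi_H <- y[7L]
  I_int <- if (cfg$equilibration_tau > 0) y[8L] else 1
  rho <- cfg$k_rho * phi_R * x / (cfg$K_x + x)
  upt <- cfg$Y * phi_C * S / (cfg$K_S + S)
  fH <- sim_f_H(cfg, I, I_int, S)
  a <- x / (cfg$alloc_Kx + x)
  rem <- 1 - cfg$f_Q - fH
  fR <- rem * a
  fC <- rem * (1 - a)
  c(rho * M,                                  # dM: mu = rho
    -upt * M,                                 # dS
    upt - rho - rho * x,                      # dx: fixation - consumption - dilution
    rho * (fR - phi_R),
    rho * (fC - phi_C),
    rho * (cfg$f_Q - phi_Q),
    rho * (fH - phi_H),
    if (cfg$equilibration_tau > 0) (1 - I_int) / cfg$equilibration_tau else 0,
    if (cfg$maturation_time > 0)
      (cfg$kappa_flu * phi_H * M - y[9L]) / cfg$maturation_time else 0)
}

rk4_step <- function(y, cfg, I, h) {
  k1 <- sim_deriv(y, cfg, I)
  k2 <- sim_deriv(y + h / 2 * k1, cfg, I)
  k3 <- sim_deriv(y + h / 2 * k2, cfg, I)
  k4 <- sim_deriv(y + h * k3, cfg, I)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Advance the allocation model by one step
#'
#' Integrates the model ODE system with fixed-step fourth-order Runge-Kutta
#' substeps. If a step drives any state negative (beyond roundoff) it is
#' retried once with a 10x finer substep before failing.
#'
#' @param state Named state vector as produced by [step_model()] or
#'   internally (`M`, `S`, `x`, `phi_R`, `phi_C`, `phi_Q`, `phi_H`, `I_int`,
#'   `G`).
#' @param config A [sim_config()].
#' @param I External inducer concentration.
#' @param dt Time increment in hours (integrated with substeps of at most
#'   `dt_sample / n_substeps`).
#' @return The advanced named state vector.
#' @export
step_model <- function(state, config, I, dt) {
  h_max <- config$dt_sample / config$n_substeps
  n_sub <- max(1L, ceiling(dt / h_max - 1e-9))
  h <- dt / n_sub
  y <- state
  for (i in seq_len(n_sub)) {
    y1 <- rk4_step(y, config, I, h)
    if (min(y1) < -1e-9) {
      # stiff spot (e.g. nutrient exhaustion): retry once at h/10
      y1 <- y
      for (j in 1:10) y1 <- rk4_step(y1, config, I, h / 10)
      if (min(y1) < -1e-9)
        bs_error(sprintf("integration step failed near t-step %d (state went negative)", i),
                 "bs_step_error")
    }
    y1[y1 < 0] <- 0   # clip roundoff-scale negatives
    y <- y1
  }
  y
}

#' Simulate a noiseless model trajectory
#'
#' Integrates the allocation model for one inducer concentration and records
#' the full state, the instantaneous effective expression fraction `f_H` and
#' the biosynthesis rate `rho` at every output time. This is the ground truth
#' against which the estimators are validated.
#'
#' @inheritParams step_model
#' @param config A [sim_config()].
#' @param dt_out Output grid spacing (defaults to `dt_sample`; use a finer
#'   grid to resolve fast transients such as the arrest-driven peak).
#' @return A data.frame with columns `time_h`, `M`, `S`, `x`, `phi_R`,
#'   `phi_C`, `phi_Q`, `phi_H`, `I_int`, `G`, `f_H`, `rho`.
#' @export
simulate_trajectory <- function(config, I, dt_out = config$dt_sample) {
  n_out <- floor(config$t_end / dt_out + 1e-9)
  times <- seq(0, by = dt_out, length.out = n_out + 1L)
  y <- sim_init_state(config, I)
  out <- matrix(NA_real_, nrow = n_out + 1L, ncol = length(y),
                dimnames = list(NULL, names(y)))
  fH <- rho <- numeric(n_out + 1L)
  record <- function(i, y) {
    out[i, ] <<- y
    I_int <- if (config$equilibration_tau > 0) y[["I_int"]] else 1
    fH[i] <<- sim_f_H(config, I, I_int, y[["S"]])
    rho[i] <<- config$k_rho * y[["phi_R"]] * y[["x"]] / (config$K_x + y[["x"]])
  }
  record(1L, y)
  for (i in seq_len(n_out)) {
    y <- step_model(y, config, I, dt_out)
    record(i + 1L, y)
  }
  df <- as.data.frame(out)
  df <- cbind(time_h = times, df, f_H = fH, rho = rho)
  if (config$maturation_time <= 0) df$G <- config$kappa_flu * df$phi_H * df$M
  df
}

#' Simulate replicate plate-reader wells for one condition
#'
#' Samples the noiseless trajectory every `dt_sample` hours, converts to
#' observables (`OD = c_od * M`; fluorescence is `kappa_flu * phi_H * M`,
#' first-order-convolved with the maturation time when one is set) and
#' applies independent multiplicative lognormal observation noise per
#' replicate. Identical seeds give bit-identical output.
#'
#' @inheritParams simulate_trajectory
#' @param seed RNG seed for the observation noise (defaults to
#'   `config$seed`); the RNG state of the caller is left untouched.
#' @param channel Name given to the fluorescence channel.
#' @return A list of `n_replicates` [well_series()] objects.
#' @export
simulate_culture <- function(config, I, seed = config$seed, channel = "gfp") {
  traj <- simulate_trajectory(config, I)
  od_true <- config$c_od * traj$M
  flu_true <- traj$G
  m <- nrow(traj)
  with_seed(seed, {
    lapply(seq_len(config$n_replicates), function(r) {
      od <- od_true * exp(config$noise_od * stats::rnorm(m))
      flu <- flu_true * exp(config$noise_flu * stats::rnorm(m))
      well_series(sprintf("R%d", r), traj$time_h, od,
                  stats::setNames(list(flu), channel))
    })
  })
}

#' Simulate a full titration experiment
#'
#' Generates the tidy data + layout CSV dialect of [read_tidy_csv()] for a
#' titration of one or more strains across inducer concentrations, together
#' with a ground-truth table of the generating expression fractions. Noise
#' seeds are split deterministically from `config$seed` per strain and
#' concentration, so a titration is reproducible from a single seed.
#'
#' @param config A [sim_config()] (the base configuration).
#' @param concentrations Numeric vector (>= 3) of external inducer
#'   concentrations.
#' @param strains Optional named list of per-strain overrides to `config`
#'   fields (e.g. `list(BL21 = list(), MG1655 = list(k_rho = 2))`); by default
#'   a single strain `"sim"` with no overrides.
#' @param inducer Inducer label written to the layout.
#' @param conc_unit Concentration unit recorded in the layout.
#' @param dir Optional directory; when given, `data.csv`, `layout.csv` and
#'   `truth.csv` are written there.
#' @param channel Fluorescence channel name.
#' @param n_blanks Number of blank wells (constant medium background, noisy)
#'   appended to the dataset.
#' @return A list with `data` (tidy data.frame), `layout`, `truth` (one row
#'   per strain x concentration with the generating `f_h` on the fraction and
#'   fluorescence/OD scales, plus the Hill parameters) and `config`.
#' @export
simulate_titration <- function(config, concentrations, strains = NULL,
                               inducer = "IPTG", conc_unit = "uM", dir = NULL,
                               channel = "gfp", n_blanks = 0) {
  if (length(concentrations) < 3L)
    bs_usage_error("a titration needs at least 3 concentrations")
  if (is.null(strains)) strains <- list(sim = list())
  data_rows <- list()
  layout_rows <- list()
  truth_rows <- list()
  for (si in seq_along(strains)) {
    sname <- names(strains)[si]
    cfg_s <- utils::modifyList(config, strains[[si]])
    class(cfg_s) <- "sim_config"
    for (ci in seq_along(concentrations)) {
      I <- concentrations[ci]
      seed_ci <- (config$seed + 99991L * si + 101L * ci) %% 2147483647L
      wells <- simulate_culture(cfg_s, I, seed = seed_ci, channel = channel)
      for (r in seq_along(wells)) {
        ws <- wells[[r]]
        wid <- sprintf("S%02dC%02dR%02d", si, ci, r)
        df <- data.frame(time_h = ws$times, well = wid, od600 = ws$od600,
                         stringsAsFactors = FALSE)
        df[[paste0("flu_", channel)]] <- ws$fluorescence[[channel]]
        data_rows[[length(data_rows) + 1L]] <- df
        layout_rows[[length(layout_rows) + 1L]] <- data.frame(
          well = wid, strain = sname, inducer = inducer, concentration = I,
          conc_unit = conc_unit, replicate = r, is_blank = FALSE,
          stringsAsFactors = FALSE)
      }
      fh <- hill_eval(I, cfg_s$hill_H, cfg_s$hill_kI, cfg_s$hill_n, form = "reduced")
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        strain = sname, inducer = inducer, concentration = I,
        conc_unit = conc_unit, f_h_fraction = fh,
        f_h_phi = cfg_s$kappa_flu * fh, hill_H = cfg_s$hill_H,
        hill_kI = cfg_s$hill_kI, hill_n = cfg_s$hill_n,
        kappa_flu = cfg_s$kappa_flu, stringsAsFactors = FALSE)
    }
  }
  if (n_blanks > 0) {
    times <- seq(0, config$t_end, by = config$dt_sample)
    with_seed((config$seed + 777L) %% 2147483647L, {
      for (b in seq_len(n_blanks)) {
        wid <- sprintf("BLK%02d", b)
        od <- 0.04 * exp(config$noise_od * stats::rnorm(length(times)))
        df <- data.frame(time_h = times, well = wid, od600 = od,
                         stringsAsFactors = FALSE)
        df[[paste0("flu_", channel)]] <- numeric(length(times))
        data_rows[[length(data_rows) + 1L]] <- df
        layout_rows[[length(layout_rows) + 1L]] <- data.frame(
          well = wid, strain = "blank", inducer = "none", concentration = 0,
          conc_unit = conc_unit, replicate = b, is_blank = TRUE,
          stringsAsFactors = FALSE)
      }
    })
  }
  out <- list(data = do.call(rbind, data_rows),
              layout = do.call(rbind, layout_rows),
              truth = do.call(rbind, truth_rows),
              config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_csv_exact(out$data, file.path(dir, "data.csv"))
    write_csv_exact(out$layout, file.path(dir, "layout.csv"))
    write_csv_exact(out$truth, file.path(dir, "truth.csv"))
    out$paths <- file.path(dir, c("data.csv", "layout.csv", "truth.csv"))
  }
  out
}
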