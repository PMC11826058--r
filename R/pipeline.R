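#' Assemble a run configuration
#'
#' A run is driven either by real data (tidy data + layout CSV paths) or by a
#' simulation block — exactly one of the two. All analysis settings live here
#' so that a run is reproducible from the configuration and seed alone.
#'
#' @param data,layout Paths to the tidy data and layout CSVs (real-data runs).
#' @param simulation List for simulated runs: `concentrations` (numeric) plus
#'   optional [sim_config()] field overrides and optional `strains` (named
#'   list of per-strain overrides).
#' @param out_dir Output directory.
#' @param channel Fluorescence channel to analyse.
#' @param maturation_time Hours; reporter maturation shift for the rate
#'   computation (e.g. 1 for RFP, 0 for fast-maturing GFP).
#' @param alpha Growth-phase t-test significance level.
#' @param window_h Maximum-method search window (hours).
#' @param min_points Minimum points retained by the slope-fit trimming loop.
#' @param slope_model `"free_intercept"` or `"through_origin"`.
#' @param hill_form `"reduced"` or `"full"`.
#' @param blank_mode `"none"` or `"mean_blank"`.
#' @param r2_floor Quality floor for slope fits.
#' @param seed Seed controlling all randomness of the run.
#' @param plots Whether to render diagnostic plots (numbers never depend on
#'   them).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, data = NULL, layout = NULL, simulation = NULL,
                       channel = "gfp", maturation_time = 0, alpha = 0.05,
                       window_h = 10, min_points = 4,
                       slope_model = c("free_intercept", "through_origin"),
                       hill_form = c("reduced", "full"),
                       blank_mode = c("none", "mean_blank"),
                       r2_floor = 0.9, seed = 1, plots = TRUE) {
  cfg <- list(out_dir = out_dir, data = data, layout = layout,
              simulation = simulation, channel = channel,
              maturation_time = maturation_time, alpha = alpha,
              window_h = window_h, min_points = min_points,
              slope_model = match.arg(slope_model),
              hill_form = match.arg(hill_form),
              blank_mode = match.arg(blank_mode),
              r2_floor = r2_floor, seed = seed, plots = plots)
  has_real <- !is.null(data) || !is.null(layout)
  has_sim <- !is.null(simulation)
  if (has_real == has_sim)
    bs_usage_error("exactly one of {data+layout, simulation} must be given")
  if (has_real && (is.null(data) || is.null(layout)))
    bs_usage_error("real-data runs need both 'data' and 'layout' paths")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [run_config()]'s
#'   arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    bs_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             class(e)[1L])
  })
}

#' Run the full characterization pipeline
#'
#' Sequences the whole analysis: input (read or simulate), optional blank
#' correction, rate computation, the maximum method and the slope method per
#' condition, Hill fits per (strain, inducer) and method, and the
#' method-comparison report. Writes `rates.csv`, `max_method.csv`,
#' `slope_method.csv`, `hill_params.json`, `method_comparison.csv`, a run
#' `manifest.json` (configuration, its MD5 hash, seed, versions) and — unless
#' disabled — the two diagnostic figures (phi_H vs time with marked maxima;
#' rho_H vs mu with trimmed points greyed). CSV/JSON outputs are
#' byte-identical across reruns with the same configuration and seed.
#'
#' @param config A `run_config`, or the path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with every intermediate result (groups, rates,
#'   dose-response tables, Hill fits, comparisons, manifest).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  flags <- character()

  pd <- stage("input", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      conc <- sim$concentrations
      if (is.null(conc)) bs_usage_error("simulation block needs 'concentrations'")
      strains <- sim$strains
      over <- sim[setdiff(names(sim), c("concentrations", "strains"))]
      scfg <- do.call(sim_config, c(over, list(seed = config$seed)))
      tt <- simulate_titration(scfg, conc, strains = strains,
                               dir = file.path(out, "sim"),
                               channel = config$channel)
      read_tidy_csv(file.path(out, "sim", "data.csv"),
                    file.path(out, "sim", "layout.csv"))
    } else {
      read_tidy_csv(config$data, config$layout)
    }
  })
  pd <- stage("blank_correction", blank_correct(pd, mode = config$blank_mode))

  rates <- stage("rates", rates_table(pd, config$channel, config$maturation_time))
  write_csv_exact(rates, file.path(out, "rates.csv"))

  meta <- data.frame(
    strain = vapply(pd$groups, `[[`, "", "strain"),
    inducer = vapply(pd$groups, `[[`, "", "inducer"),
    stringsAsFactors = FALSE)
  combos <- unique(meta)

  max_rows <- list(); slope_rows <- list()
  hill_out <- list(); cmp_rows <- list()
  dr_pairs <- list()
  for (k in seq_len(nrow(combos))) {
    s <- combos$strain[k]; ind <- combos$inducer[k]
    idx <- which(meta$strain == s & meta$inducer == ind)
    groups <- pd$groups[idx]
    label <- paste(s, ind, sep = "/")

    mf <- stage(paste0("max_method[", label, "]"),
                lapply(groups, find_phi_max, channel = config$channel,
                       window_h = config$window_h))
    sf <- stage(paste0("slope_method[", label, "]"),
                lapply(groups, fit_slope, channel = config$channel,
                       model = config$slope_model, min_points = config$min_points,
                       maturation_time = config$maturation_time,
                       alpha = config$alpha))
    for (m in mf) max_rows[[length(max_rows) + 1L]] <- data.frame(
      strain = m$strain, inducer = m$inducer, concentration = m$concentration,
      conc_unit = m$conc_unit, f_h_max = m$phi_max_mean, variance = m$phi_max_var,
      n = m$n_replicates, t_max_mean = mean(m$t_max),
      boundary_flag = m$boundary_flag, stringsAsFactors = FALSE)
    for (f in sf) slope_rows[[length(slope_rows) + 1L]] <- data.frame(
      strain = f$strain, inducer = f$inducer, concentration = f$concentration,
      conc_unit = f$conc_unit, slope = f$slope, slope_se = f$slope_se,
      intercept = f$intercept, b = f$b, r_squared = f$r_squared,
      window_start_h = f$window_start_h, window_end_h = f$window_end_h,
      n_points = f$n_points, model = f$model, stringsAsFactors = FALSE)

    n_conc <- length(unique(vapply(groups, `[[`, 0, "concentration")))
    if (n_conc < 3L) {
      flags <- c(flags, sprintf("hill_skipped[%s]: only %d concentration(s)", label, n_conc))
      next
    }
    dr_max <- max_dose_response(mf)
    dr_slope <- suppressWarnings(slope_dose_response(sf, r2_floor = config$r2_floor))
    hp_max <- stage(paste0("fit_hill_max[", label, "]"),
                    fit_hill(dr_max, form = config$hill_form))
    hp_slope <- stage(paste0("fit_hill_slope[", label, "]"),
                      fit_hill(dr_slope, form = config$hill_form))
    hill_out[[label]] <- list(maximum = unclass(hp_max), slope = unclass(hp_slope))
    cmp <- compare_methods(hp_max, hp_slope)
    cmp$strain <- s; cmp$inducer <- ind
    cmp_rows[[length(cmp_rows) + 1L]] <- cmp
    dr_pairs[[label]] <- list(maximum = dr_max, slope = dr_slope,
                              max_fractions = mf, slope_fits = sf)
  }

  if (length(max_rows))
    write_csv_exact(do.call(rbind, max_rows), file.path(out, "max_method.csv"))
  if (length(slope_rows))
    write_csv_exact(do.call(rbind, slope_rows), file.path(out, "slope_method.csv"))
  jsonlite::write_json(hill_out, file.path(out, "hill_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(cmp_rows))
    write_csv_exact(do.call(rbind, cmp_rows), file.path(out, "method_comparison.csv"))

  if (isTRUE(config$plots)) {
    stage("plots", {
      grDevices::pdf(NULL) # never leave a stray device on error
      grDevices::dev.off()
      ggplot2::ggsave(file.path(out, "phi_timecourse.pdf"),
                      plot_phi_timecourse(pd, config$channel, config$window_h),
                      width = 9, height = 6)
      ggplot2::ggsave(file.path(out, "rate_plane.pdf"),
                      plot_rate_plane(pd, config$channel, config$maturation_time,
                                      config$alpha, config$slope_model,
                                      config$min_points),
                      width = 9, height = 6)
    })
  }

  cfg_path <- file.path(out, "run_config.yaml")
  cfg_yaml <- config
  class(cfg_yaml) <- NULL
  yaml::write_yaml(cfg_yaml, cfg_path)
  manifest <- list(
    config = cfg_yaml,
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    n_groups = length(pd$groups),
    flags = as.list(flags),
    versions = list(biosensr = as.character(utils::packageVersion("biosensr")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(plate = pd, rates = rates,
                 max_method = if (length(max_rows)) do.call(rbind, max_rows),
                 slope_method = if (length(slope_rows)) do.call(rbind, slope_rows),
                 hill = hill_out, comparison = if (length(cmp_rows)) do.call(rbind, cmp_rows),
                 dose_response = dr_pairs, manifest = manifest))
}
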