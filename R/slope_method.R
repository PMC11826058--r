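#' Detect the growth phase by per-time-point t-tests
#'
#' For every forward-difference time point, tests whether the replicate
#' specific growth rates differ significantly from zero (two-sided one-sample
#' t-test). A time point belongs to the growth phase when p < `alpha` *and*
#' the replicate mean is positive — the significance test read jointly with
#' the growth-phase definition \eqn{\mu > 0}.
#'
#' With a single replicate a t-test is impossible; the detector falls back to
#' a fixed threshold `mu > mu_min` with a warning.
#'
#' @param group A [condition_group()] with replicate wells on a shared grid.
#' @param alpha Significance level (default 0.05).
#' @param mu_min Fallback threshold (per hour) used when N = 1.
#' @return An object of class `growth_phase_mask`: `times`, logical
#'   `included`, per-point `p_values`, replicate mean `mu_mean`, and `alpha`.
#' @export
detect_growth_phase <- function(group, alpha = 0.05, mu_min = 0.05) {
  stopifnot(inherits(group, "condition_group"))
  mus <- lapply(group$series, specific_growth_rate)
  times <- mus[[1L]]$time_h
  mu_mat <- vapply(mus, `[[`, numeric(length(times)), "mu")
  mu_mat <- matrix(mu_mat, nrow = length(times))
  mu_mean <- rowMeans(mu_mat)
  n_rep <- ncol(mu_mat)

  if (n_rep < 2L) {
    warning("single replicate: growth phase from threshold mu > mu_min, no t-test possible")
    p <- rep(NA_real_, length(times))
    included <- mu_mat[, 1L] > mu_min
  } else {
    p <- apply(mu_mat, 1L, function(x) {
      s <- stats::sd(x)
      if (s == 0) {
        # degenerate: all replicates identical; zero mean carries no evidence
        if (mean(x) == 0) 1 else 0
      } else {
        stats::t.test(x, mu = 0)$p.value
      }
    })
    included <- (p < alpha) & (mu_mean > 0)
  }
  structure(list(times = times, included = included, p_values = p,
                 mu_mean = mu_mean, alpha = alpha, n_replicates = n_rep),
            class = "growth_phase_mask")
}

#' @export
print.growth_phase_mask <- function(x, ...) {
  rng <- range(x$times[x$included])
  cat(sprintf("<growth_phase_mask> %d/%d points in growth phase (%.2f-%.2f h), alpha = %g\n",
              sum(x$included), length(x$included), rng[1L], rng[2L], x$alpha))
  invisible(x)
}

# Closed-form R^2 for every prefix-trim depth in one O(n) pass, using suffix
# sums. Matches summary.lm()$r.squared: centered for the free-intercept model,
# uncentered for regression through the origin.
trim_scan_r2 <- function(x, y, min_points, origin) {
  n <- length(x)
  rs <- function(v) rev(cumsum(rev(v)))   # suffix sums
  Sx <- rs(x); Sy <- rs(y); Sxx <- rs(x^2); Syy <- rs(y^2); Sxy <- rs(x * y)
  depths <- 0:(n - min_points)
  vapply(depths, function(d) {
    i <- d + 1L
    m <- n - d
    if (origin) {
      den <- Sxx[i] * Syy[i]
      if (den <= 0) return(0)
      min(1, Sxy[i]^2 / den)
    } else {
      sxx <- Sxx[i] - Sx[i]^2 / m
      syy <- Syy[i] - Sy[i]^2 / m
      if (sxx <= 0 || syy <= 0) return(0)
      min(1, (Sxy[i] - Sx[i] * Sy[i] / m)^2 / (sxx * syy))
    }
  }, 0)
}

#' Fit the expression fraction as the slope of production vs growth rate
#'
#' During balanced growth the specific production rate is proportional to the
#' specific growth rate, \eqn{\rho_H(t) = f_H \cdot \mu(t)}, so the expression
#' fraction is the slope of an ordinary least-squares regression of
#' \eqn{\rho_H} on \eqn{\mu}. Immediately after induction the points trace a
#' curved "hook" while the inducer equilibrates; the fit therefore removes the
#' chronologically earliest remaining point, refits, and keeps the window with
#' the maximal \eqn{R^2} (global argmax over all prefix-trim depths, at least
#' `min_points` points retained; ties within 1e-12 resolved toward more
#' points).
#'
#' With `model = "free_intercept"` the x-axis intercept
#' \eqn{b = -intercept/slope} captures production ceasing before growth does
#' (\eqn{\rho_H = f_H (\mu - b)}); `model = "through_origin"` forces the line
#' through zero, appropriate for reporters that accumulate as long as the
#' culture grows.
#'
#' @param object A [condition_group()] (rates are computed and pooled across
#'   replicates, restricted to the detected growth phase), or a numeric vector
#'   of growth rates for the low-level interface.
#' @param ... Passed between methods.
#' @return An object of class `slope_fit`: `slope` (the \eqn{f_H} estimate,
#'   fluorescence/OD units), `slope_se`, `intercept`, `b`, `r_squared`,
#'   `window_start_h`/`window_end_h`, `n_points`, `n_trimmed`, `model`.
#' @export
fit_slope <- function(object, ...) UseMethod("fit_slope")

#' @rdname fit_slope
#' @param rho_h Specific production rates paired with `object` (low-level
#'   interface).
#' @param times Chronological ordering key for the paired points.
#' @param model `"free_intercept"` or `"through_origin"`.
#' @param min_points Minimum points that must remain after trimming.
#' @export
fit_slope.default <- function(object, rho_h, times = seq_along(object),
                              model = c("free_intercept", "through_origin"),
                              min_points = 4, ...) {
  model <- match.arg(model)
  mu <- as.numeric(object)
  stopifnot(length(rho_h) == length(mu), length(times) == length(mu))
  ord <- order(times)
  mu <- mu[ord]; rho_h <- rho_h[ord]; times <- times[ord]
  n <- length(mu)
  if (n < min_points)
    bs_insufficient_data_error(sprintf(
      "slope fit needs at least %d growth-phase points, got %d", min_points, n))

  origin <- model == "through_origin"
  r2_all <- trim_scan_r2(mu, rho_h, min_points, origin)
  # trim whole time points: candidate depths start at a new (unique) time
  starts <- which(!duplicated(times))
  starts <- starts[starts <= length(r2_all)]
  r2 <- r2_all[starts]
  # remove the earliest time point while doing so still increases R^2: the
  # first local maximum. (A global argmax is upward-biased toward tiny late
  # windows whose R^2 is high by chance under observation noise.)
  best <- 1L
  while (best < length(r2) && r2[best + 1L] > r2[best] + 1e-12) best <- best + 1L
  keep <- starts[best]:n    # all points at trimmed times removed

  fml <- if (origin) rho_h[keep] ~ mu[keep] + 0 else rho_h[keep] ~ mu[keep]
  fit <- stats::lm(fml)
  # summary.lm warns on zero-residual (exact) fits; those are legitimate here
  cf <- suppressWarnings(summary(fit))$coefficients
  if (nrow(cf) < (if (origin) 1L else 2L))
    bs_insufficient_data_error("growth rates are constant over the window; slope is unidentifiable")
  slope <- cf[if (origin) 1L else 2L, 1L]
  slope_se <- cf[if (origin) 1L else 2L, 2L]
  intercept <- if (origin) 0 else cf[1L, 1L]
  b <- 0
  if (!origin) {
    if (slope > 0) {
      b <- -intercept / slope
    } else {
      warning("non-positive slope: x-axis intercept b undefined, reported as 0")
    }
  }
  structure(list(slope = slope, slope_se = slope_se, intercept = intercept,
                 b = b, r_squared = r2[best],
                 window_start_h = times[keep[1L]], window_end_h = times[n],
                 n_points = length(keep), n_trimmed = starts[best] - 1L,
                 model = model), class = "slope_fit")
}

#' @rdname fit_slope
#' @param channel Fluorescence channel name.
#' @param maturation_time Maturation delay in hours for the reporter channel.
#' @param alpha Significance level for growth-phase detection.
#' @param mu_min Single-replicate fallback threshold for growth-phase
#'   detection.
#' @param pool How replicates enter the regression. `"replicate_mean"` (the
#'   default) averages \eqn{\mu} and \eqn{\rho_H} across replicates at each
#'   time point and regresses the mean curves — one point per time point,
#'   which suppresses the point-level noise in the forward-difference rates
#'   (noise in \eqn{\mu} sits on the regressor and would otherwise attenuate
#'   the slope). `"pooled"` regresses every replicate's points in one fit;
#'   `"per_replicate"` fits each replicate separately and reports the mean
#'   slope with the standard error of the mean.
#' @export
fit_slope.condition_group <- function(object, channel,
                                      model = c("free_intercept", "through_origin"),
                                      min_points = 4, maturation_time = 0,
                                      alpha = 0.05, mu_min = 0.05,
                                      pool = c("replicate_mean", "pooled", "per_replicate"),
                                      ...) {
  model <- match.arg(model)
  pool <- match.arg(pool)
  mask <- detect_growth_phase(object, alpha = alpha, mu_min = mu_min)
  rs_list <- lapply(object$series, rate_series, channel = channel,
                    maturation_time = maturation_time)

  pick <- function(rs) {
    n <- nrow(rs$rates)
    inc <- mask$included[seq_len(n)]
    rs$rates[inc, , drop = FALSE]
  }

  res <- if (pool == "replicate_mean") {
    n <- min(vapply(rs_list, function(rs) nrow(rs$rates), 0L))
    inc <- mask$included[seq_len(n)]
    mu_bar <- rowMeans(vapply(rs_list, function(rs) rs$rates$mu[seq_len(n)], numeric(n)))
    rho_bar <- rowMeans(vapply(rs_list, function(rs) rs$rates$rho_h[seq_len(n)], numeric(n)))
    tm <- rs_list[[1L]]$rates$time_h[seq_len(n)]
    fit_slope(mu_bar[inc], rho_bar[inc], tm[inc], model = model, min_points = min_points)
  } else if (pool == "pooled") {
    pts <- do.call(rbind, lapply(rs_list, pick))
    fit_slope(pts$mu, pts$rho_h, pts$time_h, model = model, min_points = min_points)
  } else {
    fits <- lapply(rs_list, function(rs) {
      pts <- pick(rs)
      fit_slope(pts$mu, pts$rho_h, pts$time_h, model = model, min_points = min_points)
    })
    slopes <- vapply(fits, `[[`, 0, "slope")
    avg <- fits[[1L]]
    avg$slope <- mean(slopes)
    avg$slope_se <- if (length(slopes) > 1L) stats::sd(slopes) / sqrt(length(slopes)) else fits[[1L]]$slope_se
    avg$intercept <- mean(vapply(fits, `[[`, 0, "intercept"))
    avg$b <- mean(vapply(fits, `[[`, 0, "b"))
    avg$r_squared <- mean(vapply(fits, `[[`, 0, "r_squared"))
    avg$window_start_h <- min(vapply(fits, `[[`, 0, "window_start_h"))
    avg$window_end_h <- max(vapply(fits, `[[`, 0, "window_end_h"))
    avg$n_points <- sum(vapply(fits, `[[`, 0L, "n_points"))
    avg$n_trimmed <- sum(vapply(fits, `[[`, 0L, "n_trimmed"))
    avg$per_replicate <- fits
    avg
  }
  res$strain <- object$strain
  res$inducer <- object$inducer
  res$concentration <- object$concentration
  res$conc_unit <- object$conc_unit
  res$channel <- channel
  res$growth_phase <- mask
  res
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope = %.4g +/- %.3g, b = %.3g /h, R2 = %.4f, %d points (%d trimmed), %s\n",
              x$slope, x$slope_se, x$b, x$r_squared, x$n_points, x$n_trimmed, x$model))
  invisible(x)
}

#' Assemble a slope-method dose-response table
#'
#' Collects [fit_slope()] results (from the `condition_group` method, so each
#' carries its condition) for one strain/inducer into the table fed to the
#' Hill fit. The slope is the \eqn{f_H} estimate and its squared standard
#' error the variance used for inverse-variance weighting. Fits whose
#' \eqn{R^2} falls below `r2_floor` are included but flagged low-quality.
#'
#' @param fits List of `slope_fit` objects from [fit_slope.condition_group()].
#' @param r2_floor Quality floor on \eqn{R^2} (default 0.9).
#' @return A `dose_response` data.frame sorted by concentration with
#'   attribute `method = "slope"`.
#' @export
slope_dose_response <- function(fits, r2_floor = 0.9) {
  if (inherits(fits, "slope_fit")) fits <- list(fits)
  for (f in fits)
    if (is.null(f$strain))
      bs_usage_error("slope_dose_response needs fits produced from condition groups")
  strains <- unique(vapply(fits, `[[`, "", "strain"))
  inducers <- unique(vapply(fits, `[[`, "", "inducer"))
  if (length(strains) > 1L || length(inducers) > 1L)
    bs_usage_error("slope_dose_response expects fits from a single strain and inducer")
  conc <- vapply(fits, `[[`, 0, "concentration")
  if (anyDuplicated(conc))
    bs_duplication_error(sprintf("duplicate concentration %g for strain '%s'",
                                 conc[duplicated(conc)][1L], strains))
  if (length(unique(conc)) < 3L)
    bs_insufficient_data_error("dose-response needs at least 3 distinct concentrations")
  ord <- order(conc)
  r2 <- vapply(fits, `[[`, 0, "r_squared")
  dr <- dose_response(
    data.frame(concentration = conc[ord],
               f_h = vapply(fits, `[[`, 0, "slope")[ord],
               variance = vapply(fits, `[[`, 0, "slope_se")[ord]^2,
               n = vapply(fits, `[[`, 0L, "n_points")[ord],
               r_squared = r2[ord],
               b = vapply(fits, `[[`, 0, "b")[ord],
               low_quality = (r2 < r2_floor)[ord]),
    strain = strains, inducer = inducers,
    conc_unit = unique(vapply(fits, `[[`, "", "conc_unit"))[1L],
    method = "slope")
  if (any(dr$low_quality))
    warning(sprintf("%d slope fit(s) below the R2 floor %g flagged low-quality",
                    sum(dr$low_quality), r2_floor))
  dr
}
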