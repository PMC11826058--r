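#' Construct a dose-response table
#'
#' One row per inducer concentration with the expression-fraction estimate,
#' its variance (inverse-variance weight in the Hill fit) and the number of
#' observations behind it. Concentrations must be non-negative, distinct and
#' sorted; estimates must be finite.
#'
#' @param points Data.frame with at least `concentration`, `f_h`, `variance`,
#'   `n`.
#' @param strain,inducer Condition labels.
#' @param conc_unit Concentration unit, carried verbatim (no silent
#'   conversion).
#' @param method `"maximum"` or `"slope"`.
#' @return The data.frame with class `dose_response` and condition attributes.
#' @export
dose_response <- function(points, strain, inducer, conc_unit = "uM",
                          method = c("maximum", "slope")) {
  method <- match.arg(method)
  for (col in c("concentration", "f_h", "variance", "n"))
    if (!col %in% names(points))
      bs_format_error(sprintf("dose_response points lack column '%s'", col))
  if (any(points$concentration < 0))
    bs_usage_error("concentrations must be non-negative")
  if (is.unsorted(points$concentration, strictly = TRUE))
    bs_usage_error("concentrations must be strictly increasing")
  structure(points, class = c("dose_response", "data.frame"),
            strain = strain, inducer = inducer, conc_unit = conc_unit,
            method = method)
}

#' Evaluate the Hill dose-response function
#'
#' The expression fraction of an inducible circuit follows
#' \deqn{f_H(I) = \frac{H \, I^n}{(H+1)\, I^n + k_I^n}}
#' in its full form; when the heterologous fraction is small (reporter below
#' ~15% of biomass) the \eqn{(H+1)} factor is approximately 1, giving the
#' reduced (standard Hill) form \eqn{H I^n / (I^n + k_I^n)}. `H` is the
#' maximum expression, `k_I` the apparent affinity (same unit as `I`) and `n`
#' the Hill coefficient. Because whole-cell titrations convolve transport and
#' regulation, `k_I` and `n` are apparent, cell-context parameters, not
#' molecular binding constants.
#'
#' @param I Inducer concentration(s), >= 0.
#' @param H,k_I,n Hill parameters (alternatively pass a `hill_params` object
#'   as `params`).
#' @param form `"reduced"` or `"full"`.
#' @param params Optional `hill_params` object overriding `H`, `k_I`, `n` and
#'   `form`.
#' @return Numeric vector of \eqn{f_H} values.
#' @export
hill_eval <- function(I, H, k_I, n, form = c("reduced", "full"), params = NULL) {
  if (!is.null(params)) {
    H <- params$H; k_I <- params$k_I; n <- params$n; form <- params$form
  }
  form <- match.arg(form, c("reduced", "full"))
  if (any(I < 0)) bs_usage_error("inducer concentration must be >= 0")
  # work on the ratio (I/k_I)^n for overflow-safe saturation behaviour
  r <- ifelse(I == 0, 0, if (k_I > 0) (I / k_I)^n else Inf)
  out <- if (form == "reduced") {
    ifelse(is.infinite(r), H, H * r / (1 + r))
  } else {
    ifelse(is.infinite(r), H / (H + 1), H * r / ((H + 1) * r + 1))
  }
  ifelse(I == 0, 0, out)
}

hill_params_obj <- function(est, se, form, converged, rss, n_points, flags = character()) {
  structure(list(H = est[["H"]], k_I = est[["k_I"]], n = est[["n"]],
                 se_H = se[["H"]], se_kI = se[["k_I"]], se_n = se[["n"]],
                 form = form, converged = converged, rss = rss,
                 n_points = n_points, flags = flags),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<hill_params> (%s form)%s\n", x$form,
              if (!x$converged) " NOT CONVERGED" else ""))
  cat(sprintf("  H   = %.6g +/- %.3g\n  k_I = %.6g +/- %.3g\n  n   = %.4g +/- %.3g\n",
              x$H, x$se_H, x$k_I, x$se_kI, x$n, x$se_n))
  cat(sprintf("  weighted RSS = %.4g over %d points\n", x$rss, x$n_points))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit Hill parameters by bounded, inverse-variance-weighted NLS
#'
#' Minimizes \eqn{\sum_i w_i (f_{H,i} - hill(I_i))^2} with weights
#' \eqn{w_i = 1/variance_i}, using bounded nonlinear least squares
#' (`nls` with the port algorithm) under the constraints \eqn{H \ge 0},
#' \eqn{k_I \ge 0}, \eqn{n \ge 1}. Hill fits are multimodal in `n`, so the
#' optimizer is multi-started from \eqn{n_0 \in \{1, 2, 4\}} with
#' \eqn{H_0 = \max f_H} and \eqn{k_{I,0}} the concentration nearest half-max;
#' the start with the lowest weighted RSS wins. Standard errors are the
#' asymptotic values from the weighted Jacobian at the optimum.
#'
#' A zero-concentration point is a legitimate observation (the model value at
#' \eqn{I = 0} is 0; there is no basal-leak term). Zero-variance points
#' receive the median positive variance of the table, with a warning.
#'
#' @param dr A [dose_response()] table with >= 4 points and >= 3 distinct
#'   positive concentrations.
#' @param form `"reduced"` (default, the small-fraction approximation the
#'   method is normally used with) or `"full"`.
#' @return A `hill_params` object. If no start converges the result has
#'   `converged = FALSE` and `NA` estimates rather than an error.
#' @export
fit_hill <- function(dr, form = c("reduced", "full")) {
  form <- match.arg(form)
  I <- dr$concentration
  y <- dr$f_h
  v <- dr$variance
  if (length(I) < 4L)
    bs_insufficient_data_error("Hill fit needs at least 4 dose-response points")
  if (length(unique(I[I > 0])) < 3L)
    bs_insufficient_data_error("Hill fit needs at least 3 distinct positive concentrations")
  bad_var <- !is.finite(v) | v <= 0
  if (all(bad_var)) {
    v[] <- 1
    warning("no usable variances; falling back to equal weights")
  } else if (any(bad_var)) {
    v[bad_var] <- stats::median(v[!bad_var])
    warning(sprintf("%d zero/missing variance(s) replaced by the group median", sum(bad_var)))
  }
  w <- 1 / v

  ymax <- max(y)
  H0 <- if (form == "reduced") max(ymax, 1e-8) else {
    fr <- min(max(ymax, 1e-8), 1 - 1e-6)   # full form saturates at H/(H+1)
    fr / (1 - fr)
  }
  pos <- I > 0
  k0 <- I[pos][which.min(abs(y[pos] - ymax / 2))]
  starts <- lapply(c(1, 2, 4), function(n0) list(H = H0, k_I = k0, n = n0))

  env <- list2env(list(I = I, y = y, w = w, FORM = form))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::nls(y ~ hill_eval(I, H, k_I, n, form = FORM),
                 data = env, start = st, weights = w,
                 algorithm = "port", lower = c(H = 0, k_I = 0, n = 1),
                 control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || stats::deviance(fit) < stats::deviance(best)))
      best <- fit
  }
  if (is.null(best)) {
    na <- c(H = NA_real_, k_I = NA_real_, n = NA_real_)
    return(hill_params_obj(na, na, form, converged = FALSE, rss = NA_real_,
                           n_points = length(I), flags = "fit_failed"))
  }
  est <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, 2L],
                 error = function(e) c(H = NA_real_, k_I = NA_real_, n = NA_real_))
  flags <- character()
  if (est[["k_I"]] < 1e-3 * min(I[pos]))
    flags <- c(flags, "non_identifiable")   # k_I driven to the boundary
  if (abs(est[["n"]] - 1) < 1e-8)
    flags <- c(flags, "n_at_lower_bound")
  hill_params_obj(est, se, form, converged = TRUE, rss = stats::deviance(best),
                  n_points = length(I), flags = flags)
}

#' Compare Hill parameters obtained by the two methods
#'
#' Per-parameter absolute and relative differences and z-scores using the
#' combined standard errors,
#' \eqn{z = |\theta_1 - \theta_2| / \sqrt{se_1^2 + se_2^2}}. Agreement of the
#' maximum- and slope-method parameters (|z| < 2) indicates the expression
#' fraction was constant over the regression window through to the peak.
#'
#' @param max_params,slope_params `hill_params` objects for the same
#'   strain/inducer (the first conventionally from the maximum method).
#' @return A data.frame of class `method_comparison` with one row per
#'   parameter.
#' @export
compare_methods <- function(max_params, slope_params) {
  stopifnot(inherits(max_params, "hill_params"), inherits(slope_params, "hill_params"))
  par <- c("H", "k_I", "n")
  v1 <- c(max_params$H, max_params$k_I, max_params$n)
  v2 <- c(slope_params$H, slope_params$k_I, slope_params$n)
  s1 <- c(max_params$se_H, max_params$se_kI, max_params$se_n)
  s2 <- c(slope_params$se_H, slope_params$se_kI, slope_params$se_n)
  d <- v1 - v2
  structure(data.frame(parameter = par, maximum = v1, slope = v2,
                       abs_diff = abs(d), rel_diff = abs(d) / abs(v1),
                       z = abs(d) / sqrt(s1^2 + s2^2),
                       stringsAsFactors = FALSE),
            class = c("method_comparison", "data.frame"))
}
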