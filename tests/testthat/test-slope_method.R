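# Build a replicate group whose forward-difference growth rates at each time
# point take prescribed per-replicate values (od reconstructed recursively).
group_from_mu <- function(mu_by_time, dt = 0.25, od0 = 0.5) {
  n_rep <- ncol(mu_by_time)
  times <- seq(0, by = dt, length.out = nrow(mu_by_time) + 1L)
  series <- lapply(seq_len(n_rep), function(r) {
    od <- Reduce(function(o, mu) o * (1 + mu * dt), mu_by_time[, r],
                 accumulate = TRUE, init = od0)
    well_series(sprintf("W%d", r), times, od,
                list(gfp = rep(0, length(times))))
  })
  condition_group("toy", "IPTG", 50, series)
}

test_that("growth phase is detected by per-time-point t-tests", {
  mu_by_time <- rbind(c(0.50, 0.52, 0.48, 0.50),    # clearly growing
                      c(0.01, -0.02, 0.02, -0.01),  # not significant
                      c(0, 0, 0, 0),                # degenerate, all zero
                      c(-0.30, -0.31, -0.29, -0.30))# significant but negative
  g <- group_from_mu(mu_by_time)
  mask <- detect_growth_phase(g, alpha = 0.05)
  expect_equal(mask$included, c(TRUE, FALSE, FALSE, FALSE))
  # cross-check the first point against t.test directly: t ~ 61, p << alpha
  tt <- t.test(c(0.50, 0.52, 0.48, 0.50), mu = 0)
  expect_equal(mask$p_values[1L], tt$p.value)
  expect_lt(mask$p_values[1L], 1e-4)
  expect_gt(mask$p_values[2L], 0.05)
  expect_equal(mask$p_values[3L], 1)            # sd = 0, mean = 0 convention
  # mean mu > 0 is required even when p < alpha
  expect_lt(mask$p_values[4L], 0.05)
  expect_true(all(mask$included == (mask$p_values < mask$alpha & mask$mu_mean > 0)))
})

test_that("single-replicate groups fall back to a threshold with a warning", {
  g1 <- condition_group("toy", "IPTG", 50, list(make_exp_series(mu0 = 0.4)))
  expect_warning(mask <- detect_growth_phase(g1, mu_min = 0.05), "threshold")
  expect_true(all(mask$included))
  expect_true(all(is.na(mask$p_values)))
})

test_that("exact linear and affine rate relations are fit without trimming", {
  mu <- seq(0.7, 0.2, length.out = 10)
  fit <- fit_slope(mu, 0.3 * mu, times = seq_along(mu))
  expect_equal(fit$slope, 0.3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n_trimmed, 0L)
  expect_equal(fit$b, 0, tolerance = 1e-9)

  # affine data: rho = 0.3 * (mu - 0.1) gives slope 0.3 and intercept b = 0.1
  fit2 <- fit_slope(mu, 0.3 * (mu - 0.1), times = seq_along(mu))
  expect_equal(fit2$slope, 0.3, tolerance = 1e-12)
  expect_equal(fit2$b, 0.1, tolerance = 1e-10)
  expect_equal(fit2$intercept, -0.03, tolerance = 1e-12)

  fit3 <- fit_slope(mu, 0.3 * mu, times = seq_along(mu), model = "through_origin")
  expect_equal(fit3$slope, 0.3, tolerance = 1e-12)
  expect_identical(fit3$intercept, 0)
  expect_identical(fit3$b, 0)
  # on b = 0 data the two models agree within one standard error
  expect_lt(abs(fit3$slope - fit$slope), fit$slope_se + 1e-12)

  expect_error(fit_slope(mu[1:3], mu[1:3], times = 1:3),
               class = "bs_insufficient_data_error")
  expect_warning(fit_slope(mu, -0.2 * mu + 0.05, times = seq_along(mu)),
                 "non-positive slope")
})

test_that("the early hook is trimmed away and the slope recovered", {
  set.seed(7)
  n <- 26
  times <- seq(0.25, by = 0.25, length.out = n)
  mu <- seq(0.72, 0.25, length.out = n)
  rho <- 0.25 * mu
  hook_scale <- c(0.10, 0.30, 0.50, 0.70, 0.85, 0.95)  # inducer equilibration
  rho[1:6] <- rho[1:6] * hook_scale
  rho <- rho * (1 + 1e-3 * rnorm(n))
  fit <- fit_slope(mu, rho, times = times)
  expect_gte(fit$n_trimmed, 6L)
  expect_lte(fit$n_trimmed, 9L)
  expect_lt(abs(fit$slope - 0.25), 3 * fit$slope_se + 1e-6)
  expect_lt(abs(fit$slope - 0.25) / 0.25, 0.01)
  expect_gte(fit$window_start_h, times[7])
  expect_gt(fit$r_squared, 0.999)
})

test_that("the untrimmed fit equals closed-form least squares", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n, mean = 0.5, sd = 0.2)
    y <- 0.8 * x + 0.1 + rnorm(n, sd = 0.05)
    f <- fit_slope(x, y, times = seq_len(n), min_points = n)
    sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
    expect_equal(f$slope, sxy / sxx, tolerance = 1e-10)
    expect_equal(f$intercept, mean(y) - sxy / sxx * mean(x), tolerance = 1e-10)
    fo <- fit_slope(x, y, times = seq_len(n), min_points = n,
                    model = "through_origin")
    expect_equal(fo$slope, sum(x * y) / sum(x^2), tolerance = 1e-10)
  }
})

test_that("condition groups are fit on replicate-mean rate curves", {
  # exact construction: flu = K*(OD - OD0) makes rho_h = K * mu identically
  g <- make_logistic_group(n_rep = 4, kappa_fh = 2000)
  fit <- fit_slope(g, channel = "gfp")
  expect_equal(fit$slope, 2000, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$strain, "toy")
  expect_equal(fit$concentration, 50)
  # pooled and per-replicate options agree on noiseless data
  fitp <- fit_slope(g, channel = "gfp", pool = "pooled")
  fitr <- fit_slope(g, channel = "gfp", pool = "per_replicate")
  expect_equal(fitp$slope, 2000, tolerance = 1e-9)
  expect_equal(fitr$slope, 2000, tolerance = 1e-9)
})

test_that("slope dose-response flags low-quality fits and propagates variance", {
  set.seed(3)
  concs <- c(10, 50, 100)
  fits <- lapply(concs, function(cc) {
    g <- make_logistic_group(n_rep = 2, concentration = cc, kappa_fh = 10 * cc)
    fit_slope(g, channel = "gfp")
  })
  dr <- slope_dose_response(fits)
  expect_equal(dr$f_h, 10 * concs, tolerance = 1e-9)
  expect_equal(dr$variance, vapply(fits, `[[`, 0, "slope_se")[order(concs)]^2)
  expect_false(any(dr$low_quality))
  expect_equal(attr(dr, "method"), "slope")

  # degrade one condition with heavy noise so its R^2 drops below the floor
  noisy <- make_logistic_group(n_rep = 2, concentration = 200, kappa_fh = 500)
  for (r in seq_along(noisy$series)) {
    f <- noisy$series[[r]]$fluorescence$gfp
    noisy$series[[r]]$fluorescence$gfp <- f + rnorm(length(f), sd = 30)
  }
  fits2 <- c(fits, list(suppressWarnings(fit_slope(noisy, channel = "gfp"))))
  expect_warning(dr2 <- slope_dose_response(fits2), "low-quality")
  expect_true(dr2$low_quality[dr2$concentration == 200])

  expect_error(slope_dose_response(fits[1:2]), class = "bs_insufficient_data_error")
  expect_error(suppressWarnings(slope_dose_response(c(fits, fits[2]))),
               class = "bs_duplication_error")
})
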