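make_dr <- function(conc, f_h, variance = rep(1, length(conc)),
                    n = rep(4L, length(conc)), method = "maximum") {
  dose_response(data.frame(concentration = conc, f_h = f_h,
                           variance = variance, n = n),
                strain = "toy", inducer = "IPTG", method = method)
}

test_that("hill_eval satisfies the defining identities", {
  expect_equal(hill_eval(0, 10, 5, 2), 0)
  expect_equal(hill_eval(0, 10, 5, 2, form = "full"), 0)
  # saturation limits
  expect_equal(hill_eval(1e12, 10, 5, 2), 10, tolerance = 1e-6)
  expect_equal(hill_eval(1e12, 10, 5, 2, form = "full"), 10 / 11, tolerance = 1e-6)
  # half-saturation at I = k_I for any n (reduced form)
  for (n in c(1, 1.7, 2.5, 6)) expect_equal(hill_eval(31, 9784, 31, n), 9784 / 2)
  expect_error(hill_eval(-1, 10, 5, 2), class = "bs_usage_error")

  # monotone non-decreasing in I over random admissible parameters
  set.seed(5)
  I <- sort(c(0, exp(seq(log(0.01), log(1e4), length.out = 80))))
  for (i in 1:10) {
    H <- runif(1, 0.1, 1e4); k <- runif(1, 0.1, 500); n <- runif(1, 1, 6)
    for (form in c("reduced", "full"))
      expect_true(all(diff(hill_eval(I, H, k, n, form = form)) >= -1e-12))
  }
})

test_that("full and reduced forms are related by the documented rescaling", {
  set.seed(6)
  I <- c(0, 10^seq(-1, 3, length.out = 30))
  for (i in 1:10) {
    H <- runif(1, 0.05, 50); k <- runif(1, 1, 300); n <- runif(1, 1, 5)
    lhs <- hill_eval(I, H, k, n, form = "full")
    rhs <- hill_eval(I, H / (H + 1), k * (H + 1)^(-1 / n), n, form = "reduced")
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("noiseless Hill data are recovered to four significant figures", {
  H <- 9784; k <- 31.0; n <- 2.5
  conc <- c(0, 5, 10, 20, 31, 60, 120, 300)
  dr <- make_dr(conc, hill_eval(conc, H, k, n))
  fit <- fit_hill(dr)
  expect_true(fit$converged)
  expect_equal(fit$H, H, tolerance = 1e-4)
  expect_equal(fit$k_I, k, tolerance = 1e-4)
  expect_equal(fit$n, n, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-6)

  # the full form is meaningful on the fraction scale (its plateau is
  # H/(H+1)); a reduced-form fit of full-form data recovers the rescaled
  # parameters
  Hf <- 0.15; kf <- 31; nf <- 2.5
  yf <- hill_eval(conc, Hf, kf, nf, form = "full")
  fit_full <- fit_hill(make_dr(conc, yf), form = "full")
  expect_equal(fit_full$H, Hf, tolerance = 1e-3)
  expect_equal(fit_full$k_I, kf, tolerance = 1e-3)
  fit_red <- fit_hill(make_dr(conc, yf), form = "reduced")
  expect_equal(fit_red$H, Hf / (Hf + 1), tolerance = 1e-3)
  expect_equal(fit_red$k_I, kf * (Hf + 1)^(-1 / nf), tolerance = 1e-3)
  expect_equal(fit_red$n, nf, tolerance = 1e-3)
})

test_that("the n >= 1 bound activates and matches a profile-scan oracle", {
  H <- 100; k <- 50
  conc <- c(0, 2, 5, 10, 20, 50, 100, 200)
  y <- hill_eval(conc, H, k, 0.8)       # sub-cooperative truth
  dr <- make_dr(conc, y)
  fit <- fit_hill(dr)
  expect_equal(fit$n, 1, tolerance = 1e-6)
  expect_true("n_at_lower_bound" %in% fit$flags)

  # independent oracle: profile the RSS over a grid of n, minimizing over
  # (H, k_I) by general-purpose bounded optimization at each grid point
  profile_rss <- function(nv) {
    o <- optim(c(max(y), 50), function(p)
      sum((y - hill_eval(conc, p[1], p[2], nv))^2),
      method = "L-BFGS-B", lower = c(1e-9, 1e-9))
    c(o$value, o$par)
  }
  grid <- seq(1, 3, by = 0.1)
  prof <- vapply(grid, profile_rss, numeric(3))
  expect_equal(grid[which.min(prof[1, ])], 1)   # constrained optimum at n = 1
  expect_equal(fit$H, prof[2, 1], tolerance = 1e-3)
  expect_equal(fit$k_I, prof[3, 1], tolerance = 1e-3)
  expect_lte(fit$rss, prof[1, 1] * (1 + 1e-6) + 1e-12)
})

test_that("weights behave: equal weights match unweighted, zeros are repaired", {
  set.seed(8)
  conc <- c(0, 5, 15, 40, 80, 200)
  y <- hill_eval(conc, 1200, 35, 2) * exp(rnorm(6, sd = 0.03))
  f1 <- fit_hill(make_dr(conc, y, variance = rep(1, 6)))
  f7 <- fit_hill(make_dr(conc, y, variance = rep(7, 6)))
  expect_equal(f1$H, f7$H, tolerance = 1e-8)
  expect_equal(f1$k_I, f7$k_I, tolerance = 1e-8)
  expect_equal(f1$n, f7$n, tolerance = 1e-8)

  v <- c(0, 4, 5, 6, 5, 4)   # zero variance at I = 0 gets the group median
  expect_warning(fz <- fit_hill(make_dr(conc, y, variance = v)), "median")
  expect_true(fz$converged)

  expect_error(fit_hill(make_dr(c(0, 10, 20), c(0, 1, 2))),
               class = "bs_insufficient_data_error")
})

test_that("the port-algorithm fit agrees with an independent NLS implementation", {
  skip_if_not_installed("minpack.lm")
  set.seed(21)
  conc <- c(0, 8, 20, 45, 90, 180, 400)
  v <- c(1, 2, 4, 9, 16, 25, 30)
  y <- hill_eval(conc, 2500, 60, 2.2) * exp(rnorm(7, sd = 0.04))
  fit <- fit_hill(make_dr(conc, y, variance = v))
  alt <- minpack.lm::nlsLM(
    y ~ hill_eval(I, H, k_I, n),
    data = data.frame(I = conc, y = y),
    start = list(H = max(y), k_I = 50, n = 2), weights = 1 / v,
    lower = c(0, 0, 1), control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(fit$H, coef(alt)[["H"]], tolerance = 1e-5)
  expect_equal(fit$k_I, coef(alt)[["k_I"]], tolerance = 1e-5)
  expect_equal(fit$n, coef(alt)[["n"]], tolerance = 1e-5)
})

test_that("concentration-independent data are flagged non-identifiable", {
  conc <- c(5, 10, 50, 100, 200)
  fit <- suppressWarnings(fit_hill(make_dr(conc, rep(5, 5))))
  expect_true(fit$converged)
  expect_true("non_identifiable" %in% fit$flags)
  expect_equal(fit$H, 5, tolerance = 0.02)
  expect_lt(fit$k_I, 1e-3 * 5)
})

test_that("hill parameters are recovered across noisy replicate titrations", {
  # module-level recovery: 5% multiplicative noise applied directly to the
  # f_H samples, 4 replicates, 6 concentrations straddling k_I
  H <- 9600; k <- 50; n <- 2.5
  conc <- c(0, 12.5, 25, 50, 100, 200)
  set.seed(2024)
  err_k <- err_n <- numeric(100)
  for (i in 1:100) {
    reps <- vapply(seq_len(4), function(r)
      hill_eval(conc, H, k, n) * exp(rnorm(6, sd = 0.05)), numeric(6))
    dr <- make_dr(conc, rowMeans(reps), variance = apply(reps, 1, var))
    fit <- suppressWarnings(fit_hill(dr))
    err_k[i] <- abs(fit$k_I - k) / k
    err_n[i] <- abs(fit$n - n)
  }
  expect_lt(median(err_k), 0.10)
  expect_lt(median(err_n), 0.5)
})

test_that("method comparison reports differences and z-scores", {
  mk <- function(H, seH, k, sek, n, sen) {
    biosensr:::hill_params_obj(c(H = H, k_I = k, n = n),
                               c(H = seH, k_I = sek, n = sen),
                               "reduced", TRUE, 0, 6L)
  }
  a <- mk(9784, 191, 31.0, 3.7, 2.5, 0.3)
  same <- compare_methods(a, a)
  expect_equal(same$abs_diff, rep(0, 3))
  expect_equal(same$z, rep(0, 3))

  b <- mk(8457, 225, 35.6, 5.5, 2.5, 0.5)
  cmp <- compare_methods(a, b)
  expect_equal(cmp$rel_diff[1], 1327 / 9784, tolerance = 1e-6)
  expect_equal(cmp$z[1], 1327 / sqrt(191^2 + 225^2), tolerance = 1e-6)
  expect_equal(cmp$z[1], 4.496, tolerance = 1e-3)
  expect_equal(cmp$abs_diff[3], 0)
})
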