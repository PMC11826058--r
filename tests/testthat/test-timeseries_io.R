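test_that("tidy reader builds condition groups and keeps blanks aside", {
  dir <- withr::local_tempdir()
  dat <- data.frame(
    time_h = rep(c(0, 0.25, 0.5), 2),
    well = rep(c("A1", "A2"), each = 3),
    od600 = c(0.10, 0.12, 0.15, 0.04, 0.04, 0.04),
    flu_gfp = c(0, 10, 25, 0, 0, 0))
  lay <- data.frame(well = c("A1", "A2"), strain = c("BL21", "blank"),
                    inducer = c("IPTG", "none"), concentration = c(100, 0),
                    conc_unit = "uM", replicate = 1,
                    is_blank = c(FALSE, TRUE))
  write.csv(dat, file.path(dir, "d.csv"), row.names = FALSE)
  write.csv(lay, file.path(dir, "l.csv"), row.names = FALSE)

  pd <- read_tidy_csv(file.path(dir, "d.csv"), file.path(dir, "l.csv"))
  expect_length(pd$groups, 1L)
  expect_length(pd$blanks, 1L)
  g <- pd$groups[[1L]]
  expect_equal(g$strain, "BL21")
  expect_equal(g$concentration, 100)
  expect_length(g$series, 1L)
  expect_equal(g$series[[1L]]$od600, c(0.10, 0.12, 0.15))
  expect_equal(g$series[[1L]]$fluorescence$gfp, c(0, 10, 25))
  expect_equal(pd$blanks[[1L]]$well_id, "A2")

  # minutes are converted only via the explicit flag
  dat_min <- dat; dat_min$time_h <- dat_min$time_h * 60
  write.csv(dat_min, file.path(dir, "dm.csv"), row.names = FALSE)
  pd_min <- read_tidy_csv(file.path(dir, "dm.csv"), file.path(dir, "l.csv"),
                          time_unit = "minutes")
  expect_equal(pd_min$groups[[1L]]$series[[1L]]$times, c(0, 0.25, 0.5))
})

test_that("a factorial titration design partitions into condition groups", {
  fr <- make_factorial_frames(n_strain = 5, n_conc = 6, n_rep = 4, n_time = 64)
  pd <- as_plate_data(fr$data, fr$layout)
  expect_length(pd$groups, 30L)
  expect_true(all(vapply(pd$groups, function(g) length(g$series), 0L) == 4L))
  # partition property: every non-blank well appears in exactly one group
  wells <- unname(unlist(lapply(pd$groups, function(g)
    vapply(g$series, `[[`, "", "well_id"))))
  expect_equal(sort(wells), sort(unique(fr$layout$well)))
  expect_equal(anyDuplicated(wells), 0L)
})

test_that("reader errors identify the offending column, well, or ordering", {
  fr <- make_factorial_frames(n_strain = 1, n_conc = 3, n_rep = 1, n_time = 4)
  expect_error(as_plate_data(fr$data[setdiff(names(fr$data), "od600")], fr$layout),
               "od600", class = "bs_format_error")
  expect_error(as_plate_data(fr$data[c(1, 1:nrow(fr$data)), ], fr$layout),
               class = "bs_duplication_error")
  scr <- fr$data
  scr$time_h[2:3] <- scr$time_h[3:2]
  expect_error(as_plate_data(scr, fr$layout), "non-monotone",
               class = "bs_ordering_error")
  lay2 <- rbind(fr$layout,
                data.frame(well = "GHOST", strain = "x", inducer = "IPTG",
                           concentration = 1, conc_unit = "uM", replicate = 9,
                           is_blank = FALSE))
  expect_error(as_plate_data(fr$data, lay2), "GHOST", class = "bs_format_error")
})

test_that("read -> write -> read round-trips times and values bit-exactly", {
  dir <- withr::local_tempdir()
  fr <- make_factorial_frames(n_strain = 1, n_conc = 3, n_rep = 2, n_time = 8)
  # awkward doubles on purpose
  fr$data$od600 <- fr$data$od600 * (1 / 3)
  write_csv_path <- file.path(dir, "d1.csv")
  biosensr:::write_csv_exact(fr$data, write_csv_path)
  write.csv(fr$layout, file.path(dir, "l.csv"), row.names = FALSE)
  pd1 <- read_tidy_csv(write_csv_path, file.path(dir, "l.csv"))
  write_tidy_csv(pd1, file.path(dir, "d2.csv"), file.path(dir, "l2.csv"))
  pd2 <- read_tidy_csv(file.path(dir, "d2.csv"), file.path(dir, "l2.csv"))
  for (k in seq_along(pd1$groups)) {
    for (r in seq_along(pd1$groups[[k]]$series)) {
      a <- pd1$groups[[k]]$series[[r]]; b <- pd2$groups[[k]]$series[[r]]
      expect_identical(a$times, b$times)
      expect_identical(a$od600, b$od600)
      expect_identical(a$fluorescence$gfp, b$fluorescence$gfp)
    }
  }
})

test_that("blank correction subtracts mean blanks, clips at the floor", {
  times <- seq(0, 1, by = 0.25)
  sample_ws <- well_series("S1", times, rep(0.14, 5), list(gfp = rep(50, 5)))
  blank1 <- well_series("B1", times, rep(0.03, 5), list(gfp = rep(5, 5)))
  blank2 <- well_series("B2", times, rep(0.05, 5), list(gfp = rep(5, 5)))
  lay <- data.frame(well = c("S1", "B1", "B2"), strain = c("s", "b", "b"),
                    inducer = "IPTG", concentration = c(10, 0, 0),
                    conc_unit = "uM", replicate = 1,
                    is_blank = c(FALSE, TRUE, TRUE))
  pd <- structure(list(groups = list(condition_group("s", "IPTG", 10, list(sample_ws))),
                       blanks = list(blank1, blank2), layout = lay),
                  class = "plate_data")

  expect_identical(blank_correct(pd, mode = "none"), pd)
  cor <- blank_correct(pd, mode = "mean_blank")
  expect_equal(cor$groups[[1L]]$series[[1L]]$od600, rep(0.10, 5))
  expect_equal(cor$groups[[1L]]$series[[1L]]$fluorescence$gfp, rep(45, 5))

  # blank exceeding the sample at one time point -> clipped at the floor
  dip <- pd
  dip$groups[[1L]]$series[[1L]]$od600[3] <- 0.02
  expect_warning(cor2 <- blank_correct(dip, mode = "mean_blank", eps_od = 1e-3),
                 "clipped")
  expect_equal(cor2$groups[[1L]]$series[[1L]]$od600[3], 1e-3)
  expect_gt(min(cor2$groups[[1L]]$series[[1L]]$od600), 0)

  # a well that is entirely below blank is a data-quality error
  dead <- pd
  dead$groups[[1L]]$series[[1L]]$od600 <- rep(0.01, 5)
  expect_error(blank_correct(dead, mode = "mean_blank"),
               class = "bs_data_quality_error")
  # no blanks available
  nb <- pd; nb$blanks <- list()
  expect_error(blank_correct(nb, mode = "mean_blank"),
               class = "bs_insufficient_data_error")
})

test_that("matrix exports convert to the tidy dialect", {
  dir <- withr::local_tempdir()
  times <- seq(0, 1, by = 0.5)
  od <- data.frame(time = times, W1 = c(0.1, 0.2, 0.4), W2 = c(0.1, 0.15, 0.2))
  fl <- data.frame(time = times, W1 = c(0, 5, 20), W2 = c(0, 1, 2))
  write.csv(od, file.path(dir, "od.csv"), row.names = FALSE)
  write.csv(fl, file.path(dir, "fl.csv"), row.names = FALSE)
  tidy <- read_matrix_csv(file.path(dir, "od.csv"),
                          c(gfp = file.path(dir, "fl.csv")))
  expect_equal(names(tidy), c("time_h", "well", "od600", "flu_gfp"))
  expect_equal(nrow(tidy), 6L)
  expect_equal(tidy$od600[tidy$well == "W1"], c(0.1, 0.2, 0.4))
  expect_equal(tidy$flu_gfp[tidy$well == "W2"], c(0, 1, 2))
})
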