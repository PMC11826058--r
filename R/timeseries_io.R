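#' Construct a single-well time series
#'
#' A `well_series` holds one well's sampled optical density and fluorescence
#' trajectories on a common, strictly increasing time grid (hours).
#'
#' @param well_id Plate coordinate or other unique well label.
#' @param times Numeric vector of sampling times in hours, strictly increasing,
#'   length >= 2.
#' @param od600 Numeric vector of blank-corrected absorbance values, same
#'   length as `times`.
#' @param fluorescence Named list of numeric vectors (one per fluorescence
#'   channel, e.g. `gfp`), each the same length as `times`. Units are
#'   instrument-arbitrary and channels are treated as incommensurable.
#' @return An object of class `well_series`.
#' @export
well_series <- function(well_id, times, od600, fluorescence = list()) {
  times <- as.numeric(times)
  od600 <- as.numeric(od600)
  if (length(times) < 2L)
    bs_insufficient_data_error(sprintf("well '%s': at least 2 time points required", well_id))
  if (any(diff(times) <= 0))
    bs_ordering_error(sprintf("well '%s': times must be strictly increasing", well_id))
  if (length(od600) != length(times))
    bs_format_error(sprintf("well '%s': od600 length differs from times", well_id))
  if (!is.list(fluorescence) || (length(fluorescence) && is.null(names(fluorescence))))
    bs_format_error(sprintf("well '%s': fluorescence must be a named list", well_id))
  for (ch in names(fluorescence)) {
    fluorescence[[ch]] <- as.numeric(fluorescence[[ch]])
    if (length(fluorescence[[ch]]) != length(times))
      bs_format_error(sprintf("well '%s': channel '%s' length differs from times", well_id, ch))
  }
  structure(list(well_id = as.character(well_id), times = times, od600 = od600,
                 fluorescence = fluorescence),
            class = "well_series")
}

#' @export
print.well_series <- function(x, ...) {
  cat(sprintf("<well_series> %s: %d points, %.2f-%.2f h, channels: %s\n",
              x$well_id, length(x$times), min(x$times), max(x$times),
              paste(names(x$fluorescence), collapse = ", ")))
  invisible(x)
}

#' Construct a replicate condition group
#'
#' Groups the replicate wells measured for one (strain, inducer,
#' concentration) condition. All member series must share an identical time
#' grid; resampling mismatched grids is treated as an error, never done
#' silently.
#'
#' @param strain,inducer Free-text condition labels.
#' @param concentration Inducer concentration (unit in `conc_unit`).
#' @param series List of [well_series()] replicates (N >= 1).
#' @param conc_unit Concentration unit string, carried verbatim (e.g. `"uM"`,
#'   `"nM"`).
#' @param grid_tol Relative tolerance for declaring replicate time grids
#'   identical.
#' @return An object of class `condition_group`.
#' @export
condition_group <- function(strain, inducer, concentration, series,
                            conc_unit = "uM", grid_tol = 1e-8) {
  if (!length(series)) bs_insufficient_data_error("condition_group needs at least one series")
  ref <- series[[1L]]$times
  for (ws in series) {
    if (length(ws$times) != length(ref) ||
        max(abs(ws$times - ref)) > grid_tol * max(1, max(abs(ref))))
      bs_format_error(sprintf(
        "replicate time grids differ within condition (%s, %s, %s); resample explicitly",
        strain, inducer, format(concentration)))
  }
  structure(list(strain = as.character(strain), inducer = as.character(inducer),
                 concentration = as.numeric(concentration),
                 conc_unit = as.character(conc_unit), series = series),
            class = "condition_group")
}

#' @export
print.condition_group <- function(x, ...) {
  cat(sprintf("<condition_group> %s / %s / %g %s: N = %d replicates, %d points\n",
              x$strain, x$inducer, x$concentration, x$conc_unit,
              length(x$series), length(x$series[[1L]]$times)))
  invisible(x)
}

condition_key <- function(strain, inducer, concentration) {
  paste(strain, inducer, fmt_num(as.numeric(concentration)), sep = "|")
}

#' Read a tidy plate-reader dataset and its layout
#'
#' The canonical input is long/tidy CSV: one measurement row per well and time
#' point. The data file must have columns `time_h`, `well`, `od600` and at
#' least one fluorescence column named `flu_<channel>`; the layout file maps
#' wells to experimental conditions with columns `well`, `strain`, `inducer`,
#' `concentration`, `replicate`, `is_blank` (and optionally `conc_unit`).
#'
#' Non-blank wells are partitioned into [condition_group()]s keyed by
#' (strain, inducer, concentration); blank wells are excluded from groups but
#' retained for blank correction.
#'
#' @param path Path to the tidy data CSV.
#' @param layout_path Path to the layout CSV.
#' @param time_unit Unit of the time column; converted to hours internally.
#'   Never guessed from the data.
#' @return An object of class `plate_data`: a list with elements `groups`
#'   (named list of `condition_group`), `blanks` (list of `well_series`) and
#'   `layout` (the layout as a data.frame).
#' @export
read_tidy_csv <- function(path, layout_path, time_unit = c("hours", "minutes", "seconds")) {
  time_unit <- match.arg(time_unit)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  lay <- utils::read.csv(layout_path, stringsAsFactors = FALSE, check.names = FALSE)
  as_plate_data(dat, lay, time_unit = time_unit)
}

#' Build a plate dataset from in-memory data frames
#'
#' The data.frame counterpart of [read_tidy_csv()]: same columns, same
#' validation, no files. Useful when the data come from a simulation or an
#' upstream pipeline stage.
#'
#' @param dat Tidy measurement data.frame (`time_h`, `well`, `od600`,
#'   `flu_<channel>` columns).
#' @param lay Layout data.frame (`well`, `strain`, `inducer`,
#'   `concentration`, `replicate`, `is_blank`, optionally `conc_unit`).
#' @inheritParams read_tidy_csv
#' @return A `plate_data` object.
#' @export
as_plate_data <- function(dat, lay, time_unit = c("hours", "minutes", "seconds")) {
  time_unit <- match.arg(time_unit)
  for (col in c("time_h", "well", "od600"))
    if (!col %in% names(dat))
      bs_format_error(sprintf("data file is missing required column '%s'", col))
  flu_cols <- grep("^flu_", names(dat), value = TRUE)
  if (!length(flu_cols))
    bs_format_error("data file needs at least one fluorescence column named 'flu_<channel>'")
  for (col in c("well", "strain", "inducer", "concentration", "replicate", "is_blank"))
    if (!col %in% names(lay))
      bs_format_error(sprintf("layout file is missing required column '%s'", col))
  if (!"conc_unit" %in% names(lay)) lay$conc_unit <- "uM"

  div <- c(hours = 1, minutes = 60, seconds = 3600)[[time_unit]]
  dat$time_h <- as.numeric(dat$time_h) / div

  dup <- duplicated(dat[, c("well", "time_h")])
  if (any(dup)) {
    first <- dat[which(dup)[1L], ]
    bs_duplication_error(sprintf("duplicate (well, time) row: well '%s' at t = %g h",
                                 first$well, first$time_h))
  }

  data_wells <- unique(dat$well)
  layout_wells <- unique(lay$well)
  missing_in_data <- setdiff(layout_wells, data_wells)
  if (length(missing_in_data))
    bs_format_error(sprintf("layout references well '%s' absent from the data file",
                            missing_in_data[1L]))
  missing_in_layout <- setdiff(data_wells, layout_wells)
  if (length(missing_in_layout))
    bs_format_error(sprintf("data contains well '%s' absent from the layout",
                            missing_in_layout[1L]))
  if (anyDuplicated(lay$well))
    bs_duplication_error(sprintf("layout lists well '%s' more than once",
                                 lay$well[duplicated(lay$well)][1L]))

  channels <- sub("^flu_", "", flu_cols)
  wells <- lapply(data_wells, function(w) {
    rows <- dat[dat$well == w, , drop = FALSE]
    if (any(diff(rows$time_h) <= 0))
      bs_ordering_error(sprintf("well '%s': non-monotone time series", w))
    flu <- stats::setNames(lapply(flu_cols, function(cl) as.numeric(rows[[cl]])), channels)
    well_series(w, rows$time_h, rows$od600, flu)
  })
  names(wells) <- data_wells

  lay$is_blank <- as.logical(lay$is_blank)
  blanks <- wells[lay$well[lay$is_blank]]
  samp <- lay[!lay$is_blank, , drop = FALSE]
  keys <- condition_key(samp$strain, samp$inducer, samp$concentration)
  groups <- lapply(split(seq_len(nrow(samp)), keys), function(idx) {
    rows <- samp[idx, , drop = FALSE]
    rows <- rows[order(rows$replicate), , drop = FALSE]
    if (length(unique(rows$conc_unit)) > 1L)
      bs_format_error(sprintf("inconsistent conc_unit within condition for strain '%s'",
                              rows$strain[1L]))
    condition_group(rows$strain[1L], rows$inducer[1L], rows$concentration[1L],
                    wells[rows$well], conc_unit = rows$conc_unit[1L])
  })
  ord <- order(vapply(groups, `[[`, "", "strain"),
               vapply(groups, `[[`, "", "inducer"),
               vapply(groups, `[[`, 0, "concentration"))
  structure(list(groups = groups[ord], blanks = unname(blanks), layout = lay),
            class = "plate_data")
}

#' @export
print.plate_data <- function(x, ...) {
  cat(sprintf("<plate_data> %d condition groups, %d blank wells\n",
              length(x$groups), length(x$blanks)))
  invisible(x)
}

#' Write a plate dataset back to the tidy CSV dialect
#'
#' Numeric values are written with enough digits that a read/write/read cycle
#' reproduces them bit-exactly.
#'
#' @param x A `plate_data` object (or list of `well_series`).
#' @param path Output path for the data CSV.
#' @param layout_path Optional output path for the layout CSV (only for
#'   `plate_data` input).
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(x, path, layout_path = NULL) {
  wells <- if (inherits(x, "plate_data")) {
    c(unlist(lapply(x$groups, `[[`, "series"), recursive = FALSE, use.names = FALSE),
      x$blanks)
  } else if (inherits(x, "well_series")) list(x) else x
  channels <- names(wells[[1L]]$fluorescence)
  rows <- lapply(wells, function(ws) {
    df <- data.frame(time_h = ws$times, well = ws$well_id, od600 = ws$od600,
                     stringsAsFactors = FALSE)
    for (ch in channels) df[[paste0("flu_", ch)]] <- ws$fluorescence[[ch]]
    df
  })
  write_csv_exact(do.call(rbind, rows), path)
  if (!is.null(layout_path) && inherits(x, "plate_data"))
    write_csv_exact(x$layout, layout_path)
  invisible(path)
}

#' Convert a plate-reader matrix export to the tidy dialect
#'
#' Many instruments export one matrix per channel: time in rows, wells in
#' columns. This converts such exports (already loaded or as CSV paths) into
#' the tidy long data.frame consumed by [read_tidy_csv()].
#'
#' @param od_path CSV with a time column (first column) and one column per
#'   well containing OD600.
#' @param flu_paths Named character vector of per-channel CSVs with the same
#'   shape (names become channel names).
#' @param time_unit Unit of the exported time column.
#' @return A tidy data.frame with columns `time_h`, `well`, `od600`,
#'   `flu_<channel>`.
#' @export
read_matrix_csv <- function(od_path, flu_paths, time_unit = c("hours", "minutes", "seconds")) {
  time_unit <- match.arg(time_unit)
  div <- c(hours = 1, minutes = 60, seconds = 3600)[[time_unit]]
  od <- utils::read.csv(od_path, stringsAsFactors = FALSE, check.names = FALSE)
  wells <- names(od)[-1L]
  out <- data.frame(
    time_h = rep(as.numeric(od[[1L]]) / div, times = length(wells)),
    well = rep(wells, each = nrow(od)),
    od600 = unlist(od[-1L], use.names = FALSE),
    stringsAsFactors = FALSE)
  for (ch in names(flu_paths)) {
    flu <- utils::read.csv(flu_paths[[ch]], stringsAsFactors = FALSE, check.names = FALSE)
    if (!identical(names(flu)[-1L], wells))
      bs_format_error(sprintf("channel '%s' matrix has different well columns than the OD matrix", ch))
    out[[paste0("flu_", ch)]] <- unlist(flu[-1L], use.names = FALSE)
  }
  out[order(match(out$well, wells), out$time_h), , drop = FALSE]
}

#' Blank-correct a plate dataset
#'
#' Subtracts the per-time-point mean blank OD and fluorescence from every
#' sample well. Corrected OD values are clipped at a positive floor `eps_od`
#' so that downstream rate computations never divide by non-positive OD. The
#' default mode is `"none"`: raw fluorescence is normalized by raw OD in the
#' rate definitions, so blank handling is an explicit opt-in.
#'
#' @param x A `plate_data` object.
#' @param mode `"none"` (identity) or `"mean_blank"`.
#' @param eps_od Positive floor (absorbance units) applied after subtraction.
#' @return A corrected `plate_data` object.
#' @export
blank_correct <- function(x, mode = c("none", "mean_blank"), eps_od = 1e-3) {
  mode <- match.arg(mode)
  if (mode == "none") return(x)
  if (!length(x$blanks))
    bs_insufficient_data_error("mode = 'mean_blank' requires at least one blank well")
  ref <- x$blanks[[1L]]$times
  od_mat <- vapply(x$blanks, function(b) {
    if (length(b$times) != length(ref)) bs_format_error("blank wells have mismatched time grids")
    b$od600
  }, numeric(length(ref)))
  od_blank <- rowMeans(as.matrix(od_mat))
  channels <- names(x$blanks[[1L]]$fluorescence)
  flu_blank <- lapply(channels, function(ch)
    rowMeans(as.matrix(vapply(x$blanks, function(b) b$fluorescence[[ch]],
                              numeric(length(ref))))))
  names(flu_blank) <- channels

  n_clipped <- 0L
  correct_ws <- function(ws) {
    if (length(ws$times) != length(ref))
      bs_format_error(sprintf("well '%s': time grid differs from the blank wells'", ws$well_id))
    od <- ws$od600 - od_blank
    if (all(od <= 0))
      bs_data_quality_error(sprintf("well '%s': OD entirely <= 0 after blank correction", ws$well_id))
    clipped <- od <= 0
    n_clipped <<- n_clipped + sum(clipped)
    od[clipped] <- eps_od
    flu <- ws$fluorescence
    for (ch in intersect(names(flu), channels)) flu[[ch]] <- flu[[ch]] - flu_blank[[ch]]
    well_series(ws$well_id, ws$times, od, flu)
  }
  x$groups <- lapply(x$groups, function(g) {
    g$series <- lapply(g$series, correct_ws)
    g
  })
  if (n_clipped > 0L)
    warning(sprintf("blank correction clipped %d OD value(s) at the floor %g", n_clipped, eps_od))
  x
}
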