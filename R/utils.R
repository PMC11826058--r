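#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can map failures to exit codes.
bs_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "biosensr_error", "error", "condition")))
}

bs_format_error <- function(msg) bs_error(msg, "bs_format_error")
bs_duplication_error <- function(msg) bs_error(msg, "bs_duplication_error")
bs_ordering_error <- function(msg) bs_error(msg, "bs_ordering_error")
bs_data_quality_error <- function(msg) bs_error(msg, "bs_data_quality_error")
bs_insufficient_data_error <- function(msg) bs_error(msg, "bs_insufficient_data_error")
bs_fit_failure <- function(msg) bs_error(msg, "bs_fit_failure")
bs_usage_error <- function(msg) bs_error(msg, "bs_usage_error")

# Run code with a temporary RNG seed, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shortest decimal representation that survives a write/read round trip.
fmt_num <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- is.finite(x) & (suppressWarnings(as.numeric(s)) != x)
  if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
  s
}

# Write a data.frame as CSV with round-trippable numerics.
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NSE column names used inside ggplot2::aes()
utils::globalVariables(c("time_h", "phi_h", "well", "concentration", "mu",
                         "rho_h", "panel", "fitted", "slope", "intercept"))
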