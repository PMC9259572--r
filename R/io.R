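#' Write a photon stream as CSV
#'
#' Plain-text dialect of the time-tagged photon layout: `#`-prefixed
#' `key=value` header lines (laser period plus any scalar metadata),
#' followed by columns `macrotime_s`, `microtime_ns`, `channel`. Floats are
#' written with 17 significant digits so a read round-trips exactly.
#'
#' @param stream A [photon_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_photon_stream <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# laser_period_ns=%.17g", stream$laser_period), con)
  meta <- stream$metadata
  for (k in names(meta)) {
    v <- meta[[k]]
    if (length(v) == 1 && (is.character(v) || is.numeric(v) || is.logical(v)))
      writeLines(sprintf("# %s=%s", k, format(v, digits = 17)), con)
  }
  writeLines("macrotime_s,microtime_ns,channel", con)
  if (length(stream) > 0)
    writeLines(sprintf("%.17g,%.17g,%s", stream$macrotime, stream$microtime,
                       as.character(stream$channel)), con)
  invisible(path)
}

#' Read a photon stream from CSV
#'
#' Reads the dialect written by [write_photon_stream()]. Validation rejects
#' rather than repairs: the file must declare `laser_period_ns`, macrotimes
#' must already be sorted (unsorted input is an error, not silently
#' sorted), microtimes must lie inside the laser period, and channel codes
#' must be `donor` or `acceptor`; each violation names the offending row.
#'
#' @param path File path.
#' @return A [photon_stream()] with the header metadata attached.
#' @export
read_photon_stream <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  if (is.null(meta$laser_period_ns))
    abort("file does not declare laser_period_ns: %s", path)
  period <- meta$laser_period_ns
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                        stringsAsFactors = FALSE)
  need <- c("macrotime_s", "microtime_ns", "channel")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort("missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) > 0) {
    if (is.unsorted(df$macrotime_s)) {
      bad <- which(diff(df$macrotime_s) < 0)[1] + 1L
      abort("macrotimes not sorted at row %d", bad)
    }
    bad <- which(df$microtime_ns < 0 | df$microtime_ns >= period)
    if (length(bad) > 0)
      abort("microtime %.4g ns outside [0, %.4g) at row %d",
            df$microtime_ns[bad[1]], period, bad[1])
    badch <- which(!df$channel %in% c("donor", "acceptor"))
    if (length(badch) > 0)
      abort("unknown channel '%s' at row %d", df$channel[badch[1]], badch[1])
  }
  meta$laser_period_ns <- NULL
  photon_stream(df$macrotime_s, df$microtime_ns, df$channel,
                laser_period = period, metadata = meta)
}

#' Write a results table as CSV at full precision
#'
#' One row per molecule/bunch/fit; numeric columns are written with 17
#' significant digits so [read_results_table()] reproduces them to machine
#' precision. An empty record set yields a header-only file.
#'
#' @param records A data frame (homogeneous records).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a results table
#'
#' @param path File path written by [write_results_table()].
#' @return Data frame with numeric columns restored.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a run configuration as YAML
#'
#' Flat key-value serialization of calibration constants, binning and fit
#' settings; round-trips losslessly through [read_run_config()].
#'
#' @param config Named list of scalar settings.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config))
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

#' Read a run configuration
#'
#' @param path YAML file written by [write_run_config()].
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  yaml::read_yaml(path)
}
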