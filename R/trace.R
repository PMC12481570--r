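#' Construct a current trace
#'
#' A `current_trace` is a uniformly sampled ionic-current recording: the
#' fundamental input of every downstream analysis. Currents are stored in
#' nanoamperes; sample index `i` (0-based) maps to time `i / sampling_rate`
#' seconds.
#'
#' @param samples Numeric vector of current samples (nA). All values must be
#'   finite; at least 2 samples are required.
#' @param sampling_rate Sampling rate in Hz (> 0). Nanopore acquisition is
#'   typically 50 kHz.
#' @param applied_voltage_mV Signed applied bias in mV (e.g. -300), or `NA`.
#' @param label Free-text label for the recording.
#' @param source Provenance string: a file path, or `"synthetic"`.
#' @return An object of class `current_trace`.
#' @seealso [read_trace()], [simulate_trace()], [detect_events()]
#' @export
#' @examples
#' tr <- current_trace(rnorm(1000, -13.6, 0.05), sampling_rate = 50000,
#'                     applied_voltage_mV = -300)
#' trace_duration(tr)
current_trace <- function(samples, sampling_rate, applied_voltage_mV = NA_real_,
                          label = "", source = "memory") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a current_trace needs at least 2 samples")
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop("non-finite sample at index ", bad[1] - 1L, " (0-based)")
  sampling_rate <- as.numeric(sampling_rate)[1]
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive, finite number (Hz)")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         applied_voltage_mV = as.numeric(applied_voltage_mV)[1],
         label = as.character(label)[1], source = as.character(source)[1]),
    class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<current_trace> %d samples @ %g Hz (%.6g s)\n",
              n, x$sampling_rate, trace_duration(x)))
  cat(sprintf("  current range [%.4g, %.4g] nA; bias %s mV; label '%s'; source %s\n",
              min(x$samples), max(x$samples),
              ifelse(is.na(x$applied_voltage_mV), "?",
                     format(x$applied_voltage_mV)),
              x$label, x$source))
  invisible(x)
}

#' Trace duration in seconds
#'
#' Exactly `(n_samples - 1) / sampling_rate`.
#' @param trace A [current_trace()].
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  (length(trace$samples) - 1) / trace$sampling_rate
}

#' Sample times of a trace
#'
#' @param trace A [current_trace()].
#' @return Numeric vector of times (s), one per sample, starting at 0.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' @export
plot.current_trace <- function(x, downsample = 1L, xlab = "time (s)",
                               ylab = "current (nA)", type = "l", ...) {
  idx <- seq(1L, length(x$samples), by = max(1L, as.integer(downsample)))
  graphics::plot(trace_times(x)[idx], x$samples[idx],
                 type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

## ---- trace file I/O --------------------------------------------------------

# Parse '#'-prefixed "key=value" comment lines into a named list.
parse_meta_comments <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

#' Read a current trace from a file
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{`delimited`}{CSV/TSV with header `time_s,current_nA` or a single
#'     `current_nA` column. `#`-prefixed comment lines carry `key=value`
#'     metadata (`sampling_rate`, `applied_voltage_mV`, `label`). When a time
#'     column is present it must advance in uniform steps; the implied
#'     sampling rate is cross-checked against any supplied rate to within
#'     1 part in 1e4.}
#'   \item{`container`}{A flat binary array of little-endian doubles with a
#'     JSON sidecar `<path>.json` holding `n`, `sampling_rate`,
#'     `applied_voltage_mV` and `label`. Round-trips samples bit-exactly.}
#' }
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.bin` is container, otherwise
#'   delimited), `"delimited"` or `"container"`.
#' @param sampling_rate Optional override / requirement (Hz). Mandatory for a
#'   single-column delimited file with no metadata line.
#' @param applied_voltage_mV,label Optional metadata overrides.
#' @return A [current_trace()].
#' @export
read_trace <- function(path, format = c("auto", "delimited", "container"),
                       sampling_rate = NULL, applied_voltage_mV = NULL,
                       label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.bin$", path)) "container" else "delimited"
  if (format == "container")
    return(read_trace_container(path, sampling_rate, applied_voltage_mV, label))

  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- parse_meta_comments(lines[is_comment])
  if (!is.null(sampling_rate)) meta$sampling_rate <- sampling_rate
  if (!is.null(applied_voltage_mV)) meta$applied_voltage_mV <- applied_voltage_mV
  if (!is.null(label)) meta$label <- label

  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("no data rows in ", path)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep)

  if ("current_nA" %in% names(df)) {
    cur <- df$current_nA
  } else if (ncol(df) == 1L) {
    cur <- df[[1]]
  } else stop("expected a 'current_nA' column in ", path)

  bad <- which(!is.finite(cur))
  if (length(bad))
    stop("non-finite current sample at row ", bad[1], " of ", path)

  if ("time_s" %in% names(df)) {
    tt <- df$time_s
    steps <- diff(tt)
    if (any(steps <= 0)) stop("non-increasing time steps in ", path)
    rel_spread <- (max(steps) - min(steps)) / stats::median(steps)
    if (rel_spread > 1e-4)
      stop("non-uniform time steps in ", path,
           " (first offending row ", which.max(abs(steps - stats::median(steps))) + 1L, ")")
    fs_time <- 1 / stats::median(steps)
    if (!is.null(meta$sampling_rate)) {
      if (abs(fs_time - meta$sampling_rate) / meta$sampling_rate > 1e-4)
        stop(sprintf("time column implies %.6g Hz but metadata says %.6g Hz",
                     fs_time, meta$sampling_rate))
    } else meta$sampling_rate <- fs_time
  }
  if (is.null(meta$sampling_rate))
    stop("sampling rate missing: no time_s column and no sampling_rate metadata")

  current_trace(cur, meta$sampling_rate,
                applied_voltage_mV = meta$applied_voltage_mV %||% NA_real_,
                label = meta$label %||% "", source = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_trace_container <- function(path, sampling_rate = NULL,
                                 applied_voltage_mV = NULL, label = NULL) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("container sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = meta$n, size = 8, endian = "little")
  if (length(x) != meta$n)
    stop("container truncated: expected ", meta$n, " samples, got ", length(x))
  current_trace(x, sampling_rate %||% meta$sampling_rate,
                applied_voltage_mV = applied_voltage_mV %||%
                  (meta$applied_voltage_mV %||% NA_real_),
                label = label %||% (meta$label %||% ""), source = path)
}

#' Write a current trace to a file
#'
#' @param trace A [current_trace()].
#' @param path Output path.
#' @param format `"container"` (binary doubles + JSON sidecar, bit-exact
#'   round trip) or `"delimited"` (CSV with metadata comments).
#' @param time_column For delimited output, whether to write a `time_s`
#'   column alongside `current_nA`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("container", "delimited"),
                        time_column = FALSE) {
  stopifnot(inherits(trace, "current_trace"))
  format <- match.arg(format)
  if (format == "container") {
    con <- file(path, "wb")
    writeBin(trace$samples, con, size = 8, endian = "little")
    close(con)
    jsonlite::write_json(
      list(n = length(trace$samples), sampling_rate = trace$sampling_rate,
           applied_voltage_mV = trace$applied_voltage_mV, label = trace$label),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    hdr <- c(sprintf("# sampling_rate=%.17g", trace$sampling_rate),
             if (!is.na(trace$applied_voltage_mV))
               sprintf("# applied_voltage_mV=%.17g", trace$applied_voltage_mV),
             if (nzchar(trace$label)) paste0("# label=", trace$label))
    if (time_column) {
      body <- c("time_s,current_nA",
                sprintf("%.17g,%.17g", trace_times(trace), trace$samples))
    } else {
      body <- c("current_nA", sprintf("%.17g", trace$samples))
    }
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

## ---- I-V sweeps ------------------------------------------------------------

#' Construct an I-V dataset
#'
#' An ordered current-voltage sweep used for pore conductance estimation.
#'
#' @param voltage_mV Applied voltages (mV); at least 3 distinct values.
#' @param current_nA Measured currents (nA), same length.
#' @return An object of class `iv_dataset` (a data frame with columns
#'   `voltage_mV`, `current_nA`, sorted by voltage).
#' @seealso [fit_iv()]
#' @export
iv_dataset <- function(voltage_mV, current_nA) {
  voltage_mV <- as.numeric(voltage_mV); current_nA <- as.numeric(current_nA)
  if (length(voltage_mV) != length(current_nA))
    stop("voltage and current must have equal length")
  if (!all(is.finite(voltage_mV)) || !all(is.finite(current_nA)))
    stop("I-V points must be finite")
  if (length(unique(voltage_mV)) < 3L)
    stop("need at least 3 distinct voltages")
  o <- order(voltage_mV)
  df <- data.frame(voltage_mV = voltage_mV[o], current_nA = current_nA[o])
  class(df) <- c("iv_dataset", "data.frame")
  df
}

#' Read an I-V sweep from a CSV file
#'
#' Expects columns `voltage_mV,current_nA`; `#` comment lines are ignored.
#' @param path File path.
#' @return An [iv_dataset()].
#' @export
read_iv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("voltage_mV", "current_nA") %in% names(df)))
    stop("expected columns voltage_mV,current_nA in ", path)
  iv_dataset(df$voltage_mV, df$current_nA)
}

## ---- event tables ----------------------------------------------------------

event_table_columns <- c("start_index", "end_index", "dwell_ms", "blockage_pct",
                         "peak_blockage_pct", "baseline_nA", "depth_nA",
                         "t_extremum_frac", "padded_start", "padded_end",
                         "shape_class", "dwell_class")

#' Construct an event table
#'
#' A data frame of translocation-event summaries, one row per event, carrying
#' the detection configuration and trace label as attributes. Indices are
#' 0-based, half-open `[start_index, end_index)`.
#'
#' @param df Data frame with at least `start_index`, `end_index`, `dwell_ms`,
#'   `blockage_pct`, `baseline_nA`. Optional classification columns are
#'   filled with `NA` when absent.
#' @param config Detection configuration snapshot (list or
#'   [detection_config()]), or `NULL`.
#' @param trace_label Label of the source trace.
#' @return An object of class `event_table` (a data frame).
#' @export
event_table <- function(df, config = NULL, trace_label = "") {
  df <- as.data.frame(df)
  needed <- c("start_index", "end_index", "dwell_ms", "blockage_pct", "baseline_nA")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("event table missing columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(event_table_columns, names(df)))
    df[[col]] <- rep(if (col %in% c("shape_class", "dwell_class"))
      NA_character_ else NA_real_, nrow(df))
  df <- df[, event_table_columns]
  if (nrow(df) > 1L) {
    o <- order(df$start_index)
    df <- df[o, , drop = FALSE]
    if (any(df$end_index[-nrow(df)] > df$start_index[-1]))
      stop("events overlap; an event table must hold disjoint, ordered events")
  }
  rownames(df) <- NULL
  structure(df, config = config, trace_label = trace_label,
            class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events (trace '%s')\n",
              nrow(x), attr(x, "trace_label") %||% ""))
  if (nrow(x)) {
    cat(sprintf("  dwell %.3g-%.3g ms; blockage %.3g-%.3g %%\n",
                min(x$dwell_ms), max(x$dwell_ms),
                min(x$blockage_pct), max(x$blockage_pct)))
    print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' @export
plot.event_table <- function(x, log = "x",
                             xlab = "dwell time (ms)",
                             ylab = "current blockage (%)", ...) {
  graphics::plot(x$dwell_ms, x$blockage_pct, log = log,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write an event table
#'
#' The `delimited` format writes a CSV of events plus a JSON sidecar
#' `<path>.json` holding the detection-configuration snapshot and trace
#' label, so a table round-trips through [read_events()] at full precision.
#' The `structured` format writes a single JSON document.
#'
#' @param table An [event_table()].
#' @param path Output path.
#' @param format `"delimited"` or `"structured"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, format = c("delimited", "structured")) {
  stopifnot(inherits(table, "event_table"))
  format <- match.arg(format)
  # re-validate the disjointness invariant before touching the disk
  event_table(as.data.frame(table), attr(table, "config"),
              attr(table, "trace_label"))
  meta <- list(trace_label = attr(table, "trace_label") %||% "",
               config = config_snapshot(attr(table, "config")))
  if (format == "delimited") {
    con <- file(path, "w")
    df <- as.data.frame(table)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    jsonlite::write_json(c(meta, list(events = as.data.frame(table))),
                         path, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
  }
  invisible(path)
}

config_snapshot <- function(config) {
  if (is.null(config)) return(NULL)
  unclass(config)
}

#' Read an event table written by [write_events()]
#'
#' @param path Path to the CSV (delimited) or JSON (structured) file.
#' @param format `"auto"` (by extension), `"delimited"` or `"structured"`.
#' @return An [event_table()].
#' @export
read_events <- function(path, format = c("auto", "delimited", "structured")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path)) "structured" else "delimited"
  if (format == "delimited") {
    df <- utils::read.csv(path, colClasses = NA)
    meta <- if (file.exists(paste0(path, ".json")))
      jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    else list()
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(doc$events)
    if (nrow(df) == 0L)
      df <- as.data.frame(stats::setNames(
        rep(list(numeric(0)), length(event_table_columns)), event_table_columns))
    meta <- doc[c("trace_label", "config")]
  }
  event_table(df, config = meta$config, trace_label = meta$trace_label %||% "")
}
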