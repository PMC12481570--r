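#' Classify events by dwell time
#'
#' Assigns each dwell time to `short` (below the first edge), `medium`
#' (between the edges, boundaries included) or `long` (above the second
#' edge). The default edges 0.3 and 1.0 ms separate fast collapsed
#' translocations, partially structured molecules and long, structured
#' concatemers. Values exactly on an edge are medium in every code path
#' (the documented closed-interval rule).
#'
#' @param dwell_ms Numeric dwell times (ms), or a data frame / event table
#'   with a `dwell_ms` column.
#' @param edges_ms Two strictly increasing positive class edges (ms).
#' @return A factor with levels `short`, `medium`, `long`.
#' @export
#' @examples
#' classify_dwell(c(0.2, 0.3, 0.5, 1.0, 88.3))
classify_dwell <- function(dwell_ms, edges_ms = c(0.3, 1.0)) {
  if (is.data.frame(dwell_ms)) dwell_ms <- dwell_ms$dwell_ms
  if (length(edges_ms) != 2L || !all(is.finite(edges_ms)) ||
      edges_ms[1] <= 0 || edges_ms[2] <= edges_ms[1])
    stop("edges_ms must be two strictly increasing positive values")
  x <- as.numeric(dwell_ms)
  out <- ifelse(x < edges_ms[1], "short",
                ifelse(x > edges_ms[2], "long", "medium"))
  factor(out, levels = c("short", "medium", "long"))
}

#' Classify events by blockade asymmetry
#'
#' Uses the fractional position of the deepest blockade within the event
#' (`t_extremum_frac`, see [compute_features()]): an extremum early in the
#' event (`< f_lo`) marks a `deep_first` morphology (a deep blockade
#' followed by a sloping recovery), a late extremum (`> f_hi`) a
#' `ramp_then_deep` morphology (a sloping lead-in ending in a deep
#' blockade), anything between is `symmetric`. Because the extremum of a
#' flat-bottomed event is located at its plateau midpoint, noise-free square
#' events are symmetric.
#'
#' @param t_extremum_frac Numeric fractions in `[0, 1]`, or a data frame /
#'   event table with a `t_extremum_frac` column.
#' @param f_lo,f_hi Class cut points (defaults 0.35 / 0.65).
#' @return A factor with levels `deep_first`, `symmetric`, `ramp_then_deep`.
#' @export
classify_shape <- function(t_extremum_frac, f_lo = 0.35, f_hi = 0.65) {
  if (is.data.frame(t_extremum_frac))
    t_extremum_frac <- t_extremum_frac$t_extremum_frac
  if (!(f_lo > 0 && f_hi < 1 && f_lo < f_hi))
    stop("need 0 < f_lo < f_hi < 1")
  x <- as.numeric(t_extremum_frac)
  if (anyNA(x)) stop("t_extremum_frac missing (zero-depth event?)")
  out <- ifelse(x < f_lo, "deep_first",
                ifelse(x > f_hi, "ramp_then_deep", "symmetric"))
  factor(out, levels = c("deep_first", "symmetric", "ramp_then_deep"))
}

#' Summarise event classes for one condition
#'
#' Counts and proportions of the dwell-time classes and (when
#' `t_extremum_frac` is available) the shape classes of an event table.
#'
#' @param events An [event_table()] or data frame with `dwell_ms` and
#'   optionally `t_extremum_frac`; non-empty.
#' @param edges_ms Dwell class edges, see [classify_dwell()].
#' @param f_lo,f_hi Shape cut points, see [classify_shape()].
#' @return An object of class `event_class_summary` with `dwell_counts`,
#'   `dwell_proportions`, `shape_counts`, `shape_proportions`, `n_events`.
#' @export
summarize_classes <- function(events, edges_ms = c(0.3, 1.0),
                              f_lo = 0.35, f_hi = 0.65) {
  if (is.null(nrow(events)) || nrow(events) == 0L) stop("empty event table")
  dcl <- classify_dwell(events$dwell_ms, edges_ms)
  dwell_counts <- table(dcl)
  shape_counts <- shape_props <- NULL
  if (!is.null(events$t_extremum_frac) && !anyNA(events$t_extremum_frac)) {
    scl <- classify_shape(events$t_extremum_frac, f_lo, f_hi)
    shape_counts <- table(scl)
    shape_props <- as.numeric(shape_counts) / nrow(events)
    names(shape_props) <- names(shape_counts)
  }
  dwell_props <- as.numeric(dwell_counts) / nrow(events)
  names(dwell_props) <- names(dwell_counts)
  structure(list(n_events = nrow(events),
                 dwell_counts = c(unclass(dwell_counts)),
                 dwell_proportions = dwell_props,
                 shape_counts = if (!is.null(shape_counts)) c(unclass(shape_counts)),
                 shape_proportions = shape_props,
                 edges_ms = edges_ms, f_lo = f_lo, f_hi = f_hi),
            class = "event_class_summary")
}

#' @export
print.event_class_summary <- function(x, ...) {
  cat(sprintf("<event_class_summary> n = %d events\n", x$n_events))
  cat(sprintf("  dwell classes (edges %g/%g ms): %s\n",
              x$edges_ms[1], x$edges_ms[2],
              paste(sprintf("%s %d (%.1f%%)", names(x$dwell_counts),
                            x$dwell_counts, 100 * x$dwell_proportions),
                    collapse = ", ")))
  if (!is.null(x$shape_counts))
    cat(sprintf("  shape classes (cuts %g/%g): %s\n", x$f_lo, x$f_hi,
                paste(sprintf("%s %d (%.1f%%)", names(x$shape_counts),
                              x$shape_counts, 100 * x$shape_proportions),
                      collapse = ", ")))
  invisible(x)
}

#' Expected dwell-class proportions under an exponential model
#'
#' For exponentially distributed dwell times with mean `tau_ms`, the
#' probability of each class follows from the survival function
#' `P(T > t) = exp(-t / tau)`.
#'
#' @param tau_ms Exponential mean (ms).
#' @param edges_ms Class edges (ms).
#' @return Named numeric vector of probabilities for short/medium/long.
#' @export
expected_dwell_proportions <- function(tau_ms, edges_ms = c(0.3, 1.0)) {
  stopifnot(tau_ms > 0)
  s1 <- exp(-edges_ms[1] / tau_ms)
  s2 <- exp(-edges_ms[2] / tau_ms)
  c(short = 1 - s1, medium = s1 - s2, long = s2)
}

#' Export per-class event excerpts
#'
#' Writes one CSV per event (its padded excerpt: `time_s,current_nA`) into
#' per-class subdirectories, mirroring a gallery presentation of short,
#' medium and long events.
#'
#' @param trace The source [current_trace()].
#' @param events An [event_table()] with classification columns filled, or
#'   raw; classes are (re)computed from the defaults when absent.
#' @param dir Output directory (created if needed).
#' @param by `"dwell_class"` or `"shape_class"`.
#' @return Invisibly, the written file paths.
#' @export
export_event_gallery <- function(trace, events, dir, by = c("dwell_class",
                                                            "shape_class")) {
  by <- match.arg(by)
  if (nrow(events) == 0L) return(invisible(character(0)))
  cls <- if (by == "dwell_class") as.character(classify_dwell(events$dwell_ms))
         else as.character(classify_shape(events$t_extremum_frac))
  paths <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    sub <- file.path(dir, cls[i])
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    idx <- (events$padded_start[i] + 1L):events$padded_end[i]
    paths[i] <- file.path(sub, sprintf("event_%05d.csv", i))
    utils::write.csv(data.frame(time_s = (idx - 1) / trace$sampling_rate,
                                current_nA = trace$samples[idx]),
                     paths[i], row.names = FALSE)
  }
  invisible(paths)
}
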