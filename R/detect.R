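#' Detection configuration
#'
#' The four extraction parameters of the event-extraction algorithm —
#' baseline level (`lvl0`), detection threshold (`lvl1`), baseline
#' `tolerance` and visualization `padding` — plus auxiliaries controlling
#' merging and minimum event width.
#'
#' `lvl0` is the open-pore current (nA) or `"auto"` to estimate it with
#' [estimate_baseline()]. `lvl1` is the minimum deviation from `lvl0`
#' required to trigger an event, given either in nA or as a fraction of
#' `|lvl0|` (`lvl1_units`). `tolerance` is the band around `lvl0` (nA)
#' within which the signal counts as baseline; it closes event boundaries.
#' `padding` only widens exported excerpts and never affects dwell or
#' blockage.
#'
#' @param lvl0 Baseline current (nA, signed) or `"auto"`.
#' @param lvl1 Detection threshold deviation (nA, or fraction of `|lvl0|`).
#' @param tolerance Baseline tolerance band (nA, > 0, < the lvl1 deviation).
#' @param padding Samples kept before/after each event in excerpts (>= 0).
#' @param min_event_samples Minimum event width kept (samples, >= 1).
#' @param merge_gap_samples Events separated by at most this many samples are
#'   merged (>= 0).
#' @param lvl1_units `"nA"` or `"fraction"`.
#' @return An object of class `detection_config`.
#' @seealso [detect_events()]
#' @export
#' @examples
#' detection_config(lvl0 = -13.6, lvl1 = 0.5, tolerance = 0.2)
detection_config <- function(lvl0 = "auto", lvl1, tolerance, padding = 100L,
                             min_event_samples = 3L, merge_gap_samples = 0L,
                             lvl1_units = c("nA", "fraction")) {
  lvl1_units <- match.arg(lvl1_units)
  if (!identical(lvl0, "auto")) {
    lvl0 <- as.numeric(lvl0)
    if (!is.finite(lvl0) || lvl0 == 0) stop("lvl0 must be nonzero and finite, or 'auto'")
  }
  stopifnot(is.finite(lvl1), lvl1 > 0, is.finite(tolerance), tolerance > 0,
            padding >= 0, min_event_samples >= 1, merge_gap_samples >= 0)
  if (lvl1_units == "fraction" && lvl1 >= 1)
    stop("fractional lvl1 must be < 1")
  cfg <- structure(list(lvl0 = lvl0, lvl1 = lvl1, tolerance = tolerance,
                        padding = as.integer(padding),
                        min_event_samples = as.integer(min_event_samples),
                        merge_gap_samples = as.integer(merge_gap_samples),
                        lvl1_units = lvl1_units,
                        polarity = "blockade_toward_zero"),
                   class = "detection_config")
  if (!identical(cfg$lvl0, "auto") && lvl1_deviation(cfg) <= tolerance)
    stop("the lvl1 deviation must exceed the tolerance band")
  cfg
}

lvl1_deviation <- function(config, lvl0 = config$lvl0) {
  if (config$lvl1_units == "fraction") config$lvl1 * abs(lvl0) else config$lvl1
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf("<detection_config> lvl0=%s, lvl1=%g %s, tolerance=%g nA, padding=%d\n",
              if (identical(x$lvl0, "auto")) "auto" else format(x$lvl0),
              x$lvl1, x$lvl1_units, x$tolerance, x$padding))
  cat(sprintf("  min_event_samples=%d, merge_gap_samples=%d, polarity=%s\n",
              x$min_event_samples, x$merge_gap_samples, x$polarity))
  invisible(x)
}

#' Robust baseline estimation
#'
#' Estimates the open-pore level (`lvl0`) and noise SD from a trace that may
#' contain events. The `exclude_fraction` of samples farthest from the
#' global median is discarded; `lvl0` is the median of the remainder and the
#' noise SD is `1.4826 x` their median absolute deviation.
#'
#' @param trace A [current_trace()] with at least 100 samples.
#' @param exclude_fraction Fraction in `[0, 0.5)` of samples to discard
#'   (default 0.1; set above the expected event occupancy).
#' @return A list with elements `lvl0` (nA) and `noise_sd` (nA).
#' @export
estimate_baseline <- function(trace, exclude_fraction = 0.1) {
  stopifnot(inherits(trace, "current_trace"))
  if (length(trace$samples) < 100L)
    stop("automatic baseline estimation needs at least 100 samples")
  if (exclude_fraction < 0 || exclude_fraction >= 0.5)
    stop("exclude_fraction must lie in [0, 0.5)")
  x <- trace$samples
  m <- stats::median(x)
  if (exclude_fraction > 0) {
    keep_n <- ceiling(length(x) * (1 - exclude_fraction))
    x <- x[order(abs(x - m))[seq_len(keep_n)]]
  }
  lvl0 <- stats::median(x)
  list(lvl0 = lvl0, noise_sd = stats::mad(x, center = lvl0))
}

#' Detect translocation events in a current trace
#'
#' Implements threshold-triggered, tolerance-closed event extraction. An
#' event opens at the first sample whose deviation from `lvl0` toward zero
#' strictly exceeds the `lvl1` deviation. Its boundaries are then extended
#' outward to the nearest samples on each side lying within `tolerance` of
#' `lvl0`: the event starts one sample after the last in-tolerance sample
#' before the crossing and ends at the first in-tolerance sample after
#' re-entry (half-open). Events separated by at most `merge_gap_samples`
#' are merged; events narrower than `min_event_samples` are dropped; events
#' whose tolerance extension reaches a trace boundary cannot be measured and
#' are excluded (their count is returned in the `n_boundary_discarded`
#' attribute).
#'
#' A deviation exactly equal to the `lvl1` deviation does not trigger
#' (strict inequality).
#'
#' @param trace A [current_trace()].
#' @param config A [detection_config()]. With `lvl0 = "auto"` the baseline
#'   is estimated by [estimate_baseline()].
#' @param exclude_fraction Passed to [estimate_baseline()] in auto mode.
#' @return An [event_table()] of disjoint, ordered events with features from
#'   [compute_features()]. Attributes: `config` (snapshot with resolved
#'   `lvl0`), `n_boundary_discarded`, `noise_sd` (auto mode only),
#'   `sampling_rate`.
#' @export
detect_events <- function(trace, config, exclude_fraction = 0.1) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(config, "detection_config"))
  noise_sd <- NA_real_
  if (identical(config$lvl0, "auto")) {
    est <- estimate_baseline(trace, exclude_fraction)
    config$lvl0 <- est$lvl0
    noise_sd <- est$noise_sd
  }
  lvl0 <- config$lvl0
  if (!is.finite(lvl0) || lvl0 == 0) stop("unresolved or zero lvl0")
  thr <- lvl1_deviation(config, lvl0)
  if (thr <= config$tolerance)
    stop("the lvl1 deviation must exceed the tolerance band")

  x <- trace$samples
  n <- length(x)
  sgn <- sign(lvl0)
  dev_toward_zero <- (lvl0 - x) * sgn       # > 0 for blockades
  over <- dev_toward_zero > thr             # strict
  in_tol <- abs(x - lvl0) <= config$tolerance

  intervals <- NULL
  n_boundary <- 0L
  if (any(over)) {
    idx <- seq_len(n)
    prev_tol <- cummax(ifelse(in_tol, idx, 0L))          # last in-tol <= i
    nxt <- rev(cummax(rev(ifelse(in_tol, n + 1L - idx, 0L))))
    next_tol <- ifelse(nxt == 0L, 0L, n + 1L - nxt)      # first in-tol >= i

    r <- rle(over)
    ends_run <- cumsum(r$lengths)
    starts_run <- ends_run - r$lengths + 1L
    c1 <- starts_run[r$values]   # first over-threshold sample of each run
    c2 <- ends_run[r$values]     # last

    s <- ifelse(c1 > 1L, prev_tol[c1 - 1L], 0L)
    e <- ifelse(c2 < n, next_tol[c2 + 1L], 0L)
    open_left <- s == 0L
    open_right <- e == 0L
    start1 <- s + 1L             # 1-based inclusive
    end1 <- e                    # 1-based exclusive

    m <- cbind(start1, end1, open_left, open_right)
    m <- unique(m)
    # merge runs that resolved to overlapping/identical tolerance extents,
    # then runs separated by <= merge_gap_samples
    o <- order(m[, 1], m[, 2])
    m <- m[o, , drop = FALSE]
    merged <- list()
    cur <- m[1, ]
    if (nrow(m) > 1) for (i in 2:nrow(m)) {
      row <- m[i, ]
      if (row[1] - cur[2] <= config$merge_gap_samples || row[1] <= cur[2]) {
        cur[2] <- max(cur[2], row[2])
        cur[3] <- cur[3] | row[3]
        cur[4] <- cur[4] | row[4]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- row
      }
    }
    merged[[length(merged) + 1L]] <- cur
    m <- do.call(rbind, merged)

    boundary <- m[, 3] | m[, 4]
    n_boundary <- sum(boundary)
    m <- m[!boundary, , drop = FALSE]
    if (nrow(m)) {
      wide_enough <- (m[, 2] - m[, 1]) >= config$min_event_samples
      m <- m[wide_enough, , drop = FALSE]
    }
    if (nrow(m)) intervals <- m[, 1:2, drop = FALSE]
  }

  if (is.null(intervals)) {
    tab <- event_table(empty_event_df(), config = config,
                       trace_label = trace$label)
  } else {
    rows <- lapply(seq_len(nrow(intervals)), function(i) {
      compute_features(trace, intervals[i, 1] - 1L, intervals[i, 2] - 1L,
                       lvl0 = lvl0, padding = config$padding)
    })
    tab <- event_table(do.call(rbind, rows), config = config,
                       trace_label = trace$label)
  }
  attr(tab, "n_boundary_discarded") <- n_boundary
  attr(tab, "noise_sd") <- noise_sd
  attr(tab, "sampling_rate") <- trace$sampling_rate
  tab
}

empty_event_df <- function() {
  as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(event_table_columns)), event_table_columns))
}

#' Compute per-event features
#'
#' Given an event window (0-based, half-open `[start, end)`) on a trace,
#' computes dwell time, mean and peak percentage blockage and the fractional
#' position of the deepest blockade:
#' \itemize{
#'   \item `dwell_ms = (end - start) / sampling_rate * 1000`
#'   \item `depth_nA = |lvl0| - |mean event current|`;
#'     `blockage_pct = 100 * depth_nA / |lvl0|`
#'   \item `peak_blockage_pct` uses the sample of smallest current magnitude
#'   \item `t_extremum_frac` locates the extremum as a fraction of the event;
#'     for an extended plateau at the extremum the plateau midpoint is used,
#'     so a flat-bottomed event is symmetric rather than tied to its first
#'     sample.
#' }
#'
#' @param trace A [current_trace()].
#' @param start,end 0-based half-open sample bounds, `0 <= start < end <= n`.
#' @param lvl0 Baseline current (nA, nonzero).
#' @param padding Samples of context recorded in `padded_start`/`padded_end`
#'   (clipped to the trace).
#' @return A one-row data frame with the [event_table()] feature columns.
#' @export
compute_features <- function(trace, start, end, lvl0, padding = 0L) {
  stopifnot(inherits(trace, "current_trace"))
  n <- length(trace$samples)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end > n || start >= end)
    stop("need 0 <= start < end <= n_samples (0-based, half-open)")
  if (!is.finite(lvl0) || lvl0 == 0) stop("lvl0 must be nonzero")
  x <- trace$samples[(start + 1L):end]
  m <- end - start
  ax <- abs(x)
  depth <- abs(lvl0) - abs(mean(x))
  peak_depth <- abs(lvl0) - min(ax)
  # extremum position: midpoint of the first contiguous run at minimum |I|
  at_min <- which(ax == min(ax))
  run_end <- at_min[c(diff(at_min) != 1L, TRUE)][1]
  run <- at_min[at_min <= run_end]
  mid0 <- (run[1] - 1 + run_end - 1) / 2     # 0-based within event
  data.frame(start_index = start, end_index = end,
             dwell_ms = m / trace$sampling_rate * 1000,
             blockage_pct = 100 * depth / abs(lvl0),
             peak_blockage_pct = 100 * peak_depth / abs(lvl0),
             baseline_nA = lvl0, depth_nA = depth,
             t_extremum_frac = mid0 / m,
             padded_start = max(0L, start - as.integer(padding)),
             padded_end = min(n, end + as.integer(padding)),
             shape_class = NA_character_, dwell_class = NA_character_)
}
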