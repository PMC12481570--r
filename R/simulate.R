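#' Event deflection profiles
#'
#' Phenomenological blockade morphologies observed in long-concatemer
#' translocations: a flat blockade (`square`), a deep entry relaxing toward
#' the baseline (`deep_first`), and a gradual entry ending in a deep blockade
#' (`ramp_then_deep`). Profiles are positive deflections (nA, toward zero
#' current); the asymmetric shapes decay linearly between full depth and 25%
#' of full depth, a fixed package constant.
#'
#' @param shape One of `"square"`, `"deep_first"`, `"ramp_then_deep"`.
#' @param n_samples Number of samples (>= 2).
#' @param depth_nA Full deflection depth (nA, > 0).
#' @return Numeric vector of `n_samples` deflections; the extremum equals
#'   `depth_nA` and every sample deflects by at least `0.25 * depth_nA`.
#' @export
#' @examples
#' make_shape("deep_first", 8, 1.5)
make_shape <- function(shape, n_samples, depth_nA) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop("a shape needs at least 2 samples")
  if (depth_nA <= 0) stop("depth_nA must be positive")
  switch(as.character(shape),
    square = rep(depth_nA, n_samples),
    deep_first = seq(depth_nA, shape_residual_frac * depth_nA,
                     length.out = n_samples),
    ramp_then_deep = seq(shape_residual_frac * depth_nA, depth_nA,
                         length.out = n_samples),
    stop("unknown shape label: ", shape))
}

# exit/entry residual deflection for the asymmetric morphologies
shape_residual_frac <- 0.25

shape_labels <- c("square", "deep_first", "ramp_then_deep")

#' Specify a synthetic nanopore recording
#'
#' The generative model behind [simulate_trace()]: an open-pore baseline with
#' additive Gaussian noise, downward blockade events arriving as a homogeneous
#' Poisson process (thinned to respect a refractory gap), exponential dwell
#' times, Gaussian(-mixture) blockage depths, a mixture of blockade
#' morphologies, and an optional low-pass filter emulating the recording
#' chain. Defaults mirror a typical solid-state SiN pore run: 50 kHz
#' sampling, 10 kHz filtering, -300 mV bias with a ~13.6 nA open-pore
#' current, and a two-population blockage mixture at 13.2% and 18.4%.
#'
#' @param duration_s Recording length (s).
#' @param seed Integer seed; mandatory, every draw is derived from it.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param baseline_nA Open-pore current (nA), signed; negative under negative
#'   bias. Events always deflect toward zero.
#' @param noise_sd_nA Baseline noise SD (nA RMS).
#' @param event_rate_per_s Poisson arrival rate (events/s).
#' @param dwell_tau_ms Mean of the exponential dwell-time distribution (ms).
#'   Ignored when `dwell_ms` is given.
#' @param dwell_ms Optional explicit dwell times (ms), recycled over events.
#' @param blockage_components List of `c(weight, mean_pct, sd_pct)` triples;
#'   weights must sum to 1, means in (0, 100).
#' @param shape_mix Named proportions over [shape_labels] summing to 1.
#' @param filter_cutoff_hz Low-pass cutoff (Hz), or `NULL` to disable.
#' @param refractory_gap_samples Minimum baseline gap enforced between
#'   consecutive injected events and at the trace ends (samples).
#' @param label Label recorded on the generated trace.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(duration_s, seed,
                            sampling_rate_hz = 50000,
                            baseline_nA = -13.6,
                            noise_sd_nA = 0.05,
                            event_rate_per_s = 10,
                            dwell_tau_ms = 4.7,
                            dwell_ms = NULL,
                            blockage_components = list(c(0.5, 13.2, 1.0),
                                                       c(0.5, 18.4, 1.0)),
                            shape_mix = c(square = 0.5, deep_first = 0.25,
                                          ramp_then_deep = 0.25),
                            filter_cutoff_hz = 10000,
                            refractory_gap_samples = 250,
                            label = "synthetic") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(duration_s > 0, sampling_rate_hz > 0, noise_sd_nA >= 0,
            event_rate_per_s >= 0, refractory_gap_samples >= 0)
  if (baseline_nA == 0) stop("baseline_nA must be nonzero")
  comps <- do.call(rbind, lapply(blockage_components, function(x) {
    x <- as.numeric(x)
    if (length(x) != 3L) stop("each blockage component is (weight, mean_pct, sd_pct)")
    x
  }))
  colnames(comps) <- c("weight", "mean_pct", "sd_pct")
  if (any(comps[, "weight"] < 0) || abs(sum(comps[, "weight"]) - 1) > 1e-9)
    stop("component weights must be nonnegative and sum to 1")
  if (any(comps[, "mean_pct"] <= 0) || any(comps[, "mean_pct"] >= 100))
    stop("component mean_pct must lie in (0, 100)")
  if (any(comps[, "sd_pct"] < 0)) stop("component sd_pct must be nonnegative")
  shape_mix <- shape_mix[shape_labels]
  if (anyNA(shape_mix) || any(shape_mix < 0) || abs(sum(shape_mix) - 1) > 1e-9)
    stop("shape_mix must give nonnegative proportions over ",
         paste(shape_labels, collapse = "/"), " summing to 1")
  if (is.null(dwell_ms)) {
    if (dwell_tau_ms <= 0) stop("dwell_tau_ms must be positive")
    mean_dwell_s <- dwell_tau_ms / 1000
  } else {
    if (any(dwell_ms <= 0)) stop("explicit dwell_ms must be positive")
    mean_dwell_s <- mean(dwell_ms) / 1000
  }
  if (event_rate_per_s * mean_dwell_s > 0.5)
    stop("expected event occupancy (rate x mean dwell = ",
         signif(event_rate_per_s * mean_dwell_s, 3),
         ") exceeds 0.5 of the recording; events would merge pathologically")
  if (!is.null(filter_cutoff_hz) &&
      (filter_cutoff_hz <= 0 || filter_cutoff_hz >= sampling_rate_hz / 2))
    stop("filter_cutoff_hz must lie in (0, sampling_rate/2)")
  structure(list(duration_s = duration_s, seed = as.integer(seed),
                 sampling_rate_hz = sampling_rate_hz, baseline_nA = baseline_nA,
                 noise_sd_nA = noise_sd_nA, event_rate_per_s = event_rate_per_s,
                 dwell_tau_ms = dwell_tau_ms, dwell_ms = dwell_ms,
                 blockage_components = comps, shape_mix = shape_mix,
                 filter_cutoff_hz = filter_cutoff_hz,
                 refractory_gap_samples = as.integer(refractory_gap_samples),
                 label = label),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("<simulation_spec> %g s @ %g Hz, baseline %g nA, noise %g nA\n",
              x$duration_s, x$sampling_rate_hz, x$baseline_nA, x$noise_sd_nA))
  cat(sprintf("  rate %g /s, dwell tau %g ms, %d blockage component(s), seed %d\n",
              x$event_rate_per_s, x$dwell_tau_ms,
              nrow(x$blockage_components), x$seed))
  invisible(x)
}

#' Simulate a nanopore recording with ground truth
#'
#' Generates a [current_trace()] from a [simulation_spec()] together with a
#' ledger of every injected event, for validating detection, fitting and
#' classification. Deterministic for a fixed seed.
#'
#' Ledger columns (indices 0-based, half-open): `start_index`, `end_index`,
#' `true_dwell_ms` (the realised injected width), `true_blockage_pct` (the
#' mean deflection of the injected profile as a percentage of the open-pore
#' magnitude — the quantity event detection estimates), `true_peak_pct` (the
#' drawn peak depth) and `shape`.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `trace` ([current_trace()]) and `ledger`
#'   (data frame).
#' @export
#' @examples
#' sim <- simulate_trace(simulation_spec(duration_s = 1, seed = 7,
#'                                       filter_cutoff_hz = NULL))
#' nrow(sim$ledger)
simulate_trace <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  fs <- spec$sampling_rate_hz
  n <- round(spec$duration_s * fs)
  gap <- spec$refractory_gap_samples

  x <- if (spec$noise_sd_nA > 0)
    stats::rnorm(n, spec$baseline_nA, spec$noise_sd_nA)
  else rep(spec$baseline_nA, n)

  # Poisson arrivals, uniform in time, sorted, then thinned so that each
  # event keeps >= gap baseline samples from its neighbours and the ends.
  n_arr <- stats::rpois(1, spec$event_rate_per_s * spec$duration_s)
  ledger <- empty_ledger()
  if (n_arr > 0) {
    starts <- sort(sample.int(n, n_arr, replace = TRUE)) - 1L  # 0-based
    if (is.null(spec$dwell_ms)) {
      dwell_s <- stats::rexp(n_arr, rate = 1000 / spec$dwell_tau_ms)
    } else {
      dwell_s <- rep_len(spec$dwell_ms, n_arr) / 1000
    }
    widths <- pmax(2L, as.integer(round(dwell_s * fs)))
    comp <- sample.int(nrow(spec$blockage_components), n_arr, replace = TRUE,
                       prob = spec$blockage_components[, "weight"])
    peak_pct <- stats::rnorm(n_arr,
                             spec$blockage_components[comp, "mean_pct"],
                             spec$blockage_components[comp, "sd_pct"])
    peak_pct <- pmin(pmax(peak_pct, 0.1), 99.9)
    shapes <- sample(shape_labels, n_arr, replace = TRUE,
                     prob = spec$shape_mix)

    keep <- logical(n_arr)
    last_end <- 0L
    for (i in seq_len(n_arr)) {
      if (starts[i] >= last_end + gap &&
          starts[i] + widths[i] + gap <= n) {
        keep[i] <- TRUE
        last_end <- starts[i] + widths[i]
      }
    }
    if (any(keep)) {
      starts <- starts[keep]; widths <- widths[keep]
      peak_pct <- peak_pct[keep]; shapes <- shapes[keep]
      depth <- peak_pct / 100 * abs(spec$baseline_nA)
      sgn <- sign(spec$baseline_nA)
      mean_pct <- numeric(length(starts))
      for (i in seq_along(starts)) {
        prof <- make_shape(shapes[i], widths[i], depth[i])
        idx <- (starts[i] + 1L):(starts[i] + widths[i])
        x[idx] <- x[idx] - sgn * prof
        mean_pct[i] <- 100 * mean(prof) / abs(spec$baseline_nA)
      }
      ledger <- data.frame(start_index = starts,
                           end_index = starts + widths,
                           true_dwell_ms = widths / fs * 1000,
                           true_blockage_pct = mean_pct,
                           true_peak_pct = peak_pct,
                           shape = shapes)
    }
  }

  if (!is.null(spec$filter_cutoff_hz))
    x <- spec$baseline_nA +
      lowpass_filter(x - spec$baseline_nA, spec$filter_cutoff_hz, fs)

  list(trace = current_trace(x, fs,
                             applied_voltage_mV = NA_real_,
                             label = spec$label, source = "synthetic"),
       ledger = ledger)
}

empty_ledger <- function() {
  data.frame(start_index = integer(0), end_index = integer(0),
             true_dwell_ms = numeric(0), true_blockage_pct = numeric(0),
             true_peak_pct = numeric(0), shape = character(0))
}

#' Low-pass filter a signal
#'
#' A causal 4-pole Butterworth low-pass, the package's model of the recording
#' chain's analogue filter (typically 10 kHz on a 50 kHz acquisition). Applied
#' to the deviation from the operating point by [simulate_trace()] so no
#' start-up step transient is introduced.
#'
#' @param x Numeric signal.
#' @param cutoff_hz Cutoff frequency (Hz), below Nyquist.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @return Filtered signal, same length.
#' @export
lowpass_filter <- function(x, cutoff_hz, sampling_rate_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_rate_hz / 2)
    stop("cutoff must lie in (0, sampling_rate/2)")
  bf <- signal::butter(4, 2 * cutoff_hz / sampling_rate_hz, type = "low")
  as.numeric(signal::filter(bf, x))
}
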