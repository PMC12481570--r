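# Shared fixtures: small seeded simulations and event matching.

# Noise-free, unfiltered spec with square-ish parameters convenient for
# exact-recovery checks.
noisefree_spec <- function(seed, duration_s = 2, rate = 20, tau_ms = 2,
                           mean_pct = 15, shapes = c(square = 1, deep_first = 0,
                                                     ramp_then_deep = 0)) {
  simulation_spec(duration_s = duration_s, seed = seed, noise_sd_nA = 0,
                  filter_cutoff_hz = NULL, event_rate_per_s = rate,
                  dwell_tau_ms = tau_ms,
                  blockage_components = list(c(1, mean_pct, 0)),
                  shape_mix = shapes, refractory_gap_samples = 100)
}

# Conditions for the stochastic detection suite: lvl1 = 6 x noise SD and
# true depths at least twice the lvl1 deviation.
noisy_spec <- function(seed, duration_s = 2) {
  simulation_spec(duration_s = duration_s, seed = seed, noise_sd_nA = 0.05,
                  filter_cutoff_hz = NULL, event_rate_per_s = 10,
                  dwell_tau_ms = 4.7,
                  blockage_components = list(c(1, 10, 0.5)),
                  shape_mix = c(square = 0.5, deep_first = 0.25,
                                ramp_then_deep = 0.25),
                  refractory_gap_samples = 250)
}

noisy_config <- function() {
  detection_config(lvl0 = -13.6, lvl1 = 0.3, tolerance = 0.15,
                   min_event_samples = 2)
}

# Match detected events to ledger events by interval overlap.
match_events <- function(ledger, events) {
  if (nrow(ledger) == 0L)
    return(list(recall = NA_real_, n_matched = 0L, n_fp = nrow(events)))
  matched <- logical(nrow(ledger))
  fp <- 0L
  for (i in seq_len(nrow(events))) {
    ov <- which(events$start_index[i] < ledger$end_index &
                events$end_index[i] > ledger$start_index)
    if (length(ov)) matched[ov] <- TRUE else fp <- fp + 1L
  }
  list(recall = mean(matched), n_matched = sum(matched), n_fp = fp)
}

# A small valid event table for I/O tests.
toy_event_table <- function() {
  df <- data.frame(start_index = c(100L, 300L, 900L),
                   end_index = c(150L, 420L, 960L),
                   dwell_ms = c(1, 2.4, 1.2),
                   blockage_pct = c(12.5, 18.2, 9.9),
                   peak_blockage_pct = c(13, 19, 10.5),
                   baseline_nA = -13.6, depth_nA = c(1.7, 2.47, 1.35),
                   t_extremum_frac = c(0.5, 0.1, 0.9),
                   padded_start = c(80L, 280L, 880L),
                   padded_end = c(170L, 440L, 980L),
                   shape_class = c("symmetric", "deep_first", "ramp_then_deep"),
                   dwell_class = c("medium", "long", "long"))
  event_table(df, config = detection_config(lvl0 = -13.6, lvl1 = 0.5,
                                            tolerance = 0.2),
              trace_label = "toy")
}
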