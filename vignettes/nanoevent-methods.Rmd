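---
title: "Models and methods behind nanoevent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanoevent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoevent)
```

# The measurement this package analyses

A solid-state nanopore is a nanometre-scale hole in a thin (here ~12 nm)
SiN membrane separating two electrolyte reservoirs. Under an applied bias
a steady ionic current flows through the open pore (the *baseline*, `lvl0`,
typically recorded at 50 kHz and hardware-filtered at 10 kHz). When a
molecule — in the motivating assay, a rolling circle amplification (RCA)
concatemer: a single DNA strand of hundreds to thousands of tandem repeats
of a 76-nt circular template — threads the pore, it transiently displaces
ions and the current steps toward zero. Each such *translocation event*
carries two primary observables:

* **dwell time** `t_d` (ms) — how long the current stays off baseline, and
* **percentage current blockage** — the relative current reduction,
  `100 * (|lvl0| - |I_event|) / |lvl0|`.

Ensembles of events are then characterised by the distribution of these
observables: blockage depths typically cluster into one or two Gaussian
populations reflecting molecular conformations, while dwell times are well
described by an exponential law whose mean grows with product length.

# Event extraction

## Algorithm

Detection (`detect_events()`) uses four user-facing parameters — `lvl0`,
`lvl1`, `tolerance`, `padding` — with the following semantics:

1. Compute the deviation toward zero, `dev_i = sign(lvl0) * (lvl0 - x_i)`;
   blockades make `dev_i` positive regardless of bias polarity.
2. An event **opens** at the first sample with `dev_i` *strictly greater*
   than the `lvl1` deviation. A deviation exactly at threshold does not
   trigger; this tie rule makes the threshold a true open bound and is
   asserted by a dedicated test.
3. Its boundaries are **extended outward** to the nearest samples on each
   side lying within `tolerance` of `lvl0`: the event starts one sample
   after the last in-tolerance sample before the crossing and ends
   (half-open) at the first in-tolerance sample after re-entry. The dwell
   time therefore spans the *tolerance extent*, not the `lvl1` extent.
   This choice deliberately captures the shallow entry/exit tails that
   asymmetric events exhibit; with a threshold-extent definition a sloping
   recovery would be truncated at `lvl1` and its dwell underestimated.
   The two extents coincide for square events, so the choice is visible
   only for strongly asymmetric morphologies.
4. Events separated by at most `merge_gap_samples` are merged; events
   narrower than `min_event_samples` are dropped; events whose extension
   reaches a trace edge cannot be measured and are excluded (their count
   is reported separately).
5. `padding` widens only the exported excerpt bounds; it never affects
   dwell or blockage.

All indices are 0-based and half-open, times are seconds internally, and
dwell times are reported in ms. Detection is invariant to a global sign
flip of trace and `lvl0` together (tested), and merging is exhaustive: no
two returned events are within the merge gap.

## Feature definitions

Both a mean-based and a peak-based blockage are computed per event:
`blockage_pct` uses the event-mean current (robust, low variance:
its sampling error is about `100 * 3 * sigma_noise / (sqrt(n) * |lvl0|)`
percent), `peak_blockage_pct` the sample of smallest current magnitude
(closer to scatter-plot conventions, but biased upward by noise extremes).
Population fitting consumes the mean-based value by default and can be
switched (`use_peak = TRUE`). The extremum position `t_extremum_frac` uses
the midpoint of the deepest contiguous plateau, so a noise-free
flat-bottomed event sits at 0.5 (symmetric) rather than at its first
sample.

## Baseline

`lvl0` is either user-supplied or estimated (`estimate_baseline()`) as the
median after discarding the `exclude_fraction` (default 10%) of samples
farthest from the global median, with noise SD `1.4826 * MAD`. The
estimator tolerates event occupancies well below the exclusion fraction;
the default suits occupancies up to ~10%. Baseline drift is out of scope:
the model is a static level per analysed segment, and drifting recordings
should be segmented by the user before detection.

# The synthetic trace model

`simulate_trace()` generates the validation ground truth. Its defaults are
the acquisition conditions of the motivating experiment, not free knobs:

| parameter | default | why |
|---|---|---|
| `sampling_rate_hz` | 50000 | standard patch-clamp acquisition rate |
| `filter_cutoff_hz` | 10000 | hardware low-pass used during recording |
| `baseline_nA` | −13.6 | a 45.4 nS pore under −300 mV bias |
| `noise_sd_nA` | 0.05 | typical RMS noise of a low-noise SiN pore at 10 kHz |
| `blockage_components` | 13.2% / 18.4%, SD 1.0 | the two-population structure of a circularised-probe sample; SD chosen as a realistic histogram width (only the centres are anchored) |
| `dwell_tau_ms` | 4.7 | dwell scale of an early (30 min) RCA product |
| `event_rate_per_s` | 10 | event frequency is not quantified in the source data; 10/s is a realistic mid-range capture rate |
| `refractory_gap_samples` | 250 | 5 ms guard so injected events stay resolvable |

Events arrive as a homogeneous Poisson process thinned to enforce the
refractory gap (real arrivals are irregular but no arrival model is
established; Poisson is the maximum-entropy choice). Dwells are
exponential, depths Gaussian-mixture draws (clamped to (0.1, 99.9)%), and
each event takes one of three morphologies: `square` (constant depth),
`deep_first` (full depth at entry decaying linearly to a 25% residual at
exit) and `ramp_then_deep` (its mirror image). The 25% residual is a fixed
documented constant; no quantitative shape model exists to calibrate it.
The ledger records the *realised* injected width and the *mean* deflection
percentage — exactly the quantities detection estimates — so oracle
comparisons are exact, not approximate.

The recording-chain filter is modelled as a causal 4-pole Butterworth
low-pass applied to the deviation from baseline (avoiding a start-up step
transient). Two tested smoke properties pin its behaviour: a one-sample
spike is attenuated, and the mid-plateau of a 1 ms square event stays
within 1% of its unfiltered depth.

A guard rejects specifications whose expected occupancy
(`rate x mean dwell`) exceeds half the recording, where merged events
would make ground truth meaningless.

## What the simulator does *not* emulate

Real recordings add baseline drift and wander, 1/f and capacitive noise,
pore clogging, intra-event substates, and correlated event clusters. A
passing validation therefore demonstrates correctness of the *algorithms*
under the stated signal model, not performance on any particular
instrument's artefacts.

# Population fitting

Blockage depths are fitted by a 1-D Gaussian mixture
(`fit_blockage_populations()`), candidates of 1 and 2 components, by EM.
Initialisation is k-means++-style (first centre uniform, second weighted
by squared distance), 20 restarts, best log-likelihood kept; the EM
log-likelihood is non-decreasing by construction and tested. Component
count is selected by BIC — the published two-population call for ligation
products was made by inspection, and an automatic, documented criterion is
required for reproducibility. The count is capped at 2 because no nanopore
condition in the motivating assay shows more. Degenerate inputs (all
values equal) return a single component with a floored SD and a warning.
The component SDs are population widths; the `±` values printed by
`summarize_condition()` are fit standard errors of the means
(`sd / sqrt(weight * n)`), mirroring condition-table conventions.

Dwell times are fitted by exponential maximum likelihood: `tau` equals the
sample mean exactly (an identity asserted in the tests) with
`SE = tau / sqrt(n)`. MLE on raw dwells avoids the bin-choice sensitivity
of histogram curve fitting; a histogram mode
(`fit_dwell_exponential(..., method = "histogram")`) exists for comparison
with legacy workflows and is only required to agree loosely.

Numerical choices: EM stops when the relative log-likelihood gain falls
below 1e-10 or at 500 iterations; component SDs are floored at 1e-6 of the
data range to prevent variance collapse onto single points; components are
reported in increasing mean order; the fit is bit-reproducible for a fixed
seed (tested).

# Event classification

Dwell classes use edges at 0.3 and 1.0 ms: `short < 0.3`,
`0.3 <= medium <= 1.0`, `long > 1.0`. Published captions use strict
inequalities on both outer classes, leaving the boundary values
unassigned; this package assigns both boundaries to `medium` (closed
interval) in every code path, and tests pin that rule. Under an
exponential dwell law the expected class proportions follow the survival
function (`expected_dwell_proportions()`), e.g. a mean of
`1/ln 5 ≈ 0.62 ms` puts exactly 20% of events above 1 ms — the basis of a
distributional acceptance check at n = 5000.

Shape classes threshold the extremum position: `t_extremum_frac < 0.35` is
`deep_first`, `> 0.65` is `ramp_then_deep`, else `symmetric`. The
described morphologies are qualitative; 0.35/0.65 were chosen once so that
the simulator's three noise-free morphologies classify to their labels
with margin (a linear decay places the extremum at 0, a square plateau at
~0.5), and both cuts are exposed as arguments. **Limitation:** the
extremum of a noisy *flat* event is a single noise-selected sample, nearly
uniform over the event, so square events under noise scatter across all
three shape classes (visible in the README example); the asymmetry calls
are meaningful for strongly sloped events or after smoothing, and the
per-class proportions should be read accordingly.

# Pore characterisation

Conductance comes from the least-squares I–V slope (`fit_iv()`, nA/mV
converted to nS). The rectification ratio is defined here as
`(|G+| - |G-|) / ((|G+| + |G-|) / 2)` from separate branch slopes — the
term is used in the field without a standard formula; this symmetric
normalisation is exactly zero for antisymmetric sweeps and bounded in
(−2, 2). Diameter conversion uses the cylindrical-pore model with access
resistance,

$$G = \sigma \left[ \frac{4L}{\pi d^2} + \frac{1}{d} \right]^{-1},$$

which excludes surface-charge effects — adequate at 3.6 M LiCl, where
surface conductance is negligible against bulk. The inversion is the
closed-form positive root `d = (G\pi + \sqrt{G^2\pi^2 + 16\sigma\pi G L}) / (2\sigma\pi)`;
a 1000-point property sweep verifies round-trip agreement to better than
1e-9 relative over d ∈ [1, 100] nm, L ∈ [5, 50] nm, σ ∈ [1, 20] S/m. All
unit conversions live in one constants table. First-order error
propagation (`propagate_diameter_error()`) is offered for measured
uncertainties on G, L and σ; it is a package convenience, not a claim
about any published uncertainty budget.

# RCA kinetics

Deterministic arithmetic: product length is `rate x duration` over the
Phi29 rate range (50–100 nt/s default); tandem repeats are
`length / template` with three rounding conventions — `nearest_100`
(matches headline "approximately N repeats" figures), `floor` (complete
repeats, e.g. 2000 nt / 76 nt → 26), and `none`. Dilution chains multiply
`aliquot / final` ratios with the numerator and denominator accumulated
separately before one final division, so integer-ratio chains are exact;
the product is order-invariant. The ~0.4 nM worked example tracks the
probe input through a 1-in-10 ligation step and a 25-fold dilution; note
this follows the probe concentration, not a ligation yield — the
calculator implements the dilution arithmetic only. Enzyme molarities are
deliberately not computed: they require vendor specific-activity data
outside this package's scope.

# Reproducibility and problem sizes

Every stochastic stage takes an explicit integer seed; `run_pipeline()`
writes artifacts plus a manifest (config snapshot, MD5 checksums, package
version) and reruns are byte-identical — asserted down to file checksums
for a 60 s, 50 kHz (3-million-sample) four-stage run. The validation
suites use problem sizes at which the statistical bounds are sharp but the
suite stays quick: 10 × 2 s traces (10⁶ samples, ~200 events) for detector
recall and false positives, 20 replicates of 500 + 500 draws for mixture
recovery, n = 2000 for the exponential fit, and n = 5000 for class
proportions. These sizes are properties of the tests, not of the methods;
all scale linearly.

# Known limitations

* Static baseline only; no adaptive tracking or changepoint segmentation.
* No intra-event substate analysis — events are summarised, not segmented.
* Mean-based blockage is attenuated a few percent relative to injected
  peak depths when the hardware-filter emulation is enabled, because the
  tolerance-extended boundaries include filter rise/fall samples; the
  peak-based statistic is less affected but noise-biased upward.
* Shape classification degrades for flat events under noise (above).
* The cylindrical conductance model ignores surface charge; outside
  high-salt conditions the derived diameters are lower bounds.
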