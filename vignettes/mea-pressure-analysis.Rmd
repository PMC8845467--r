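---
title: "Analyzing retinal MEA spike trains under pressure stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing retinal MEA spike trains under pressure stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meapress)
```

## The analysis problem

Acute glaucoma models ask whether short, strong elevations of intraocular
pressure change the electrical behaviour of retinal ganglion cells (RGCs).
In the ex vivo preparation this package targets, a mouse retina lies on a
59-electrode planar MEA (an 8 x 8 grid with the four corners unpopulated and
one electrode wired as reference, 200 um pitch) inside a pressure chamber.
The experiment runs through four epochs: a 30 min lead time for the tissue
to settle, a 30 min pre-pressure baseline, 2 h at the test pressure
(10/30/60/90 mmHg), and 2 h of recovery. Within each epoch, 60 s recordings
capture spontaneous firing or responses to stimulation: biphasic current
pulses (+/- 80 uA, 500 us per phase, five pulses at 10 s intervals) or
full-field light pulses (1 s, five per recording, 10 s intervals).

The analysis chain is: band-pass filter the 25 kHz voltage traces (2nd-order
Butterworth, 200-2000 Hz), detect spikes at a -20 uV threshold, sort them
into single units by PCA over their waveforms, then compute per-unit
statistics per epoch - spontaneous firing rate, response rates to electrical
and light stimulation, ON/ON-OFF/OFF classification, and the percentage of
spikes fired in bursts (MaxInterval algorithm). Group summaries normalize
each statistic to the pre-pressure baseline, flag outliers with ROUT at
Q = 0.1%, and compare phases with one-way ANOVA plus Tukey's post hoc test.

Because no recorded data are distributed with the study, every stage is
driven and validated by a synthetic experiment generator with complete
ground truth.

## The synthetic generator

`sim_config()` + `simulate_population()` + `simulate_spike_trains()` create
a population of model RGCs and their spike trains over a configurable
schedule (`build_experiment()`).

What it emulates:

* **Population structure.** Categories ON / ON-OFF / OFF / unclassifiable in
  proportions 66/8/8/18% of all cells - i.e. 80.25/9.88/9.88% among the
  categorized cells, the distribution reported for light-responsive RGCs.
  Counts follow largest-remainder rounding, so they are exact up to
  rounding; labels are shuffled across cells.
* **Tonic firing.** Each cell fires at a rate drawn from 3-12 Hz, the
  typical spontaneous range in this preparation. Interspike intervals follow
  a gamma renewal process with shape 2 (`tonic_shape`; shape 1 recovers a
  Poisson process). The gamma model reflects the relative refractoriness of
  maintained retinal discharge; it matters here because a Poisson process at
  these rates produces 0.6-7% of its spikes in *chance* clusters that
  satisfy the MaxInterval criteria, which would contaminate burst
  ground-truth by several percentage points. A 2 ms absolute refractory
  interval is enforced by thinning.
* **Bursts.** A compound process: on top of tonic spikes, burst events
  arrive as a Poisson process, each contributing `3 + Geometric(0.5)` spikes
  with intra-burst intervals drawn uniformly from 2-8 ms *conditional on the
  burst spanning at least 10.2 ms*. The conditioning guarantees every
  generated burst satisfies the detector's retention rules (>= 3 spikes,
  >= 10 ms duration); without it about half of all three-spike bursts would
  be undetectable by construction and no calibration could hold. The burst
  event rate is solved from the target fraction `f` of spikes in bursts:
  `rate = f/(1-f) * tonic_rate / E[burst size]`. Each burst suppresses
  tonic firing over its span and for 50 ms afterwards
  (`post_burst_suppression`) - the afterhyperpolarization that terminates
  real bursts - with the tonic rate compensated so the realized rate stays
  at specification. Without the suppression, interval-based detection
  absorbs tonic spikes adjacent to a burst and the measured burst fraction
  drifts a few percentage points above the generative target.
* **Condition calibration.** `condition_presets()` stores, per experimental
  condition, the observed baseline percentage of spikes in bursts and its
  multiplicative change during and after pressure. Under 90 mmHg the
  pre-phase target is 9.90% rising by a factor 2.081 during pressure (to
  20.6%) and staying elevated afterwards; under 90 mmHg + taurine the
  fraction falls instead. These are the study conditions the simulator
  reproduces.
* **Light responses.** A rectangular rate gain (default 5x) for 0.4 s after
  light onset (ON, ON-OFF) and/or offset (OFF, ON-OFF). 0.4 s keeps the
  response inside the 0.5 s analysis window; the generator does not model
  response kinetics (latency, transience, adaptation).
* **Raw traces.** `render_raw()` adds each cell's biphasic template
  (negative-first, 2:1 lobe ratio, amplitudes uniform in -150 to -40 uV,
  widths 1.2-1.8 ms) at its spike times on its home channel over Gaussian
  noise. There is no cross-channel spillover, keeping sorting a per-channel
  problem, which matches the 200 um pitch of the hardware.

What it does **not** emulate - and hence what passing tests do not show
about real data: electrode drift and amplitude variability over hours,
overlapping spikes from synchronously active neighbours, stimulation
artifacts, oscillatory local field potentials, correlated (non-white)
noise, and any biophysics of pressure transduction. The generator is a
statistical stand-in calibrated to the reported group-level quantities, not
a retina model.

```{r}
design <- build_experiment(condition = "90 mmHg", profile = "desk")
cfg <- sim_config(n_cells = 40, condition = "90 mmHg", seed = 42)
cells <- simulate_population(cfg)
trains <- simulate_spike_trains(cells, design, cfg)
c(pre = gt_burst_fraction(trains, "pre"),
  pressure = gt_burst_fraction(trains, "pressure"))
```

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `hp_cutoff`, `lp_cutoff` | 200, 2000 | Hz | recording-software band-pass |
| `filter_order` | 2 | - | Butterworth sections, applied zero-phase |
| `threshold_uV` | -20 | uV | detection threshold of the bench pipeline |
| `dead_time_ms` | 1 | ms | suppresses double counts within a trough |
| `n_components` | 2 | - | PCA features per channel |
| `max_units_per_channel` | 4 | - | mixture model selection bound |
| `max_interval_start/end` | 0.01, 0.03 | s | MaxInterval open/extend bounds |
| `min_interval_between` | 0.02 | s | burst merge bound |
| `min_duration`, `min_spikes` | 0.01 s, 3 | - | burst retention rules |
| `electrical_pre/post` | 3, 0.5 | s | response-rate windows |
| `light_pre/post` | 1, 0.5 | s | onset/offset windows |
| `classify_threshold` | 1.5 | - | ON/OFF response-rate rule |
| `rout_Q` | 0.001 | - | ROUT false discovery rate (Q = 0.1%) |
| `min_active_channels` | 10 | - | retina rejection rule |

## Numerical and design choices

**Zero-phase filtering.** The bench software filters causally; this package
uses forward-backward (`signal::filtfilt`) application of the same
Butterworth sections so that detected peak times carry no group delay. All
downstream statistics use windows of 0.5 s or longer, so the distinction
only matters for timestamp fidelity, which zero-phase filtering maximizes.

**Dead time resolves to the deepest trough.** Detection emits local minima
at or below threshold; minima closer than 1 ms are collapsed to the deepest
one. This keeps the event on the spike's true trough and makes event sets
nest as the threshold hardens (the set at -30 uV is a subset of the set at
-20 uV).

**Response rate is a ratio of rates, not of counts.** The pre-stimulus
window (3 s electrical, 1 s light) is much longer than the 0.5 s
post-stimulus window. With raw counts, a non-responsive cell would score
about 0.17 (electrical) and the 1.5 classification threshold would demand a
nine-fold elevation - inconsistent with 80% of cells classifying as ON. With
duration-normalized rates a non-responsive cell scores about 1.0 and 1.5
means a 50% elevation. Both conventions are implemented
(`normalize = "rate"` or `"count"`); rate is the default. Counts are pooled
across a recording's five pulses before the ratio is taken, which avoids
undefined per-pulse ratios in sparse trains.

**Burst boundary conventions.** The interval rules state "maximal" and
"minimal" without strictness. This package opens and extends bursts at
intervals *equal to* the bounds (inclusive), merges only at gaps *strictly
below* the merge bound, and retains bursts *at* the duration/count minima.
These conventions are frozen by tests, including an exact-equivalence check
against an independent brute-force oracle on 10^4 random trains plus
adversarial trains with intervals exactly at 0.01/0.02/0.03 s. Note that
with the default parameters the merge step can never fire (candidates are
always separated by more than 0.03 s > 0.02 s); it becomes active only if
`min_interval_between` is raised above `max_interval_end`.

**Mixture-model sorting.** The original analysis used manual cluster
cutting in PCA space in a commercial sorter. The closest published analog
is a Gaussian mixture in PCA space with BIC model selection (1-4
components, ties broken toward fewer); clusters under `min_spikes_per_unit`
are merged into their nearest neighbour. Initialization is the
deterministic model-based hierarchical agglomeration of `mclust`, so
sorting is reproducible. One further rule mirrors what a human cutter does:
mixture components whose centroids sit fewer than 4 pooled SDs apart
(projected on the line joining them, `overlap_merge_sd`) are merged, since
BIC occasionally models within-unit structure - typically peak-alignment
jitter of +/- one sample - as a second component, while genuinely distinct
units on these data are separated by tens of SDs.

**ROUT as a location model.** ROUT is specified by name and Q only. The
published construction (robust fit, RSDR scale, FDR-controlled flagging) is
specialized to a constant model since the plotted quantities are univariate
per group and phase: the location is the maximum-likelihood estimate under
a Lorentzian error model initialized at the median; the scale is the
68.27th percentile of absolute residuals times n/(n-1); each point gets a
two-tailed t p-value on n-1 df; sorted p-values are compared to Q*i/n from
the most extreme point, stopping at the first failure. Identical values
(zero scale) yield no outliers. Group means are reported both ways: the
all-data mean +/- SD (running-text convention) and the ROUT-cleaned mean
(plotted-mean convention); flagging never alters the all-data mean.

**Half-open time intervals.** All epochs and windows are `[start, end)`; a
phase boundary belongs to the later phase. Reported percentages round to
the nearest integer with halves away from zero, the convention that
reproduces the published worked examples.

**Pre-sorted input mode.** `run_pipeline()` accepts either raw traces
(render, filter, detect, sort) or per-unit spike tables
(`input_mode = "spike_trains"`). The parameter-recovery study runs in the
latter mode: at 100 cells on 16 electrodes several cells share a channel,
which per-channel waveform sorting cannot and should not untangle - sorting
fidelity is validated separately on two-template channels.

## Problem sizes

The desk-scale profile used in tests and in `scripts/acceptance.R` runs 16
channels with 10 s spontaneous recordings (six per phase) and 20 s light
recordings (two per phase; five pulses need more than 10 s at a usable
interstimulus interval), 100 cells, all seeded. The full-scale profile (59
channels, 60 s recordings, 30/30/120/120 min phases) is available through
`build_experiment(profile = "full")`. Oracle-equivalence checks use 10^4
sixty-second Poisson trains at 1/10/50 Hz; ROUT behaviour uses 1000
replicates of n = 100.

## A worked run

```{r}
cfg <- experiment_config(condition = "90 mmHg", seed = 7, n_cells = 60,
                         n_channels = 16)
res <- suppressMessages(run_pipeline(cfg))
report <- make_report(res)
report$pct_bursts$table[, c("phase", "n", "mean_all", "sd_all",
                            "norm_percent", "pct_change_vs_prev")]
report$pct_bursts$anova_line
report$categories
```

The burst percentage roughly doubles from pre to pressure and stays
elevated post - the simulated 90 mmHg condition - while the ANOVA line and
category distribution mirror the reporting format of the original figures.

## Known limitations

* ROUT's step-down FDR scan and the Lorentzian location fit are one
  faithful reading of a procedure published in less detail; other software
  may flag marginal points differently. Only gross outliers are guaranteed.
* The electrical response-rate convention (rate-normalized, pooled over
  pulses) is a documented judgment call; the count convention is available
  behind a switch.
* Stimulation-artifact handling is limited to the detector dead time; the
  generator does not render artifacts.
* Spike-amplitude and local-field-potential analyses are out of scope.
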