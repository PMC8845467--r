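# meapress

Spike-train analysis of retinal multielectrode-array (MEA) recordings under
hydrostatic pressure stress.

## What this package is for

Ex vivo acute glaucoma models place a retina on a planar MEA inside a
pressure chamber and record retinal ganglion cell (RGC) activity before
(pre), during (pressure) and after (post) a pressure step of 10–90 mmHg.
`meapress` re-implements the full analysis chain of such experiments as
tested, reusable R functions:

- **Signal**: zero-phase band-pass filtering (2nd-order Butterworth,
  200–2000 Hz) and spike detection at a −20 µV threshold on 25 kHz traces,
  with noise-channel flagging.
- **Sorting**: per-electrode PCA waveform features and Gaussian-mixture
  clustering (BIC model selection) into single units.
- **Metrics**: per-unit, per-phase spontaneous firing rate; response rates
  to electrical (±80 µA biphasic pulses) and full-field light stimulation;
  ON/ON-OFF/OFF classification; MaxInterval burst detection and the
  percentage of spikes fired in bursts; normalization to the pre phase and
  integer percent-change reporting.
- **Stats**: ROUT robust outlier removal at Q = 0.1 %, dual mean reporting
  (all-data mean ± SD vs. ROUT-cleaned mean), one-way ANOVA with Tukey's
  post hoc test formatted as figure captions print it.
- **Synthetic data**: a seeded generator of ground-truth MEA experiments
  (59-electrode 8×8-minus-corners geometry, 3–12 Hz tonic rates, calibrated
  bursting per pressure condition, ON/ON-OFF/OFF light responses, raw-trace
  rendering), so every stage is verifiable without recorded data.
- **Pipeline**: `run_pipeline()` orchestrates simulate → detect → sort →
  metrics → stats with retina-level quality control (reject if fewer than
  10 of 59 channels are active after lead time), a run manifest and CSV /
  JSON / YAML outputs.

## The statistics at the core

For a unit with spike times `t_i`, the **response rate** to a stimulus at
time `s` is the duration-normalized coefficient

    RR = (N_post / T_post) / (N_pre / T_pre)

with `T_pre` = 3 s (electrical) or 1 s (light), `T_post` = 0.5 s, counts
pooled over the recording's five pulses. A cell is **ON** if
`RR_onset ≥ 1.5` and `RR_offset < 1.5`, **ON-OFF** if both ≥ 1.5, **OFF** if
only the offset responds, else uncategorized.

**Bursts** follow the MaxInterval algorithm: open a burst at an interspike
interval ≤ 0.01 s, extend while intervals ≤ 0.03 s, merge candidates closer
than 0.02 s, keep bursts with ≥ 3 spikes spanning ≥ 0.01 s. The headline
statistic is the percentage of a unit's spikes inside bursts, per phase.

**ROUT** (robust regression and outlier removal) is specialized to a
location model: a Lorentzian maximum-likelihood location, the robust scale
RSDR (68.27th percentile of |residuals| × n/(n−1)), per-point t statistics,
and a false-discovery flagging step at rate Q.

## Worked example

```r
library(meapress)

cfg <- experiment_config(condition = "90 mmHg", seed = 7,
                         n_cells = 60, n_channels = 16)
res <- run_pipeline(cfg)
report <- make_report(res)
report$pct_bursts$table[, c("phase", "n", "mean_all", "sd_all",
                            "norm_percent", "pct_change_vs_prev")]
#>     phase  n mean_all sd_all norm_percent pct_change_vs_prev
#>       pre 60    10.94  2.874          100                 NA
#>  pressure 60    21.41  3.209          196                 96
#>      post 60    21.87  3.974          200                  2
report$pct_bursts$anova_line
#> F(2, 177) = 200.3, p < 0.0001
report$categories
#>  category  n   pct
#>        ON 40 81.63
#>    ON_OFF  4  8.16
#>       OFF  5 10.20
```

Reading the output: under the simulated 90 mmHg condition the percentage of
spikes in bursts roughly doubles from the pre phase (10.9 %) to the
pressure phase (21.4 %, a +96 % change) and stays elevated in the recovery
phase — the bursting signature this class of experiment reports — while
about 82 % of the categorized units classify as ON cells. The
`norm_percent` column expresses each phase relative to the pre baseline
(pre ≡ 100), and `F(2, 177)` is the one-way ANOVA across phases over the 60
units.

The generator's calibration is directly inspectable:

```r
design <- build_experiment(condition = "90 mmHg", profile = "desk")
sim <- sim_config(n_cells = 40, condition = "90 mmHg", seed = 42)
trains <- simulate_spike_trains(simulate_population(sim), design, sim)
c(pre = gt_burst_fraction(trains, "pre"),
  pressure = gt_burst_fraction(trains, "pressure"))
#>      pre pressure
#>  9.54012 20.19619
```

i.e. ground truth near the 9.9 % baseline and its 2.08-fold elevation under
pressure.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mea-press.R", package="meapress"))')" \
    run --condition "90 mmHg" --seed 1 --out out/
```

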