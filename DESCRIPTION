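Package: meapress
Title: Spike-Train Analysis of Retinal MEA Recordings Under Hydrostatic Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the multielectrode-array (MEA)
    spike-train analysis used to study retinal ganglion cell (RGC) activity
    under hydrostatic pressure stress. Provides band-pass filtering and
    threshold spike detection on raw multichannel voltage traces, principal
    component spike sorting into single units, per-unit firing and
    peristimulus response statistics, ON/ON-OFF/OFF classification from
    full-field light responses, MaxInterval burst detection, normalization of
    phase statistics to the pre-pressure baseline, robust outlier removal
    (ROUT), and one-way ANOVA with Tukey's post hoc test. A synthetic
    retinal-MEA experiment generator with full ground truth makes every
    pipeline stage verifiable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    mclust,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
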