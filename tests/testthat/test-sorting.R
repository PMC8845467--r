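# two interleaved trains, 50 ms apart, so templates never overlap
two_template_channel <- function(noise_sd, amps = c(-60, -120),
                                 widths = c(1.3, 1.8), n_each = 500,
                                 seed = 19) {
  tA <- seq(0.05, by = 0.1, length.out = n_each)
  tB <- tA + 0.05
  render_channel(list(tA, tB), amps = amps, widths = widths,
                 noise_sd = noise_sd, duration = max(tB) + 0.05, seed = seed)
}

truth_labels <- function(times, tA, tB) {
  ifelse(vapply(times, function(t) min(abs(t - tA)) < min(abs(t - tB)),
                TRUE), 1L, 2L)
}

test_that("PCA features separate distinct templates and are deterministic", {
  r <- two_template_channel(noise_sd = 0)
  ev <- detect_spikes(r$raw)
  f <- extract_features(ev$cutouts[["E21"]], 2)
  lab <- truth_labels(ev$events$time, r$trains$time[r$trains$cell_id == "cell001"],
                      r$trains$time[r$trains$cell_id == "cell002"])
  cent <- rbind(colMeans(f[lab == 1, ]), colMeans(f[lab == 2, ]))
  between <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  within <- max(stats::sd(f[lab == 1, 1]), stats::sd(f[lab == 2, 1]), 1e-9)
  expect_gt(between, 10 * within)

  # identical cutouts: zero-variance case yields identical (zero) features
  same <- matrix(rep(c(0, -60, -30, 10, 0), each = 20), nrow = 20)
  fs <- extract_features(same, 2)
  expect_true(all(fs == 0))

  # permutation invariance: features follow the events
  perm <- sample(nrow(ev$cutouts[["E21"]]))
  fp <- extract_features(ev$cutouts[["E21"]][perm, ], 2)
  expect_equal(fp, f[perm, ], tolerance = 1e-8)

  expect_error(extract_features(same[1, , drop = FALSE]), "at least 2")
})

test_that("two-template channels are recovered as two accurate units", {
  r <- two_template_channel(noise_sd = 6) # SNR 10 for the smaller template
  ev <- detect_spikes(bandpass_filter(r$raw))
  f <- extract_features(ev$cutouts[["E21"]], 2)
  cls <- cluster_units(f, sorting_params(), seed = 1)
  expect_equal(length(unique(cls)), 2)

  tA <- r$trains$time[r$trains$cell_id == "cell001"]
  tB <- r$trains$time[r$trains$cell_id == "cell002"]
  matched <- abs(ev$events$time - round(ev$events$time / 0.05) * 0.05) < 0.001
  lab <- truth_labels(ev$events$time[matched], tA, tB)
  expect_gte(assignment_accuracy(cls[matched], lab), 0.95)

  # determinism
  cls2 <- cluster_units(f, sorting_params(), seed = 1)
  expect_identical(cls, cls2)
})

test_that("a single template yields a single unit", {
  r <- render_channel(list(seq(0.05, by = 0.1, length.out = 300)), amps = -80,
                      noise_sd = 6, duration = 30.1, seed = 23)
  ev <- detect_spikes(bandpass_filter(r$raw))
  f <- extract_features(ev$cutouts[["E21"]], 2)
  expect_equal(length(unique(cluster_units(f, sorting_params(), seed = 1))), 1)
})

test_that("unit recovery accuracy does not degrade as SNR grows", {
  accs <- vapply(c(4, 8, 12), function(snr) {
    r <- two_template_channel(noise_sd = 60 / snr, n_each = 250, seed = 29)
    # sort on cutouts extracted at the true spike samples: isolates the
    # feature/clustering stages from detection errors
    fs <- r$config$sample_rate
    samp <- round(sort(r$trains$time) * fs) + 1
    v <- r$raw$voltage[1, ]
    cut <- t(vapply(samp, function(s) v[(s - 25):(s + 50)], numeric(76)))
    f <- extract_features(cut, 2)
    lab <- truth_labels(sort(r$trains$time),
                        r$trains$time[r$trains$cell_id == "cell001"],
                        r$trains$time[r$trains$cell_id == "cell002"])
    assignment_accuracy(cluster_units(f, sorting_params(), seed = 1), lab)
  }, 0)
  expect_true(all(diff(accs) >= -1e-9))
  expect_gte(accs[1], 0.9)
})

test_that("spike trains conserve events and split cleanly by phase", {
  r <- two_template_channel(noise_sd = 0, n_each = 100)
  ev <- detect_spikes(r$raw)
  asn <- sort_events(ev, sorting_params(min_spikes_per_unit = 20), seed = 1)
  units <- build_spike_trains(asn, ev)
  expect_equal(nrow(units), nrow(ev$events)) # conservation
  expect_s3_class(units, "unit_trains")

  sched <- phase_schedule(c(0, 1), c(1, 5), c(5, 9), c(9, 15),
                          data.frame(phase = rep(c("pre", "pressure", "post"),
                                                 each = 1),
                                     kind = "spontaneous",
                                     start = c(1, 5, 9), end = c(5, 9, 13)))
  for (uid in unique(units$unit_id)) {
    t <- units$time[units$unit_id == uid]
    parts <- lapply(c("pre", "pressure", "post"), function(ph) {
      w <- phase_windows(sched, ph)
      t[in_windows(t, w)]
    })
    joined <- sort(unlist(parts))
    expect_equal(joined, t[in_windows(t, sched$windows)]) # partition
  }

  # a unit silent in a phase gives an empty sub-train and 0 Hz
  empty_rate <- phase_firing_rate(numeric(0), sched, "pre")
  expect_equal(empty_rate, 0)

  # channels with < 2 events are skipped with a log entry
  one_ev <- ev
  one_ev$cutouts[["E31"]] <- ev$cutouts[["E21"]][1, , drop = FALSE]
  expect_message(sort_events(one_ev, sorting_params(), seed = 1), "skipped")
})
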