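test_that("MaxInterval handles minimal, degenerate and boundary trains", {
  # minimal qualifying burst: 3 spikes spanning exactly min_duration
  b <- detect_bursts(c(0, 0.005, 0.010))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 3L)
  expect_equal(b$end - b$start, 0.010)

  expect_equal(nrow(detect_bursts(c(0, 0.005))), 0)     # too few spikes
  expect_equal(nrow(detect_bursts(numeric(0))), 0)
  expect_equal(nrow(detect_bursts(5)), 0)

  # an interval exactly at max_interval_start opens; exactly at
  # max_interval_end extends
  b2 <- detect_bursts(c(0, 0.01, 0.04))
  expect_equal(b2$n_spikes, 3L)
  # spikes preceding the opening interval in a run of extendable intervals
  # do not join the burst: the burst starts at the first spike of the first
  # opening interval, not at the start of the run
  b3 <- detect_bursts(c(0, 0.025, 0.030, 0.055, 0.065))
  expect_equal(nrow(b3), 1)
  expect_equal(b3$start, 0.025)
  expect_equal(b3$n_spikes, 4L)

  # merging: gap below min_interval_between joins candidates (requires
  # min_interval_between > max_interval_end to be reachable)
  p <- burst_params(max_interval_end = 0.03, min_interval_between = 0.05)
  tt <- c(0, 0.005, 0.012, 0.052, 0.057, 0.064) # gap 0.04 between candidates
  bm <- detect_bursts(tt, p)
  expect_equal(nrow(bm), 1)
  expect_equal(bm$n_spikes, 6L)
  # gap exactly at min_interval_between does not merge (strict rule); the
  # boundary is taken from the data itself to make the equality exact
  p2 <- burst_params(max_interval_end = 0.03,
                     min_interval_between = tt[4] - tt[3])
  expect_equal(nrow(detect_bursts(tt, p2)), 2)

  expect_error(detect_bursts(c(1, 0.5)), "sorted")
})

test_that("detect_bursts matches the brute-force oracle on random trains", {
  set.seed(77)
  for (lam in c(1, 10, 50)) {
    for (r in 1:100) {
      n <- stats::rpois(1, lam * 60) + 1
      tt <- cumsum(stats::rexp(n, lam))
      expect_true(burst_tables_equal(detect_bursts(tt), oracle_bursts(tt)))
    }
  }
  # adversarial trains with intervals exactly at every parameter boundary
  for (r in 1:200) {
    isis <- sample(c(0.01, 0.02, 0.03, 0.005, 0.031, 0.009, 0.05),
                   40, replace = TRUE)
    tt <- cumsum(isis)
    expect_true(burst_tables_equal(detect_bursts(tt), oracle_bursts(tt)))
  }
})

test_that("burst detection is invariant under time translation", {
  set.seed(3)
  tt <- cumsum(stats::rexp(600, 20))
  b0 <- detect_bursts(tt)
  b1 <- detect_bursts(tt + 5000)
  expect_equal(b1$start - 5000, b0$start, tolerance = 1e-9)
  expect_equal(b1$n_spikes, b0$n_spikes)
})

test_that("spikes-in-bursts percentage is bounded, monotone and windowed", {
  sched <- phase_schedule(c(0, 1), c(1, 61), c(61, 121), c(121, 181),
                          data.frame(phase = c("pre", "pressure", "post"),
                                     kind = "spontaneous",
                                     start = c(1, 61, 121),
                                     end = c(61, 121, 181)))
  # all spikes in one burst -> 100%
  tt <- 10 + c(0, 0.005, 0.012, 0.02)
  expect_equal(pct_spikes_in_bursts(tt, detect_bursts(tt), sched, "pre"), 100)
  # no bursts -> 0%
  t2 <- seq(2, 60, by = 1)
  expect_equal(pct_spikes_in_bursts(t2, detect_bursts(t2), sched, "pre"), 0)
  # no spikes in phase -> undefined
  expect_true(is.na(pct_spikes_in_bursts(t2, detect_bursts(t2), sched,
                                         "pressure")))
  # adding a fully-bursting cluster can only raise the percentage
  t3 <- sort(c(t2, 30 + c(0, 0.004, 0.009, 0.015)))
  expect_gte(pct_spikes_in_bursts(t3, detect_bursts(t3), sched, "pre"),
             pct_spikes_in_bursts(t2, detect_bursts(t2), sched, "pre"))
})

test_that("phase firing rates follow the window definition", {
  sched <- phase_schedule(c(0, 1), c(1, 61), c(61, 62), c(62, 63),
                          data.frame(phase = c("pre", "pressure", "post"),
                                     kind = "spontaneous",
                                     start = c(1, 61, 62), end = c(61, 62, 63)))
  expect_equal(phase_firing_rate(seq(1, 61 - 0.1, length.out = 600), sched,
                                 "pre"), 10)
  expect_equal(phase_firing_rate(numeric(0), sched, "pre"), 0)
  expect_error(phase_firing_rate(1, phase_schedule(
    c(0, 1), c(1, 2), c(2, 3), c(3, 4),
    data.frame(phase = "pre", kind = "light", start = 1, end = 2)), "pre"),
    "no spontaneous")

  # Poisson rate recovery: 16 x 60 s windows at 8 Hz within 3 SE
  w <- data.frame(phase = "pre", kind = "spontaneous",
                  start = 1 + (0:15) * 61, end = 61 + (0:15) * 61)
  sched2 <- phase_schedule(c(0, 1), c(1, 1000), c(1000, 1001), c(1001, 1002),
                           w)
  set.seed(10)
  tt <- cumsum(stats::rexp(10000, 8))
  est <- phase_firing_rate(tt[tt < 976], sched2, "pre")
  expect_lt(abs(est - 8), 3 * sqrt(8 / 960))
})

test_that("response rates are duration-normalized pooled ratios", {
  proto <- stimulus_protocol("electrical", onsets = c(10, 20, 30, 40, 50),
                             stim_electrode = "E44")
  # 6 spikes pooled in the five 3 s pre windows, 3 in the 0.5 s post windows
  pre_spikes <- c(7.5, 8.1, 18.2, 28.5, 37.9, 48.0)
  post_spikes <- c(10.1, 30.2, 50.3)
  tt <- sort(c(pre_spikes, post_spikes))
  expect_equal(electrical_response_rate(tt, proto), (3 / 2.5) / (6 / 15))
  expect_equal(electrical_response_rate(tt, proto, normalize = "count"), 0.5)
  # no post spikes -> 0; no pre spikes -> undefined
  expect_equal(electrical_response_rate(sort(pre_spikes), proto), 0)
  expect_true(is.na(electrical_response_rate(post_spikes, proto)))

  # a homogeneous Poisson train is non-responsive: mean RR ~ 1
  set.seed(6)
  rrs <- replicate(200, {
    tt <- cumsum(stats::rexp(500, 8))
    electrical_response_rate(tt[tt < 55], proto)
  })
  expect_lt(abs(mean(rrs, na.rm = TRUE) - 1), 0.1)
})

test_that("light responses classify ON / ON-OFF / OFF cells reliably", {
  # the quoted classification rule, including the inclusive boundary
  expect_equal(classify_rgc(2.0, 1.0), "ON")
  expect_equal(classify_rgc(2.0, 2.0), "ON_OFF")
  expect_equal(classify_rgc(1.0, 2.0), "OFF")
  expect_equal(classify_rgc(1.0, 1.0), "UNCATEGORIZED")
  expect_equal(classify_rgc(1.5, 1.5), "ON_OFF")
  expect_equal(classify_rgc(NA, 2.0), "UNCATEGORIZED")
  # exhaustive and mutually exclusive over a grid
  grid <- expand.grid(on = seq(0, 3, by = 0.25), off = seq(0, 3, by = 0.25))
  cls <- classify_rgc(grid$on, grid$off)
  expect_true(all(cls %in% c("ON", "ON_OFF", "OFF", "UNCATEGORIZED")))

  proto <- stimulus_protocol("light", onsets = seq(5, by = 10,
                                                   length.out = 15),
                             pulse_duration = 1)
  set.seed(8)
  sim_cell <- function(gain_on, gain_off) {
    lam <- stats::runif(1, 3, 12)
    tt <- cumsum(stats::rexp(3000, lam))
    tt <- tt[tt < 150]
    extra <- unlist(lapply(proto$onsets, function(o) {
      c(if (gain_on > 1) sort(stats::runif(stats::rpois(1, (gain_on - 1) *
                                                          lam * 0.4), o,
                                           o + 0.4)),
        if (gain_off > 1) sort(stats::runif(stats::rpois(1, (gain_off - 1) *
                                                           lam * 0.4), o + 1,
                                            o + 1.4)))
    }))
    sort(c(tt, extra))
  }
  on_ok <- replicate(200, {
    rr <- light_response_rates(sim_cell(5, 1), proto)
    rr[["rr_on"]] >= 1.5 && rr[["rr_off"]] < 1.5
  })
  expect_gte(mean(on_ok), 0.95)
  flat_rr <- replicate(100, light_response_rates(sim_cell(1, 1), proto))
  expect_lt(abs(mean(flat_rr["rr_on", ]) - 1), 0.15)
  expect_lt(abs(mean(flat_rr["rr_off", ]) - 1), 0.15)
  # silent in pre windows: undefined, uncategorized
  rr0 <- light_response_rates(c(5.1, 15.1), proto)
  expect_true(all(is.na(rr0)) ||
                classify_rgc(rr0[["rr_on"]], rr0[["rr_off"]]) ==
                  "UNCATEGORIZED")
})

test_that("normalization and percent change reproduce the reporting rules", {
  nz <- normalize_to_pre(c(pre = 7.13, pressure = 4.08, post = 3.75))
  expect_equal(nz$ratio[1], 1)
  expect_equal(nz$percent[nz$phase == "pressure"], 57)
  nz2 <- normalize_to_pre(c(pre = 6.86, pressure = 7.21))
  expect_equal(nz2$percent[2], 105)
  expect_equal(normalize_to_pre(c(pre = 4, pressure = 4))$ratio[2], 1)
  expect_error(normalize_to_pre(c(pressure = 1)), "pre")
  expect_error(normalize_to_pre(c(pre = 0, pressure = 1)), "positive")

  expect_equal(percent_change(11.36, 8.76), -23)
  expect_equal(percent_change(9.90, 20.60), 108)
  expect_equal(percent_change(3, 3), 0)
  # halves round away from zero
  expect_equal(percent_change(200, 201), 1)
  expect_equal(percent_change(200, 199), -1)
  expect_error(percent_change(0, 1), "before")
})
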