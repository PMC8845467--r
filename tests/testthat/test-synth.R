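test_that("population category counts follow the mixture up to rounding", {
  cfg <- sim_config(n_cells = 100, seed = 5)
  cells <- simulate_population(cfg)
  ct <- table(cells$category)
  expect_equal(unname(ct["ON"]), 66)
  expect_equal(unname(ct["ON_OFF"]), 8)
  expect_equal(unname(ct["OFF"]), 8)
  expect_equal(unname(ct["UNCATEGORIZED"]), 18)

  one <- simulate_population(sim_config(n_cells = 1,
                                        category_proportions = c(ON = 1),
                                        seed = 2))
  expect_equal(one$category, "ON")

  expect_error(sim_config(n_cells = 0), "n_cells")
  expect_error(sim_config(category_proportions = c(ON = 0.5)), "sum to 1")
})

test_that("the simulation is fully determined by the seed", {
  d <- tiny_design()
  cfg <- sim_config(n_cells = 10, seed = 33)
  a_cells <- simulate_population(cfg)
  b_cells <- simulate_population(cfg)
  expect_identical(a_cells, b_cells)
  a <- simulate_spike_trains(a_cells, d, cfg)
  b <- simulate_spike_trains(b_cells, d, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("a silent cell produces an empty train", {
  d <- tiny_design(light = c(pre = 0, pressure = 0, post = 0))
  cfg <- sim_config(n_cells = 1, tonic_rate_range = c(0, 0),
                    burst_fraction_pre = 0, seed = 4)
  cells <- simulate_population(cfg)
  tr <- simulate_spike_trains(cells, d, cfg)
  expect_equal(nrow(tr), 0)
})

test_that("ground-truth burst fractions match the configured targets", {
  # one long spontaneous window per phase, no stimulation, modulation from
  # the 90 mmHg preset (9.9% pre, x2.081 pressure)
  d <- build_experiment(condition = "90 mmHg", profile = "desk",
                        spont_recordings = c(pre = 1, pressure = 1, post = 1),
                        light_recordings = c(pre = 0, pressure = 0, post = 0),
                        spont_s = 200)
  cfg <- sim_config(n_cells = 60, condition = "90 mmHg", seed = 17)
  cells <- simulate_population(cfg)
  tr <- simulate_spike_trains(cells, d, cfg)
  per_cell <- function(ph) {
    x <- tr[tr$phase == ph & tr$kind == "spontaneous", ]
    mean(vapply(split(x$in_burst, x$cell_id), function(b) 100 * mean(b), 0))
  }
  expect_lt(abs(per_cell("pre") - 9.90), 2)
  expect_lt(abs(per_cell("pressure") - 20.60), 2)
  expect_lt(abs(per_cell("post") - 21.21), 2)

  # flat modulation: a 10% target is recovered within 2 percentage points
  d2 <- build_experiment(profile = "desk",
                         spont_recordings = c(pre = 1, pressure = 0, post = 0),
                         light_recordings = c(pre = 0, pressure = 0, post = 0),
                         spont_s = 600)
  cfg2 <- sim_config(n_cells = 50, burst_fraction_pre = 0.10,
                     burst_modulation = c(pressure = 1, post = 1), seed = 8)
  tr2 <- simulate_spike_trains(simulate_population(cfg2), d2, cfg2)
  expect_lt(abs(gt_burst_fraction(tr2, "pre") - 10), 2)
})

test_that("rates are stationary across phases when modulation is flat", {
  d <- tiny_design(light = c(pre = 0, pressure = 0, post = 0))
  cfg <- sim_config(n_cells = 50, burst_fraction_pre = 0.10,
                    burst_modulation = c(pressure = 1, post = 1), seed = 12)
  cells <- simulate_population(cfg)
  tr <- simulate_spike_trains(cells, d, cfg)
  dur <- sum(with(phase_windows(d$schedule, "pre", "spontaneous"), end - start))
  rates <- sapply(c("pre", "pressure", "post"), function(ph) {
    x <- tr[tr$phase == ph & tr$kind == "spontaneous", ]
    vapply(split(x$time, factor(x$cell_id, levels = cells$cell_id)),
           length, 0L) / dur
  })
  se <- sqrt(apply(rates, 2, stats::var) / nrow(rates))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(mean(rates[, i]) - mean(rates[, j])),
              3 * sqrt(se[i]^2 + se[j]^2))
  }
})

test_that("light responses elevate the rate in the correct windows", {
  d <- tiny_design(light = c(pre = 2, pressure = 2, post = 2))
  cfg <- sim_config(n_cells = 40, burst_fraction_pre = 0, seed = 21)
  cells <- simulate_population(cfg)
  tr <- simulate_spike_trains(cells, d, cfg)
  on_t <- d$light_protocol$onsets
  off_t <- on_t + d$light_protocol$pulse_duration
  resp_rate <- function(cell, starts) {
    t <- tr$time[tr$cell_id == cell$cell_id]
    sum(vapply(starts, function(s) sum(t >= s & t < s + 0.4), 0L)) /
      (0.4 * length(starts))
  }
  on_cells <- cells[cells$category == "ON", ]
  ratio <- vapply(seq_len(nrow(on_cells)), function(i) {
    resp_rate(on_cells[i, ], on_t) / on_cells$tonic_rate[i]
  }, 0)
  expect_gt(mean(ratio), 3) # gain 5 inside the response window
  off_ratio <- vapply(seq_len(nrow(on_cells)), function(i) {
    resp_rate(on_cells[i, ], off_t) / on_cells$tonic_rate[i]
  }, 0)
  expect_lt(mean(off_ratio), 1.5) # ON cells do not respond to offset
})

test_that("rendering places templates exactly and superposes linearly", {
  # single noiseless spike: trace minimum is the template peak at the spike
  r1 <- render_channel(list(0.1), amps = -60, noise_sd = 0, duration = 0.2)
  v <- r1$raw$voltage[1, ]
  expect_equal(min(v), -60)
  expect_equal(which.min(v), round(0.1 * 25000) + 1)

  # pure-noise trace: sample SD within 5% of the configured SD
  cfg <- sim_config(n_cells = 1, noise_sd_uV = 7, seed = 9)
  empty <- data.frame(cell_id = character(0), channel = character(0),
                      time = numeric(0))
  nr <- render_raw(empty, simulate_population(cfg)[0, ], channels = "E21",
                   config = cfg, duration = 40)
  expect_equal(ncol(nr$voltage), 1e6)
  expect_lt(abs(stats::sd(nr$voltage[1, ]) - 7) / 7, 0.05)

  # superposition: both cells = cell A with noise + cell B without
  both <- render_channel(list(c(0.1, 0.5), c(0.3)), amps = c(-60, -120),
                         noise_sd = 5, duration = 1, seed = 3)
  a <- render_channel(list(c(0.1, 0.5)), amps = -60, noise_sd = 5,
                      duration = 1, seed = 3)
  b <- render_channel(list(c(0.3)), amps = -120, noise_sd = 0,
                      duration = 1, seed = 3)
  expect_equal(both$raw$voltage, a$raw$voltage + b$raw$voltage)

  expect_error(render_channel(list(5), amps = -60, duration = 1),
               "beyond trace duration")
})
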