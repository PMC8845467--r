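#' Simulation configuration for a synthetic retinal MEA experiment
#'
#' Parameters of the ground-truth generator. The generator emulates the
#' statistical structure the downstream analysis assumes: a population of
#' retinal ganglion cells with spontaneous (tonic) rates of about 3-12 Hz, a
#' mixture of ON / ON-OFF / OFF / unclassifiable light responses (66/8/8/18%
#' of all cells, i.e. 80.25/9.88/9.88% among the categorized), and bursting
#' produced by a compound process: tonic Poisson spikes plus Poisson-arriving
#' burst events of at least three spikes with short intra-burst intervals.
#' The per-phase fraction of spikes fired in bursts is calibrated per
#' condition (e.g. 9.9% in the pre phase rising by a factor 2.08 under
#' 90 mmHg); see [condition_presets()].
#'
#' @param n_cells Number of simulated cells (>= 1).
#' @param category_proportions Named proportions for `ON`, `ON_OFF`, `OFF`,
#'   `UNCATEGORIZED`; must sum to 1.
#' @param condition Condition label; when it matches a row of
#'   [condition_presets()] the burst calibration defaults to that row.
#' @param burst_fraction_pre Target fraction (0-1) of spikes in bursts during
#'   lead/pre phases.
#' @param burst_modulation Named multipliers (`pressure`, `post`) applied to
#'   `burst_fraction_pre` in the later phases.
#' @param tonic_rate_range Range (Hz) from which cell tonic rates are drawn.
#' @param tonic_shape Gamma shape of the tonic renewal process (1 = Poisson;
#'   the default 2 reproduces the relative refractoriness of maintained
#'   retinal discharge, keeping chance interspike intervals in the burst
#'   range rare).
#' @param gain_on,gain_off Rate multipliers during the light response window
#'   after stimulus onset (ON and ON-OFF cells) and offset (OFF and ON-OFF
#'   cells).
#' @param response_duration Duration (s) of the rectangular light response.
#' @param burst_size_geom_prob Geometric parameter: burst size is
#'   `3 + rgeom(prob)`.
#' @param intra_burst_isi Range (s) of intra-burst interspike intervals.
#' @param post_burst_suppression Duration (s) of suppressed tonic firing
#'   after each burst (afterhyperpolarization); tonic spikes are also
#'   excluded from the burst span itself, and the tonic rate is compensated
#'   so the realized rate stays at specification.
#' @param refractory_s Minimum interspike interval enforced (by thinning)
#'   outside bursts.
#' @param amp_range_uV Range of waveform template peak amplitudes (negative,
#'   uV).
#' @param width_range_ms Range of waveform template widths (ms).
#' @param noise_sd_uV Additive Gaussian noise SD for raw-trace rendering.
#' @param sample_rate Sampling rate (Hz) for rendered traces.
#' @param seed Integer seed; the seed fully determines the simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 100,
                       category_proportions = c(ON = 0.66, ON_OFF = 0.08,
                                                OFF = 0.08, UNCATEGORIZED = 0.18),
                       condition = "90 mmHg",
                       burst_fraction_pre = NULL,
                       burst_modulation = NULL,
                       tonic_rate_range = c(3, 12),
                       tonic_shape = 2,
                       gain_on = 5, gain_off = 5,
                       response_duration = 0.4,
                       burst_size_geom_prob = 0.5,
                       intra_burst_isi = c(0.002, 0.008),
                       post_burst_suppression = 0.05,
                       refractory_s = 0.002,
                       amp_range_uV = c(-150, -40),
                       width_range_ms = c(1.2, 1.8),
                       noise_sd_uV = 10,
                       sample_rate = 25000,
                       seed = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  req <- c("ON", "ON_OFF", "OFF", "UNCATEGORIZED")
  p <- setNames(rep(0, 4), req)
  p[names(category_proportions)] <- category_proportions
  if (abs(sum(p) - 1) > 1e-8) {
    stop("category_proportions must sum to 1", call. = FALSE)
  }
  preset <- condition_presets()
  row <- preset[preset$condition == condition, ]
  if (is.null(burst_fraction_pre)) {
    burst_fraction_pre <- if (nrow(row)) row$pre_pct / 100 else 0.099
  }
  if (is.null(burst_modulation)) {
    burst_modulation <- if (nrow(row)) {
      c(pressure = row$pressure_mod, post = row$post_mod)
    } else c(pressure = 1, post = 1)
  }
  stopifnot(sample_rate > 0, burst_fraction_pre >= 0, burst_fraction_pre < 1,
            intra_burst_isi[2] <= 0.01)
  structure(list(n_cells = as.integer(n_cells), category_proportions = p,
                 condition = condition,
                 burst_fraction_pre = burst_fraction_pre,
                 burst_modulation = burst_modulation,
                 tonic_rate_range = tonic_rate_range,
                 tonic_shape = tonic_shape,
                 gain_on = gain_on, gain_off = gain_off,
                 response_duration = response_duration,
                 burst_size_geom_prob = burst_size_geom_prob,
                 intra_burst_isi = intra_burst_isi,
                 post_burst_suppression = post_burst_suppression,
                 refractory_s = refractory_s,
                 amp_range_uV = amp_range_uV,
                 width_range_ms = width_range_ms,
                 noise_sd_uV = noise_sd_uV,
                 sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw a synthetic RGC population
#'
#' Category counts follow the configured proportions by largest-remainder
#' rounding (so a population of 100 cells under the default mixture contains
#' exactly 66 ON, 8 ON-OFF, 8 OFF and 18 unclassifiable cells), and category
#' labels are then shuffled across cells. Tonic rates, waveform amplitudes
#' and widths are drawn uniformly from the configured ranges; home channels
#' are drawn from `channels`.
#'
#' @param config A [sim_config()].
#' @param map A [mea_channel_map()].
#' @param channels Channels available as home channels; defaults to all
#'   recording channels of `map`.
#' @return Data frame of class `sim_cells`, one row per cell.
#' @export
simulate_population <- function(config, map = mea_channel_map(),
                                channels = recording_channels(map)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  p <- config$category_proportions
  base <- floor(n * p)
  rem <- n * p - base
  extra <- utils::head(order(rem, decreasing = TRUE), n - sum(base))
  counts <- base
  counts[extra] <- counts[extra] + 1
  categories <- sample(rep(names(counts), counts))
  cells <- data.frame(
    cell_id = sprintf("cell%03d", seq_len(n)),
    category = categories,
    tonic_rate = stats::runif(n, config$tonic_rate_range[1],
                              config$tonic_rate_range[2]),
    gain_on = ifelse(categories %in% c("ON", "ON_OFF"), config$gain_on, 1),
    gain_off = ifelse(categories %in% c("OFF", "ON_OFF"), config$gain_off, 1),
    response_duration = config$response_duration,
    home_channel = sample(channels, n, replace = TRUE),
    amp_uV = stats::runif(n, config$amp_range_uV[1], config$amp_range_uV[2]),
    width_ms = stats::runif(n, config$width_range_ms[1],
                            config$width_range_ms[2]),
    stringsAsFactors = FALSE
  )
  structure(cells, class = c("sim_cells", "data.frame"), config = config)
}

# one burst: spike-time offsets from the burst event time; rejection ensures
# every generated burst satisfies the detector's retention rules
# (duration >= 0.01 s with a small safety margin)
burst_offsets <- function(size, isi_range) {
  repeat {
    isis <- stats::runif(size - 1, isi_range[1], isi_range[2])
    if (sum(isis) >= 0.0102) return(c(0, cumsum(isis)))
  }
}

# piecewise-constant-rate gamma renewal process on [0, dur): unit-mean
# gamma(shape, shape) intervals in operational time Lambda(t) = int rate dt,
# mapped back by inverting the piecewise-linear Lambda. shape = 1 gives an
# inhomogeneous Poisson process; shape > 1 gives the more regular interspike
# intervals of maintained retinal discharge.
piecewise_renewal <- function(dur, breaks, rates, shape = 2) {
  seg <- diff(breaks)
  total <- sum(seg * rates)
  if (total <= 0) return(numeric(0))
  n_guess <- ceiling(total + 4 * sqrt(total) + 10)
  s <- cumsum(stats::rgamma(n_guess, shape, rate = shape))
  while (s[length(s)] < total) {
    s <- c(s, s[length(s)] + cumsum(stats::rgamma(n_guess, shape, rate = shape)))
  }
  ops <- s[s < total]
  if (!length(ops)) return(numeric(0))
  cum <- c(0, cumsum(seg * rates))
  idx <- findInterval(ops, cum, rightmost.closed = TRUE)
  # an operational time can only fall inside a positive-rate segment
  idx <- pmin(idx, length(rates))
  while (any(rates[idx] <= 0)) idx[rates[idx] <= 0] <- idx[rates[idx] <= 0] + 1
  sort(breaks[idx] + (ops - cum[idx]) / rates[idx])
}

#' Simulate ground-truth spike trains for a population
#'
#' Generates spikes for every recording window of the schedule. Within a
#' window each cell fires tonic Poisson spikes at its tonic rate (thinned to
#' a 2 ms refractory interval) plus burst events whose rate is chosen so that
#' the expected fraction of spikes in bursts equals the phase target
#' (`burst_fraction_pre` times the phase modulation). During light windows
#' the tonic rate is multiplied by `gain_on` for `response_duration` after
#' each light onset (ON and ON-OFF cells) and by `gain_off` after each offset
#' (OFF and ON-OFF cells). Every spike is tagged with its generating process,
#' so the output doubles as ground truth.
#'
#' @param cells A [simulate_population()] result.
#' @param design An [build_experiment()] design (schedule plus protocols).
#' @param config The [sim_config()] used for the population.
#' @return Data frame of class `sim_spike_trains` with columns `cell_id`,
#'   `channel`, `time`, `phase`, `kind`, `in_burst`, sorted by cell then
#'   time. Attributes `config` and `design` carry the provenance.
#' @export
simulate_spike_trains <- function(cells, design, config) {
  stopifnot(inherits(cells, "sim_cells"), inherits(design, "experiment_design"))
  schedule <- design$schedule
  if (nrow(schedule$windows) == 0) stop("empty schedule", call. = FALSE)
  set.seed(config$seed + 1L)
  mod <- c(lead = 1, pre = 1,
           pressure = unname(config$burst_modulation["pressure"]),
           post = unname(config$burst_modulation["post"]))
  mean_burst_size <- 3 + (1 - config$burst_size_geom_prob) /
    config$burst_size_geom_prob
  onsets <- if (!is.null(design$light_protocol)) design$light_protocol$onsets else numeric(0)
  offsets <- onsets + (design$light_protocol$pulse_duration %||% 1)
  out <- vector("list", nrow(cells) * nrow(schedule$windows))
  k <- 0
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    for (wi in seq_len(nrow(schedule$windows))) {
      w <- schedule$windows[wi, ]
      dur <- w$end - w$start

      # rate profile relative to window start
      breaks <- c(0, dur); rates <- cell$tonic_rate
      if (w$kind == "light" && length(onsets)) {
        ev <- rbind(
          if (cell$gain_on > 1) cbind(onsets, cell$gain_on),
          if (cell$gain_off > 1) cbind(offsets, cell$gain_off)
        )
        if (!is.null(ev) && nrow(ev)) {
          ev <- ev[ev[, 1] >= w$start & ev[, 1] < w$end, , drop = FALSE]
          if (nrow(ev)) {
            starts <- pmax(0, ev[, 1] - w$start)
            stops <- pmin(dur, starts + cell$response_duration)
            breaks <- sort(unique(c(0, starts, stops, dur)))
            mids <- utils::head(breaks, -1) + diff(breaks) / 2
            rates <- rep(cell$tonic_rate, length(mids))
            for (j in seq_len(nrow(ev))) {
              inside <- mids >= starts[j] & mids < stops[j]
              rates[inside] <- cell$tonic_rate * ev[j, 2]
            }
          }
        }
      }

      # burst events are drawn first so tonic firing can honour the
      # post-burst suppression (afterhyperpolarization) around each burst
      btimes <- numeric(0)
      burst_spans <- NULL
      be_rate <- 0
      f <- min(0.9, config$burst_fraction_pre * mod[[w$phase]])
      if (f > 0 && cell$tonic_rate > 0) {
        be_rate <- (f / (1 - f)) * cell$tonic_rate / mean_burst_size
        margin <- 0.06
        n_ev <- stats::rpois(1, be_rate * max(0, dur - margin))
        if (n_ev > 0) {
          ev_t <- sort(stats::runif(n_ev, 0, dur - margin))
          spans <- matrix(0, n_ev, 2)
          for (e in seq_len(n_ev)) {
            size <- 3 + stats::rgeom(1, config$burst_size_geom_prob)
            off <- burst_offsets(size, config$intra_burst_isi)
            btimes <- c(btimes, ev_t[e] + off)
            spans[e, ] <- c(ev_t[e], ev_t[e] + max(off))
          }
          burst_spans <- spans
        }
      }

      # tonic rate is inflated to compensate for the suppressed intervals so
      # the realized rate stays at specification
      shadow <- min(0.5, be_rate * (0.015 + config$post_burst_suppression))
      tonic <- piecewise_renewal(dur, breaks, rates / (1 - shadow),
                                 config$tonic_shape)
      if (!is.null(burst_spans) && length(tonic)) {
        drop <- rep(FALSE, length(tonic))
        for (e in seq_len(nrow(burst_spans))) {
          drop <- drop | (tonic >= burst_spans[e, 1] &
                            tonic <= burst_spans[e, 2] +
                            config$post_burst_suppression)
        }
        tonic <- tonic[!drop]
      }
      if (config$refractory_s > 0 && length(tonic) > 1) {
        # greedy thinning against the last kept spike
        keep <- rep(TRUE, length(tonic))
        last <- tonic[1]
        for (i in seq_along(tonic)[-1]) {
          keep[i] <- (tonic[i] - last) >= config$refractory_s
          if (keep[i]) last <- tonic[i]
        }
        tonic <- tonic[keep]
      }

      n_t <- length(tonic); n_b <- length(btimes)
      if (n_t + n_b == 0) next
      t_all <- c(tonic, btimes) + w$start
      burst_tag <- c(rep(FALSE, n_t), rep(TRUE, n_b))
      o <- order(t_all)
      k <- k + 1
      out[[k]] <- data.frame(cell_id = cell$cell_id,
                             channel = cell$home_channel,
                             time = t_all[o], phase = w$phase, kind = w$kind,
                             in_burst = burst_tag[o],
                             stringsAsFactors = FALSE)
    }
  }
  trains <- if (k == 0) {
    data.frame(cell_id = character(0), channel = character(0),
               time = numeric(0), phase = character(0), kind = character(0),
               in_burst = logical(0))
  } else do.call(rbind, out[seq_len(k)])
  rownames(trains) <- NULL
  structure(trains, class = c("sim_spike_trains", "data.frame"),
            config = config, design = design)
}

#' Ground-truth fraction of spikes in bursts
#'
#' The calibration targets hold within windows of constant rate, so the
#' default restricts to spontaneous recording windows (during light responses
#' the tonic rate is transiently elevated, diluting the burst fraction there
#' exactly as it does in the analysis).
#'
#' @param trains A [simulate_spike_trains()] result.
#' @param phase Phase to evaluate, or `NULL` for the whole experiment.
#' @param cell_id Optional single cell filter.
#' @param kind Window kind(s) to evaluate over; `NULL` for all.
#' @return Percentage (0-100) of generated spikes tagged as burst spikes.
#' @export
gt_burst_fraction <- function(trains, phase = NULL, cell_id = NULL,
                              kind = "spontaneous") {
  x <- trains
  if (!is.null(phase)) x <- x[x$phase %in% phase, , drop = FALSE]
  if (!is.null(cell_id)) x <- x[x$cell_id %in% cell_id, , drop = FALSE]
  if (!is.null(kind)) x <- x[x$kind %in% kind, , drop = FALSE]
  if (nrow(x) == 0) return(NA_real_)
  100 * mean(x$in_burst)
}

#' Biphasic extracellular spike template
#'
#' Negative-first biphasic waveform with a 2:1 amplitude ratio between the
#' negative and positive lobes; the negative lobe occupies one third of the
#' total width. The negative peak falls exactly on a sample so that rendered
#' spike times are exact.
#'
#' @param amp_uV Negative peak amplitude (uV, < 0).
#' @param width_ms Total template width (ms).
#' @param sample_rate Sampling rate (Hz).
#' @return List with `wave` (numeric vector, uV) and `peak` (1-based index of
#'   the negative peak).
#' @export
spike_template <- function(amp_uV, width_ms = 1.5, sample_rate = 25000) {
  stopifnot(amp_uV < 0)
  n_total <- round(width_ms / 1000 * sample_rate)
  n1 <- max(4L, 2L * round(n_total / 6))     # even so the peak is on-sample
  n2 <- max(4L, n_total - n1)
  neg <- amp_uV * sin(pi * (0:n1) / n1)
  pos <- (-amp_uV / 2) * sin(pi * (1:n2) / (n2 + 1))
  list(wave = c(neg, pos), peak = n1 / 2 + 1)
}

#' Render spike trains into a raw multichannel voltage recording
#'
#' Adds each cell's biphasic template at its spike times on the cell's home
#' channel (no cross-channel spillover) on top of additive Gaussian noise.
#' The noise is drawn first from the seed alone, so traces rendered with the
#' same seed, channels and duration superpose linearly across cell subsets.
#'
#' @param trains Spike trains ([simulate_spike_trains()] or any data frame
#'   with `cell_id`, `channel`, `time`).
#' @param cells The [simulate_population()] table (waveform parameters).
#' @param channels Channels to render; defaults to the channels appearing in
#'   `trains`.
#' @param config A [sim_config()] (sample rate, noise SD, seed).
#' @param duration Trace duration (s); defaults to the schedule end (if
#'   `trains` carries a design) or the last spike plus 10 ms.
#' @param noise_sd_uV Noise SD override (uV).
#' @param seed Seed override for the noise.
#' @return A [raw_recording()].
#' @export
render_raw <- function(trains, cells, channels = NULL, config,
                       duration = NULL, noise_sd_uV = config$noise_sd_uV,
                       seed = config$seed + 2L) {
  fs <- config$sample_rate
  if (is.null(channels)) channels <- sort(unique(trains$channel))
  if (length(channels) == 0) stop("no channels to render", call. = FALSE)
  if (is.null(duration)) {
    design <- attr(trains, "design")
    duration <- if (!is.null(design)) {
      max(design$schedule$phases$end)
    } else if (nrow(trains)) max(trains$time) + 0.01 else 1
  }
  ns <- ceiling(duration * fs)
  if (nrow(trains) && any(trains$time < 0 | trains$time >= duration)) {
    stop("spike time beyond trace duration", call. = FALSE)
  }
  set.seed(seed)
  v <- matrix(if (noise_sd_uV > 0) stats::rnorm(length(channels) * ns, 0,
                                                noise_sd_uV) else 0,
              nrow = length(channels), ncol = ns)
  rownames(v) <- channels
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    idx <- which(trains$cell_id == cell$cell_id & trains$channel %in% channels)
    if (!length(idx)) next
    tpl <- spike_template(cell$amp_uV, cell$width_ms, fs)
    row <- match(cell$home_channel, channels)
    samp <- round(trains$time[idx] * fs) + 1L
    for (s in samp) {
      a <- s - tpl$peak + 1L
      b <- a + length(tpl$wave) - 1L
      ta <- max(1L, a); tb <- min(ns, b)
      if (ta > tb) next
      v[row, ta:tb] <- v[row, ta:tb] + tpl$wave[(ta - a + 1L):(tb - a + 1L)]
    }
  }
  raw_recording(v, sample_rate = fs, channels = channels)
}
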