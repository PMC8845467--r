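#' Peristimulus analysis windows and classification threshold
#'
#' Electrical responses compare spiking 3 s before each pulse with 0.5 s
#' after it; light responses compare 1 s before onset/offset with 0.5 s
#' after. A unit counts as responding when the response rate reaches 1.5.
#'
#' @param electrical_pre,electrical_post,light_pre,light_post Window lengths
#'   (s).
#' @param classify_threshold Response-rate threshold for ON/OFF
#'   classification.
#' @return A list of class `response_windows`.
#' @export
response_windows <- function(electrical_pre = 3, electrical_post = 0.5,
                             light_pre = 1, light_post = 0.5,
                             classify_threshold = 1.5) {
  stopifnot(electrical_pre > 0, electrical_post > 0, light_pre > 0,
            light_post > 0, classify_threshold > 0)
  structure(list(electrical_pre = electrical_pre,
                 electrical_post = electrical_post,
                 light_pre = light_pre, light_post = light_post,
                 classify_threshold = classify_threshold),
            class = "response_windows")
}

#' MaxInterval burst detection parameters
#'
#' @param max_interval_start Maximal interspike interval (s) that opens a
#'   burst.
#' @param max_interval_end Maximal interval (s) that extends a burst.
#' @param min_interval_between Minimal interval (s) between bursts; closer
#'   candidate bursts are merged.
#' @param min_duration Minimal burst duration (s), first to last spike.
#' @param min_spikes Minimal number of spikes per burst.
#' @return A list of class `burst_params`.
#' @export
burst_params <- function(max_interval_start = 0.01, max_interval_end = 0.03,
                         min_interval_between = 0.02, min_duration = 0.01,
                         min_spikes = 3) {
  stopifnot(max_interval_start > 0, max_interval_end > 0,
            min_interval_between > 0, min_duration > 0, min_spikes >= 2)
  structure(list(max_interval_start = max_interval_start,
                 max_interval_end = max_interval_end,
                 min_interval_between = min_interval_between,
                 min_duration = min_duration, min_spikes = min_spikes),
            class = "burst_params")
}

#' MaxInterval burst detection
#'
#' Implements the interval algorithm: a candidate burst opens at any
#' interspike interval at or below `max_interval_start`, extends while
#' subsequent intervals stay at or below `max_interval_end`, consecutive
#' candidates separated by less than `min_interval_between` are merged, and
#' candidates shorter than `min_duration` (first-to-last spike) or with fewer
#' than `min_spikes` spikes are discarded. Boundary conventions are inclusive
#' on qualifying: an interval exactly at `max_interval_start`/`max_interval_end`
#' opens/extends, a gap exactly at `min_interval_between` does not merge, and
#' a burst exactly at `min_duration`/`min_spikes` is retained. Output is
#' invariant under uniform time translation of the train.
#'
#' @param times Sorted numeric vector of spike times (s).
#' @param params [burst_params()].
#' @return Data frame of class `burst_set` with one row per burst: `start`,
#'   `end`, `n_spikes` plus the spike index range `start_idx`, `end_idx`.
#' @export
detect_bursts <- function(times, params = burst_params()) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = FALSE)) {
    stop("spike times must be sorted", call. = FALSE)
  }
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), start_idx = integer(0),
                      end_idx = integer(0))
  class(empty) <- c("burst_set", "data.frame")
  n <- length(times)
  if (n < 2) return(empty)
  isi <- diff(times)
  ext <- isi <= params$max_interval_end
  runs <- rle(ext)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1
  cand <- list()
  for (r in which(runs$values)) {
    idx <- run_start[r]:run_end[r]            # ISI indices in this run
    open <- idx[isi[idx] <= params$max_interval_start]
    if (!length(open)) next
    cand[[length(cand) + 1]] <- c(open[1], run_end[r] + 1)  # spike indices
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # merge candidates separated by less than min_interval_between
  merged <- list(cand[1, ])
  for (i in seq_len(nrow(cand))[-1]) {
    lastb <- merged[[length(merged)]]
    gap <- times[cand[i, 1]] - times[lastb[2]]
    if (gap < params$min_interval_between) {
      merged[[length(merged)]] <- c(lastb[1], cand[i, 2])
    } else {
      merged[[length(merged) + 1]] <- cand[i, ]
    }
  }
  m <- do.call(rbind, merged)
  n_spikes <- m[, 2] - m[, 1] + 1L
  duration <- times[m[, 2]] - times[m[, 1]]
  keep <- n_spikes >= params$min_spikes & duration >= params$min_duration
  out <- data.frame(start = times[m[keep, 1]], end = times[m[keep, 2]],
                    n_spikes = as.integer(n_spikes[keep]),
                    start_idx = as.integer(m[keep, 1]),
                    end_idx = as.integer(m[keep, 2]))
  rownames(out) <- NULL
  class(out) <- c("burst_set", "data.frame")
  out
}

#' Burst membership of each spike
#'
#' @param times The spike-time vector that `bursts` was computed from.
#' @param bursts A [detect_bursts()] result.
#' @return Logical vector: `TRUE` for spikes inside a burst.
#' @export
burst_membership <- function(times, bursts) {
  inb <- rep(FALSE, length(times))
  for (i in seq_len(nrow(bursts))) {
    inb[bursts$start_idx[i]:bursts$end_idx[i]] <- TRUE
  }
  inb
}

#' Spontaneous firing rate of a unit within a phase
#'
#' Rate = spikes inside the phase's spontaneous recording windows divided by
#' the summed window duration.
#'
#' @param times Spike times of the unit (s).
#' @param schedule A [phase_schedule()].
#' @param phase Phase name.
#' @param kind Window kind(s) to use.
#' @return Firing rate (Hz).
#' @export
phase_firing_rate <- function(times, schedule, phase, kind = "spontaneous") {
  w <- phase_windows(schedule, phase, kind)
  total <- sum(w$end - w$start)
  if (total <= 0) {
    stop("phase '", phase, "' has no ", paste(kind, collapse = "/"),
         " recording window", call. = FALSE)
  }
  sum(in_windows(times, w)) / total
}

pooled_rate_ratio <- function(times, pre_starts, pre_len, post_starts,
                              post_len, normalize = c("rate", "count")) {
  normalize <- match.arg(normalize)
  pre_n <- 0L; post_n <- 0L
  for (s in pre_starts) pre_n <- pre_n + sum(times >= s & times < s + pre_len)
  for (s in post_starts) post_n <- post_n + sum(times >= s & times < s + post_len)
  if (pre_n == 0) return(structure(NA_real_, flag = "no pre-window spikes"))
  if (normalize == "rate") {
    (post_n / (post_len * length(post_starts))) /
      (pre_n / (pre_len * length(pre_starts)))
  } else {
    post_n / pre_n
  }
}

#' Response rate to electrical stimulation
#'
#' The response rate is the coefficient of spiking after versus before the
#' stimulus: spikes are pooled over the pulses (summed counts and summed
#' window durations) and the ratio of the post-window rate (0.5 s after each
#' pulse) to the pre-window rate (3 s before each pulse) is returned. With
#' `normalize = "count"` the raw count coefficient is returned instead. A
#' unit with no pre-window spikes yields `NA` with a flag attribute and is
#' excluded from response analyses. It applies to units on the eight
#' channels surrounding the stimulation electrode (see
#' [adjacent_channels()]); enforcing that restriction is the caller's
#' responsibility.
#'
#' @param times Spike times of the unit (s).
#' @param protocol An electrical [stimulus_protocol()].
#' @param windows [response_windows()].
#' @param onsets Optional subset of pulse onsets (e.g. those of one phase);
#'   defaults to all protocol onsets.
#' @param normalize `"rate"` (duration-normalized, default) or `"count"`.
#' @return Unitless response rate, or `NA` if undefined.
#' @export
electrical_response_rate <- function(times, protocol,
                                     windows = response_windows(),
                                     onsets = NULL,
                                     normalize = c("rate", "count")) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            protocol$kind == "electrical")
  onsets <- onsets %||% protocol$onsets
  pooled_rate_ratio(times, onsets - windows$electrical_pre,
                    windows$electrical_pre, onsets,
                    windows$electrical_post, match.arg(normalize))
}

#' Response rates to light onset and offset
#'
#' For full-field light pulses, compares spiking 1 s before versus 0.5 s
#' after the pulse onset (`rr_on`) and the pulse offset (`rr_off`),
#' duration-normalized and pooled over pulses. Computed for units on all
#' recording channels.
#'
#' @param times Spike times of the unit (s).
#' @param protocol A light [stimulus_protocol()].
#' @param windows [response_windows()].
#' @param onsets Optional subset of pulse onsets; defaults to all.
#' @param normalize `"rate"` or `"count"`.
#' @return Named numeric vector `c(rr_on, rr_off)`; `NA` entries where the
#'   respective pre window contains no spikes.
#' @export
light_response_rates <- function(times, protocol,
                                 windows = response_windows(),
                                 onsets = NULL,
                                 normalize = c("rate", "count")) {
  stopifnot(inherits(protocol, "stimulus_protocol"), protocol$kind == "light")
  normalize <- match.arg(normalize)
  onsets <- onsets %||% protocol$onsets
  offsets <- onsets + protocol$pulse_duration
  rr_on <- pooled_rate_ratio(times, onsets - windows$light_pre,
                             windows$light_pre, onsets, windows$light_post,
                             normalize)
  rr_off <- pooled_rate_ratio(times, offsets - windows$light_pre,
                              windows$light_pre, offsets, windows$light_post,
                              normalize)
  c(rr_on = as.numeric(rr_on), rr_off = as.numeric(rr_off))
}

#' Classify a unit as ON, ON-OFF, OFF or uncategorized
#'
#' ON if the onset response rate is at or above the threshold and the offset
#' response below it; ON-OFF if both reach it; OFF if only the offset does;
#' uncategorized if neither does or if a response rate is undefined.
#'
#' @param rr_on,rr_off Response rates from [light_response_rates()]
#'   (vectorized).
#' @param threshold Classification threshold (default 1.5).
#' @return Character vector with values `"ON"`, `"ON_OFF"`, `"OFF"`,
#'   `"UNCATEGORIZED"`.
#' @export
classify_rgc <- function(rr_on, rr_off, threshold = 1.5) {
  out <- rep("UNCATEGORIZED", length(rr_on))
  ok <- !is.na(rr_on) & !is.na(rr_off)
  on <- ok & rr_on >= threshold
  off <- ok & rr_off >= threshold
  out[on & !off] <- "ON"
  out[on & off] <- "ON_OFF"
  out[!on & off] <- "OFF"
  out
}

#' Percentage of spikes fired in bursts within a phase
#'
#' Bursts are detected on the full train; the percentage is computed over the
#' spikes falling into the phase's recording windows.
#'
#' @param times Spike times of the unit (s).
#' @param bursts [detect_bursts()] result for `times`.
#' @param schedule A [phase_schedule()].
#' @param phase Phase name.
#' @param kind Window kind(s) to evaluate over.
#' @return Percentage in `[0, 100]`, or `NA` if the unit fired no spike in
#'   the phase windows.
#' @export
pct_spikes_in_bursts <- function(times, bursts, schedule, phase,
                                 kind = "spontaneous") {
  w <- phase_windows(schedule, phase, kind)
  in_ph <- in_windows(times, w)
  if (!any(in_ph)) return(NA_real_)
  inb <- burst_membership(times, bursts)
  100 * sum(inb & in_ph) / sum(in_ph)
}

# round half away from zero, the convention of all reported percentages
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Normalize per-phase group means to the pre phase
#'
#' The group mean of the pre phase is set to 1 and the other phases are
#' expressed relative to it, also reported as integer percent.
#'
#' @param means Named numeric vector of per-phase group means; must contain
#'   `"pre"` with a positive value.
#' @return Data frame with columns `phase`, `ratio`, `percent`.
#' @export
normalize_to_pre <- function(means) {
  if (!"pre" %in% names(means)) stop("means must contain 'pre'", call. = FALSE)
  if (!is.finite(means[["pre"]]) || means[["pre"]] <= 0) {
    stop("pre-phase mean must be positive", call. = FALSE)
  }
  ratio <- as.numeric(means) / means[["pre"]]
  data.frame(phase = names(means), ratio = ratio,
             percent = round_half_away(100 * ratio))
}

#' Signed integer percent change
#'
#' `100 * (after - before) / before`, rounded to the nearest integer with
#' halves away from zero.
#'
#' @param before,after Numeric values; `before` must be positive.
#' @return Integer percent change (vectorized).
#' @export
percent_change <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0)) {
    stop("percent_change requires before > 0", call. = FALSE)
  }
  round_half_away(100 * (after - before) / before)
}

#' Per-unit metrics across all phases
#'
#' For every unit: the spontaneous firing rate and the percentage of spikes
#' in bursts per phase, the electrical response rate per phase (only for
#' units on channels adjacent to the stimulation electrode, when an
#' electrical protocol and channel map are supplied), and the light response
#' rates pooled over the whole experiment with the resulting ON/ON-OFF/OFF
#' category.
#'
#' @param units A [unit_trains()] table.
#' @param schedule A [phase_schedule()].
#' @param light_protocol,electrical_protocol Optional [stimulus_protocol()]s.
#' @param map Optional [mea_channel_map()] (needed for the electrical
#'   adjacency rule).
#' @param windows [response_windows()].
#' @param bparams [burst_params()].
#' @param phases Phases to evaluate.
#' @return Data frame of class `unit_metrics`, one row per unit.
#' @export
compute_unit_metrics <- function(units, schedule, light_protocol = NULL,
                                 electrical_protocol = NULL, map = NULL,
                                 windows = response_windows(),
                                 bparams = burst_params(),
                                 phases = c("pre", "pressure", "post")) {
  stopifnot(inherits(units, "unit_trains"))
  adj <- if (!is.null(electrical_protocol) && !is.null(map) &&
             !is.null(electrical_protocol$stim_electrode)) {
    adjacent_channels(electrical_protocol$stim_electrode, map)
  }
  ids <- unique(units$unit_id)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    uid <- ids[i]
    sel <- units$unit_id == uid
    times <- units$time[sel]
    channel <- units$channel[sel][1]
    bursts <- detect_bursts(times, bparams)
    row <- list(unit_id = uid, channel = channel, n_spikes = length(times))
    for (ph in phases) {
      has_spont <- nrow(phase_windows(schedule, ph, "spontaneous")) > 0
      row[[paste0("rate_", ph)]] <- if (has_spont) {
        phase_firing_rate(times, schedule, ph)
      } else NA_real_
      row[[paste0("pct_bursts_", ph)]] <- if (has_spont) {
        pct_spikes_in_bursts(times, bursts, schedule, ph)
      } else NA_real_
      row[[paste0("err_", ph)]] <- if (!is.null(electrical_protocol) &&
                                       (is.null(adj) || channel %in% adj)) {
        on_ph <- electrical_protocol$onsets[
          phase_of(electrical_protocol$onsets, schedule) == ph]
        if (length(on_ph)) {
          as.numeric(electrical_response_rate(times, electrical_protocol,
                                              windows, onsets = on_ph))
        } else NA_real_
      } else NA_real_
    }
    if (!is.null(light_protocol)) {
      rr <- light_response_rates(times, light_protocol, windows)
      row$rr_on <- rr[["rr_on"]]
      row$rr_off <- rr[["rr_off"]]
      row$category <- classify_rgc(rr[["rr_on"]], rr[["rr_off"]],
                                   windows$classify_threshold)
    } else {
      row$rr_on <- NA_real_
      row$rr_off <- NA_real_
      row$category <- "UNCATEGORIZED"
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("unit_metrics", "data.frame"))
}
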