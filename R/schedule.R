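#' Experiment phase schedule
#'
#' Describes the timeline of a pressure experiment: a lead-in period for the
#' tissue to settle (used only for quality control), a pre-pressure baseline,
#' the pressure phase, and a post-pressure recovery phase, together with the
#' recording windows placed inside each phase. All times are seconds from
#' experiment start and every interval is half-open `[start, end)`; a phase
#' boundary belongs to the later phase.
#'
#' @param lead,pre,pressure,post Numeric length-2 vectors `c(start, end)` for
#'   the four phases, in seconds. They must be ordered and non-overlapping.
#' @param windows Data frame with columns `phase`, `kind` (one of
#'   `"spontaneous"`, `"light"`, `"electrical"`), `start`, `end`. Each window
#'   must lie inside its phase.
#' @param condition Condition label, e.g. `"90 mmHg"`.
#' @return An object of class `phase_schedule`.
#' @export
phase_schedule <- function(lead, pre, pressure, post, windows,
                           condition = "90 mmHg") {
  phases <- rbind(
    data.frame(phase = "lead", start = lead[1], end = lead[2]),
    data.frame(phase = "pre", start = pre[1], end = pre[2]),
    data.frame(phase = "pressure", start = pressure[1], end = pressure[2]),
    data.frame(phase = "post", start = post[1], end = post[2])
  )
  if (any(phases$end <= phases$start)) {
    stop("phase intervals must have positive duration", call. = FALSE)
  }
  if (any(diff(as.vector(rbind(phases$start, phases$end))) < 0)) {
    stop("phases must be ordered lead < pre < pressure < post and non-overlapping",
         call. = FALSE)
  }
  stopifnot(is.data.frame(windows),
            all(c("phase", "kind", "start", "end") %in% names(windows)))
  if (nrow(windows) == 0) {
    stop("schedule contains no recording windows", call. = FALSE)
  }
  if (!all(windows$phase %in% phases$phase)) {
    stop("window phases must be one of lead/pre/pressure/post", call. = FALSE)
  }
  if (!all(windows$kind %in% c("spontaneous", "light", "electrical"))) {
    stop("window kind must be spontaneous, light or electrical", call. = FALSE)
  }
  ph <- phases[match(windows$phase, phases$phase), ]
  if (any(windows$start < ph$start | windows$end > ph$end)) {
    stop("recording windows must lie inside their phase", call. = FALSE)
  }
  windows <- windows[order(windows$start), , drop = FALSE]
  rownames(windows) <- NULL
  structure(list(phases = phases, windows = windows, condition = condition),
            class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("Phase schedule (", x$condition, ")\n", sep = "")
  print(x$phases, row.names = FALSE)
  cat(nrow(x$windows), "recording windows:",
      paste(sprintf("%s=%d", names(table(x$windows$kind)),
                    as.integer(table(x$windows$kind))), collapse = ", "), "\n")
  invisible(x)
}

#' Phase bounds and recording windows
#'
#' @param schedule A [phase_schedule()].
#' @param phase One of `"lead"`, `"pre"`, `"pressure"`, `"post"`.
#' @param kind Optional window kind filter.
#' @return `phase_windows()` returns the matching rows of the window table.
#' @export
phase_windows <- function(schedule, phase, kind = NULL) {
  stopifnot(inherits(schedule, "phase_schedule"))
  w <- schedule$windows[schedule$windows$phase == phase, , drop = FALSE]
  if (!is.null(kind)) w <- w[w$kind %in% kind, , drop = FALSE]
  w
}

#' Phase membership of time points
#'
#' @param times Numeric vector of times (s).
#' @param schedule A [phase_schedule()].
#' @return Character vector: the phase containing each time (half-open
#'   intervals), `NA` outside all phases.
#' @export
phase_of <- function(times, schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  out <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(schedule$phases))) {
    p <- schedule$phases[i, ]
    out[times >= p$start & times < p$end] <- p$phase
  }
  out
}

#' Which spikes fall into a set of recording windows
#'
#' @param times Numeric vector of spike times (s).
#' @param windows Data frame with `start` and `end` columns.
#' @return Logical vector, `TRUE` where a time lies in some window
#'   (half-open).
#' @export
in_windows <- function(times, windows) {
  hit <- rep(FALSE, length(times))
  for (i in seq_len(nrow(windows))) {
    hit <- hit | (times >= windows$start[i] & times < windows$end[i])
  }
  hit
}

#' Stimulus protocol
#'
#' Typed set of stimulus onsets. Electrical stimuli are biphasic current
#' pulses (default +/- 80 uA, 500 us per phase, cathodic first) delivered
#' through one MEA electrode; light stimuli are full-field pulses with a
#' fixed duration (default 1 s), whose offset is `onset + pulse_duration`.
#'
#' @param kind `"electrical"` or `"light"`.
#' @param onsets Strictly increasing vector of stimulus onset times (s).
#' @param pulse_duration Light pulse duration (s); ignored for electrical.
#' @param amplitude_uA,phase_width_us Electrical pulse parameters.
#' @param stim_electrode Stimulation electrode id (electrical only).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(kind = c("electrical", "light"), onsets,
                              pulse_duration = 1, amplitude_uA = 80,
                              phase_width_us = 500, stim_electrode = NULL) {
  kind <- match.arg(kind)
  if (length(onsets) == 0 || any(diff(onsets) <= 0)) {
    stop("onsets must be non-empty and strictly increasing", call. = FALSE)
  }
  structure(list(kind = kind, onsets = as.numeric(onsets),
                 pulse_duration = if (kind == "light") pulse_duration else NULL,
                 amplitude_uA = if (kind == "electrical") amplitude_uA else NULL,
                 phase_width_us = if (kind == "electrical") phase_width_us else NULL,
                 stim_electrode = stim_electrode),
            class = "stimulus_protocol")
}

#' Build a complete experiment design (schedule plus protocols)
#'
#' Lays out recording windows sequentially inside each phase and attaches the
#' matching stimulus protocols. Two profiles are provided: `"full"` mirrors
#' the bench protocol (60 s recordings, 10 s interstimulus interval, 30 min
#' lead and pre phases, 2 h pressure and post phases); `"desk"` is a
#' scaled-down layout for simulation studies and tests (10 s spontaneous
#' recordings, shorter stimulation recordings sized to still fit five pulses
#' per recording).
#'
#' @param condition Condition label.
#' @param profile `"desk"` or `"full"`. Explicit arguments override profile
#'   defaults.
#' @param spont_recordings,light_recordings,electrical_recordings Named
#'   integer vectors (`pre`, `pressure`, `post`): recordings per phase.
#' @param spont_s,light_s,electrical_s Recording durations (s).
#' @param isi Interstimulus interval within a stimulation recording (s).
#' @param pulses_per_recording Stimulus pulses per stimulation recording.
#' @param lead_s Lead time before the pre phase (s); the last `spont_s`
#'   seconds of it form the quality-control recording window.
#' @param gap_s Gap between consecutive recording windows (s).
#' @param stim_electrode Electrode used for electrical stimulation.
#' @param phase_s Optional named vector of fixed phase durations (s); by
#'   default each phase is just long enough for its windows.
#' @return A list of class `experiment_design` with elements `schedule`,
#'   `light_protocol` and `electrical_protocol` (either may be `NULL`).
#' @export
build_experiment <- function(condition = "90 mmHg",
                             profile = c("desk", "full"),
                             spont_recordings = NULL,
                             light_recordings = NULL,
                             electrical_recordings = NULL,
                             spont_s = NULL, light_s = NULL,
                             electrical_s = NULL, isi = NULL,
                             pulses_per_recording = 5,
                             lead_s = NULL, gap_s = 1,
                             stim_electrode = "E44",
                             phase_s = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "full") {
    list(spont = c(pre = 4, pressure = 8, post = 4),
         light = c(pre = 2, pressure = 2, post = 2),
         elec = c(pre = 2, pressure = 2, post = 2),
         spont_s = 60, light_s = 60, electrical_s = 60, isi = 10,
         lead_s = 1800,
         phase_s = c(pre = 1800, pressure = 7200, post = 7200))
  } else {
    list(spont = c(pre = 6, pressure = 6, post = 6),
         light = c(pre = 2, pressure = 2, post = 2),
         elec = c(pre = 0, pressure = 0, post = 0),
         spont_s = 10, light_s = 20, electrical_s = 26, isi = 4,
         lead_s = 30, phase_s = NULL)
  }
  spont_recordings <- spont_recordings %||% def$spont
  light_recordings <- light_recordings %||% def$light
  electrical_recordings <- electrical_recordings %||% def$elec
  spont_s <- spont_s %||% def$spont_s
  light_s <- light_s %||% def$light_s
  electrical_s <- electrical_s %||% def$electrical_s
  isi <- isi %||% def$isi
  lead_s <- lead_s %||% def$lead_s
  phase_s <- phase_s %||% def$phase_s

  # earliest onset leaving room for the pre-stimulus analysis window
  light_first <- 2
  elec_first <- 4
  need_light <- light_first + (pulses_per_recording - 1) * isi + 1.5
  need_elec <- elec_first + (pulses_per_recording - 1) * isi + 0.5
  if (any(light_recordings > 0) && need_light > light_s) {
    stop("light recording too short for ", pulses_per_recording,
         " pulses at isi ", isi, call. = FALSE)
  }
  if (any(electrical_recordings > 0) && need_elec > electrical_s) {
    stop("electrical recording too short for the pulse protocol", call. = FALSE)
  }

  light_onsets <- numeric(0)
  elec_onsets <- numeric(0)
  win <- list()
  # the quality-control recording occupies the tail of the lead time
  qc_dur <- min(spont_s, lead_s)
  win[[1]] <- data.frame(phase = "lead", kind = "spontaneous",
                         start = lead_s - qc_dur, end = lead_s)
  t <- lead_s
  bounds <- list(lead = c(0, lead_s))
  for (ph in c("pre", "pressure", "post")) {
    ph_start <- t
    counts <- c(spontaneous = unname(spont_recordings[ph]),
                light = unname(light_recordings[ph]),
                electrical = unname(electrical_recordings[ph]))
    for (kind in names(counts)) {
      dur <- switch(kind, spontaneous = spont_s, light = light_s,
                    electrical = electrical_s)
      for (r in seq_len(counts[kind])) {
        win[[length(win) + 1]] <- data.frame(phase = ph, kind = kind,
                                             start = t, end = t + dur)
        if (kind == "light") {
          light_onsets <- c(light_onsets,
                            t + light_first + (0:(pulses_per_recording - 1)) * isi)
        }
        if (kind == "electrical") {
          elec_onsets <- c(elec_onsets,
                           t + elec_first + (0:(pulses_per_recording - 1)) * isi)
        }
        t <- t + dur + gap_s
      }
    }
    ph_end <- if (!is.null(phase_s)) ph_start + unname(phase_s[ph]) else t
    if (ph_end < t - gap_s) {
      stop("phase duration too short for its recording windows", call. = FALSE)
    }
    # a phase without recording windows still needs positive duration
    bounds[[ph]] <- c(ph_start, max(ph_end, t - gap_s + 1e-9, ph_start + 1))
    t <- bounds[[ph]][2]
  }
  schedule <- phase_schedule(bounds$lead, bounds$pre, bounds$pressure,
                             bounds$post, do.call(rbind, win), condition)
  light_protocol <- if (length(light_onsets)) {
    stimulus_protocol("light", light_onsets)
  }
  electrical_protocol <- if (length(elec_onsets)) {
    stimulus_protocol("electrical", elec_onsets, stim_electrode = stim_electrode)
  }
  structure(list(schedule = schedule, light_protocol = light_protocol,
                 electrical_protocol = electrical_protocol),
            class = "experiment_design")
}

#' Bursting levels observed per pressure condition
#'
#' Reference bursting statistics used to calibrate the simulator: the
#' percentage of spikes fired in bursts during the pre phase and the
#' multiplicative change during the pressure and post phases, for each
#' experimental condition of the pressure study. Under 90 mmHg the fraction
#' of spikes in bursts roughly doubles (9.90% to 20.60%, a factor of 2.08)
#' and stays elevated after pressure release, while taurine (1 mM)
#' counteracts the increase.
#'
#' @return Data frame with columns `condition`, `pre_pct`, `pressure_mod`,
#'   `post_mod`.
#' @export
condition_presets <- function() {
  pre <- c(17.38, 15.91, 12.11, 12.46, 11.02, 9.90, 17.81)
  pressure <- c(22.37, 16.92, 17.14, 19.37, 15.35, 20.60, 15.03)
  post <- c(21.14, 16.88, 17.77, 20.53, 13.98, 21.21, 12.09)
  data.frame(
    condition = c("open MEA", "0 mmHg", "10 mmHg", "30 mmHg", "60 mmHg",
                  "90 mmHg", "90 mmHg + taurine"),
    pre_pct = pre,
    pressure_mod = pressure / pre,
    post_mod = post / pre
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
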