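#' Raw multichannel recording container
#'
#' @param voltage Numeric matrix, channels x samples, in microvolts; row
#'   names are the channel identifiers unless `channels` is given.
#' @param sample_rate Sampling rate (Hz).
#' @param channels Channel identifiers (defaults to row names).
#' @param t0 Time of the first sample (s).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(voltage, sample_rate = 25000, channels = NULL,
                          t0 = 0) {
  stopifnot(is.matrix(voltage), sample_rate > 0, all(is.finite(voltage)))
  channels <- channels %||% rownames(voltage)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nrow(voltage)))
  stopifnot(length(channels) == nrow(voltage))
  rownames(voltage) <- channels
  structure(list(voltage = voltage, sample_rate = sample_rate,
                 channels = channels, t0 = t0,
                 duration = ncol(voltage) / sample_rate),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d channels x %d samples (%.2f s at %g Hz)\n",
              nrow(x$voltage), ncol(x$voltage), x$duration, x$sample_rate))
  invisible(x)
}

#' Spike detection parameters
#'
#' Defaults reproduce the recording-software chain: a second-order
#' Butterworth high-pass at 200 Hz and low-pass at 2000 Hz, and detection of
#' negative threshold crossings at -20 uV.
#'
#' @param hp_cutoff,lp_cutoff High-/low-pass cutoffs (Hz), `0 < hp < lp`.
#' @param filter_order Butterworth filter order.
#' @param threshold_uV Detection threshold (uV, negative).
#' @param cutout_pre_ms,cutout_post_ms Waveform cutout extent around the
#'   negative peak (ms).
#' @param dead_time_ms Minimum separation between detected events (ms).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(hp_cutoff = 200, lp_cutoff = 2000,
                             filter_order = 2, threshold_uV = -20,
                             cutout_pre_ms = 1, cutout_post_ms = 2,
                             dead_time_ms = 1) {
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff)) {
    stop("cutoffs must satisfy 0 < hp_cutoff < lp_cutoff", call. = FALSE)
  }
  if (threshold_uV >= 0) stop("threshold_uV must be negative", call. = FALSE)
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 filter_order = filter_order, threshold_uV = threshold_uV,
                 cutout_pre_ms = cutout_pre_ms,
                 cutout_post_ms = cutout_post_ms,
                 dead_time_ms = dead_time_ms),
            class = "detection_params")
}

#' Band-pass filter a raw recording
#'
#' Applies the high-pass and low-pass Butterworth sections per channel with
#' zero-phase (forward-backward) filtering, so detected peak times carry no
#' filter delay. Filtering is linear and time invariant; the DC component is
#' rejected by the high-pass section.
#'
#' @param raw A [raw_recording()].
#' @param params [detection_params()].
#' @return A filtered [raw_recording()] of the same shape and units.
#' @export
bandpass_filter <- function(raw, params = detection_params()) {
  stopifnot(inherits(raw, "raw_recording"))
  nyq <- raw$sample_rate / 2
  if (params$lp_cutoff >= nyq) {
    stop("lp_cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  bf_h <- signal::butter(params$filter_order, params$hp_cutoff / nyq,
                         type = "high")
  bf_l <- signal::butter(params$filter_order, params$lp_cutoff / nyq,
                         type = "low")
  v <- raw$voltage
  for (i in seq_len(nrow(v))) {
    x <- signal::filtfilt(bf_h, v[i, ])
    v[i, ] <- signal::filtfilt(bf_l, x)
  }
  out <- raw_recording(v, raw$sample_rate, raw$channels, raw$t0)
  attr(out, "filtered") <- TRUE
  out
}

#' Detect spikes by negative threshold crossing
#'
#' Emits one event at each local voltage minimum at or below the threshold,
#' enforcing a dead time between consecutive events (the deepest minimum of a
#' cluster wins) to prevent double counting. Each event carries a waveform
#' cutout around its
#' negative peak; events too close to the trace edges for a full cutout are
#' dropped and counted.
#'
#' @param raw A band-pass filtered [raw_recording()].
#' @param params [detection_params()].
#' @return An object of class `spike_events`: list with `events` (data frame
#'   `channel`, `time`, `sample`, `peak_uV`), `cutouts` (per-channel matrices,
#'   events x samples), `sample_rate`, `duration`, `params` and the count of
#'   `edge_dropped` events.
#' @export
detect_spikes <- function(raw, params = detection_params()) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$sample_rate
  n_pre <- round(params$cutout_pre_ms / 1000 * fs)
  n_post <- round(params$cutout_post_ms / 1000 * fs)
  dead <- params$dead_time_ms / 1000
  th <- params$threshold_uV
  ev_list <- list()
  cutouts <- list()
  edge_dropped <- 0L
  for (ch in raw$channels) {
    v <- raw$voltage[ch, ]
    n <- length(v)
    if (n < 3) next
    core <- 2:(n - 1)
    is_min <- v[core] <= th & v[core] <= v[core - 1] & v[core] < v[core + 1]
    cand <- core[is_min]
    if (!length(cand)) next
    # dead time: within a cluster of minima, keep the deepest one (keeps the
    # spike's true trough, and makes smaller event sets at stricter
    # thresholds nest inside larger ones)
    kept <- cand[1]
    for (i in seq_along(cand)[-1]) {
      last <- kept[length(kept)]
      if ((cand[i] - last) / fs < dead) {
        if (v[cand[i]] < v[last]) kept[length(kept)] <- cand[i]
      } else {
        kept <- c(kept, cand[i])
      }
    }
    cand <- kept
    full <- cand - n_pre >= 1 & cand + n_post <= n
    edge_dropped <- edge_dropped + sum(!full)
    cand <- cand[full]
    if (!length(cand)) next
    ev_list[[ch]] <- data.frame(channel = ch, time = (cand - 1) / fs,
                                sample = cand, peak_uV = v[cand],
                                stringsAsFactors = FALSE)
    cut <- matrix(0, nrow = length(cand), ncol = n_pre + n_post + 1)
    for (i in seq_along(cand)) {
      cut[i, ] <- v[(cand[i] - n_pre):(cand[i] + n_post)]
    }
    cutouts[[ch]] <- cut
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else {
    data.frame(channel = character(0), time = numeric(0),
               sample = integer(0), peak_uV = numeric(0))
  }
  rownames(events) <- NULL
  if (edge_dropped > 0) {
    message("detect_spikes: dropped ", edge_dropped,
            " event(s) too close to trace edges for a full cutout")
  }
  structure(list(events = events, cutouts = cutouts, sample_rate = fs,
                 duration = raw$duration, params = params,
                 edge_dropped = edge_dropped),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("spike_events: %d events on %d channel(s) over %.2f s\n",
              nrow(x$events), length(x$cutouts), x$duration))
  invisible(x)
}

#' Flag implausibly active or saturated channels
#'
#' Channels whose sustained event rate exceeds `max_rate` (default
#' 200 events/s, far above retinal ganglion cell rates) or whose raw trace
#' reaches `saturation_uV` are flagged as noise channels. Flags are reported,
#' never silently applied.
#'
#' @param events A [detect_spikes()] result.
#' @param max_rate Maximum plausible sustained event rate (events/s).
#' @param raw Optional raw recording for the saturation check.
#' @param saturation_uV Absolute voltage regarded as amplifier saturation.
#' @return Sorted character vector of flagged channel identifiers.
#' @export
flag_noise_channels <- function(events, max_rate = 200, raw = NULL,
                                saturation_uV = 3000) {
  stopifnot(inherits(events, "spike_events"))
  counts <- table(events$events$channel)
  rates <- as.numeric(counts) / events$duration
  flagged <- names(counts)[rates > max_rate]
  if (!is.null(raw)) {
    sat <- raw$channels[apply(abs(raw$voltage) >= saturation_uV, 1, any)]
    flagged <- union(flagged, sat)
  }
  flagged <- sort(flagged)
  if (length(flagged)) {
    message("flag_noise_channels: flagged ", paste(flagged, collapse = ", "))
  }
  flagged
}
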