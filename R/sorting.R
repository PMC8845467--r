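#' Spike sorting parameters
#'
#' @param n_components Number of principal components used as waveform
#'   features.
#' @param max_units_per_channel Upper bound on units per electrode.
#' @param min_spikes_per_unit Clusters smaller than this are merged into the
#'   nearest cluster.
#' @param overlap_merge_sd Cluster pairs whose centroids are separated by
#'   fewer than this many pooled standard deviations (projected onto the
#'   line connecting the centroids) are merged: such mixture components
#'   overlap too heavily to represent distinct cells and typically arise
#'   from alignment jitter within one unit.
#' @return A list of class `sorting_params`.
#' @export
sorting_params <- function(n_components = 2, max_units_per_channel = 4,
                           min_spikes_per_unit = 50, overlap_merge_sd = 4) {
  stopifnot(n_components >= 1, max_units_per_channel >= 1,
            min_spikes_per_unit >= 1, overlap_merge_sd >= 0)
  structure(list(n_components = n_components,
                 max_units_per_channel = max_units_per_channel,
                 min_spikes_per_unit = min_spikes_per_unit,
                 overlap_merge_sd = overlap_merge_sd),
            class = "sorting_params")
}

#' Project waveform cutouts onto principal components
#'
#' Computes the channel's PCA over the cutout matrix and returns the scores
#' on the first `n_components` components. The sign of each component is
#' fixed so that its largest-magnitude loading is positive, making the
#' features deterministic. With fewer informative dimensions than requested
#' (e.g. identical cutouts) the missing scores are zero.
#'
#' @param cutouts Numeric matrix, events x samples.
#' @param n_components Number of components to keep.
#' @return Numeric matrix, events x `n_components`.
#' @export
extract_features <- function(cutouts, n_components = 2) {
  stopifnot(is.matrix(cutouts))
  if (nrow(cutouts) < 2) {
    stop("extract_features needs at least 2 events", call. = FALSE)
  }
  scores <- matrix(0, nrow = nrow(cutouts), ncol = n_components)
  if (stats::sd(as.vector(cutouts)) == 0 ||
      all(apply(cutouts, 2, stats::sd) == 0)) {
    return(scores)  # zero-variance: all events identical
  }
  pc <- stats::prcomp(cutouts, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    flip <- if (load[which.max(abs(load))] < 0) -1 else 1
    scores[, j] <- flip * pc$x[, j]
  }
  scores
}

#' Cluster waveform features into putative units
#'
#' Fits Gaussian mixtures with 1 to `max_units_per_channel` components to the
#' feature matrix and selects the number of units by BIC (ties broken toward
#' fewer units). Two cleanup rules follow: components separated by fewer
#' than `overlap_merge_sd` pooled standard deviations (projected onto the
#' line joining their centroids) are merged, since such heavily overlapping
#' components arise from within-unit structure (e.g. peak-alignment jitter)
#' rather than distinct cells; and clusters with fewer than
#' `min_spikes_per_unit` events are merged into the nearest remaining
#' cluster (Euclidean distance between centroids). Degenerate features (all
#' identical) yield a single unit.
#'
#' @param features Matrix from [extract_features()].
#' @param params [sorting_params()].
#' @param seed Integer seed (the mixture initialization is deterministic, the
#'   seed guards any stochastic fallback).
#' @return Integer vector of unit labels (1-based, consecutive, ordered by
#'   first occurrence).
#' @export
cluster_units <- function(features, params = sorting_params(), seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  if (max(stats::dist(features)) == 0) return(rep(1L, n))
  set.seed(seed)
  fit <- tryCatch(
    Mclust(features, G = seq_len(params$max_units_per_channel),
           verbose = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) return(rep(1L, n))
  # parsimony: smallest G whose best model ties the global BIC optimum
  bic <- fit$BIC
  best <- max(bic, na.rm = TRUE)
  g_values <- as.integer(rownames(bic))
  g_best <- min(g_values[apply(bic, 1, function(r) any(!is.na(r) & r >= best - 1e-8))])
  cls <- if (g_best < fit$G) {
    refit <- tryCatch(Mclust(features, G = g_best, verbose = FALSE),
                      error = function(e) NULL)
    if (is.null(refit)) fit$classification else refit$classification
  } else fit$classification
  cls <- as.integer(cls)

  # merge mixture components that overlap too heavily to be distinct cells
  # (separation measured in pooled SDs along the line joining the centroids)
  proj_sep <- function(a, b) {
    fa <- features[cls == a, , drop = FALSE]
    fb <- features[cls == b, , drop = FALSE]
    if (nrow(fa) < 2 || nrow(fb) < 2) return(Inf)
    d <- colMeans(fb) - colMeans(fa)
    len <- sqrt(sum(d^2))
    if (len == 0) return(0)
    u <- d / len
    pooled <- sqrt((stats::var(fa %*% u)[1] + stats::var(fb %*% u)[1]) / 2)
    if (pooled == 0) return(Inf)
    len / pooled
  }
  repeat {
    labs <- sort(unique(cls))
    if (length(labs) <= 1) break
    pairs <- utils::combn(labs, 2)
    seps <- apply(pairs, 2, function(p) proj_sep(p[1], p[2]))
    if (min(seps) >= params$overlap_merge_sd) break
    p <- pairs[, which.min(seps)]
    cls[cls == p[2]] <- p[1]
  }

  # merge undersized clusters into their nearest neighbour
  repeat {
    sizes <- table(cls)
    if (length(sizes) <= 1) break
    small <- names(sizes)[sizes < params$min_spikes_per_unit]
    if (!length(small)) break
    victim <- small[which.min(sizes[small])]
    cent <- vapply(names(sizes),
                   function(g) colMeans(features[cls == as.integer(g), ,
                                                 drop = FALSE]),
                   numeric(ncol(features)))
    cent <- t(cent)
    d <- sqrt(rowSums((cent - matrix(cent[victim, ], nrow(cent),
                                     ncol(cent), byrow = TRUE))^2))
    d[victim] <- Inf
    target <- names(sizes)[which.min(d)]
    cls[cls == as.integer(victim)] <- as.integer(target)
  }
  # relabel consecutively in order of first appearance
  as.integer(factor(cls, levels = unique(cls)))
}

#' Sort detected events into units, channel by channel
#'
#' @param events A [detect_spikes()] result.
#' @param params [sorting_params()].
#' @param seed Integer seed.
#' @return Named list (per channel) of integer unit assignments; channels
#'   with fewer than two events are skipped with a message.
#' @export
sort_events <- function(events, params = sorting_params(), seed = 1) {
  stopifnot(inherits(events, "spike_events"))
  out <- list()
  for (ch in names(events$cutouts)) {
    cut <- events$cutouts[[ch]]
    if (nrow(cut) < 2) {
      message("sort_events: channel ", ch, " skipped (", nrow(cut), " event(s))")
      next
    }
    feats <- extract_features(cut, params$n_components)
    out[[ch]] <- cluster_units(feats, params, seed = seed)
  }
  out
}

#' Assemble per-unit spike trains from sorted events
#'
#' One train per (channel, unit) across the whole experiment; per-phase
#' sub-trains are obtained downstream through the phase schedule, so units
#' persist across pre/pressure/post. The total spike count equals the number
#' of assigned events.
#'
#' @param assignments Per-channel assignments from [sort_events()].
#' @param events The matching [detect_spikes()] result.
#' @return Data frame of class `unit_trains` with columns `unit_id`,
#'   `channel`, `time`, sorted by unit then time.
#' @export
build_spike_trains <- function(assignments, events) {
  stopifnot(inherits(events, "spike_events"))
  rows <- list()
  for (ch in names(assignments)) {
    ev <- events$events[events$events$channel == ch, , drop = FALSE]
    stopifnot(nrow(ev) == length(assignments[[ch]]))
    rows[[ch]] <- data.frame(unit_id = sprintf("%s_u%d", ch, assignments[[ch]]),
                             channel = ch, time = ev$time,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(unit_id = character(0), channel = character(0),
               time = numeric(0))
  }
  out <- out[order(out$unit_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("unit_trains", "data.frame"),
            n_events = nrow(out))
}

#' Validate a pre-sorted unit spike-train table
#'
#' Accepts per-unit spike timestamp tables (e.g. exported by an external
#' sorter, or the simulator's ground-truth trains) as pipeline input.
#'
#' @param df Data frame with columns `unit_id`, `channel`, `time`.
#' @return The table, sorted, with class `unit_trains`.
#' @export
unit_trains <- function(df) {
  stopifnot(all(c("unit_id", "channel", "time") %in% names(df)))
  df <- as.data.frame(df)[, c("unit_id", "channel", "time")]
  df <- df[order(df$unit_id, df$time), , drop = FALSE]
  if (any(unlist(tapply(df$time, df$unit_id, function(t) diff(t) <= 0)))) {
    stop("spike times must be strictly increasing within each unit",
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("unit_trains", "data.frame"), n_events = nrow(df))
}
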