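#' Experiment-level pipeline configuration
#'
#' Bundles every stage's parameters plus the experiment-level quality
#' control. Two input modes are supported: `"spike_trains"` feeds the
#' simulator's per-unit spike tables straight into the metrics stage (the
#' pre-sorted input mode, also used for external timestamp tables), while
#' `"raw"` renders voltage traces and runs filtering, detection and sorting
#' first.
#'
#' @param condition Condition label (see [condition_presets()]).
#' @param seed Integer seed; determines the whole run.
#' @param n_cells Simulated population size.
#' @param n_channels Number of recording channels used (<= 59; the desk
#'   profile uses 16).
#' @param profile Design profile passed to [build_experiment()].
#' @param input_mode `"spike_trains"` or `"raw"`.
#' @param min_active_channels Reject the retina when fewer channels show
#'   spontaneous firing after lead time (default 10).
#' @param noise_sd_uV Rendering noise SD (raw mode).
#' @param stats_Q ROUT coefficient for the stats stage.
#' @param windows,bparams,sorting,detection Stage parameter objects.
#' @param design_args Extra arguments for [build_experiment()].
#' @param sim_args Extra arguments for [sim_config()].
#' @param out_dir Optional output directory for CSV/JSON/YAML artifacts.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(condition = "90 mmHg", seed = 1,
                              n_cells = 100, n_channels = 16,
                              profile = c("desk", "full"),
                              input_mode = c("spike_trains", "raw"),
                              min_active_channels = 10,
                              noise_sd_uV = 10, stats_Q = 0.001,
                              windows = response_windows(),
                              bparams = burst_params(),
                              sorting = sorting_params(),
                              detection = detection_params(),
                              design_args = list(),
                              sim_args = list(),
                              out_dir = NULL) {
  profile <- match.arg(profile)
  input_mode <- match.arg(input_mode)
  if (min_active_channels < 1 || min_active_channels > 60) {
    stop("min_active_channels must be in [1, 60]", call. = FALSE)
  }
  if (n_channels < 1 || n_channels > 59) {
    stop("n_channels must be in [1, 59]", call. = FALSE)
  }
  structure(list(condition = condition, seed = as.integer(seed),
                 n_cells = n_cells, n_channels = n_channels,
                 profile = profile, input_mode = input_mode,
                 min_active_channels = min_active_channels,
                 noise_sd_uV = noise_sd_uV, stats_Q = stats_Q,
                 windows = windows, bparams = bparams, sorting = sorting,
                 detection = detection, design_args = design_args,
                 sim_args = sim_args, out_dir = out_dir),
            class = "experiment_config")
}

#' Retina-level quality control
#'
#' A retina is rejected when spontaneous firing is detected on fewer than
#' `min_active_channels` recording channels after the lead time. A channel
#' counts as active when it carries at least one spike/event in the lead-time
#' recording window.
#'
#' @param lead_counts Named numeric vector: spikes per channel in the
#'   lead-time window (zeros included).
#' @param config An [experiment_config()] (or any list with
#'   `min_active_channels`).
#' @return List with `accept` (logical), `n_active`, `min_required` and a
#'   human-readable `reason`.
#' @export
qc_retina <- function(lead_counts, config) {
  n_active <- sum(lead_counts >= 1)
  accept <- n_active >= config$min_active_channels
  reason <- sprintf("%d of %d channels active after lead time (minimum %d): %s",
                    n_active, length(lead_counts),
                    config$min_active_channels,
                    if (accept) "accepted" else "rejected")
  message("qc_retina: ", reason)
  list(accept = accept, n_active = n_active,
       min_required = config$min_active_channels, reason = reason)
}

#' Burst table for a set of unit trains
#'
#' @param units A [unit_trains()] table.
#' @param bparams [burst_params()].
#' @return Data frame `unit_id`, `start_s`, `end_s`, `n_spikes`.
#' @export
burst_table <- function(units, bparams = burst_params()) {
  rows <- lapply(unique(units$unit_id), function(uid) {
    b <- detect_bursts(units$time[units$unit_id == uid], bparams)
    if (!nrow(b)) return(NULL)
    data.frame(unit_id = uid, start_s = b$start, end_s = b$end,
               n_spikes = b$n_spikes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(unit_id = character(0), start_s = numeric(0),
                      end_s = numeric(0), n_spikes = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Group-level summary of per-unit metrics
#'
#' For each metric (spontaneous firing rate, percentage of spikes in bursts,
#' and the electrical response rate when present): per-phase n, all-data mean
#' and SD, ROUT-cleaned mean, outlier count, normalization to the pre phase
#' and integer percent change versus the previous phase; plus a one-way ANOVA
#' across phases with Tukey's post hoc test. The distribution of
#' ON/ON-OFF/OFF categories among the categorized units is reported
#' alongside.
#'
#' @param metrics A [compute_unit_metrics()] table.
#' @param Q ROUT coefficient.
#' @param phases Phases, in order.
#' @return A list of class `experiment_summary`.
#' @export
summarize_experiment <- function(metrics, Q = 0.001,
                                 phases = c("pre", "pressure", "post")) {
  out <- list()
  specs <- c(firing_rate = "rate_", pct_bursts = "pct_bursts_",
             electrical_rr = "err_")
  for (m in names(specs)) {
    cols <- paste0(specs[m], phases)
    if (!all(cols %in% names(metrics))) next
    vals <- lapply(cols, function(cl) metrics[[cl]][is.finite(metrics[[cl]])])
    names(vals) <- phases
    if (all(lengths(vals) == 0)) next
    gs <- lapply(vals, group_stats, Q = Q)
    tab <- data.frame(
      phase = phases,
      n = vapply(gs, function(g) g$n, 0L),
      mean_all = vapply(gs, function(g) g$mean_all, 0),
      sd_all = vapply(gs, function(g) g$sd_all, 0),
      mean_cleaned = vapply(gs, function(g) g$mean_cleaned, 0),
      n_outliers = vapply(gs, function(g) length(g$outliers), 0L)
    )
    if (is.finite(tab$mean_all[tab$phase == "pre"]) &&
        tab$mean_all[tab$phase == "pre"] > 0) {
      nz <- normalize_to_pre(setNames(tab$mean_all, tab$phase))
      tab$norm_ratio <- nz$ratio
      tab$norm_percent <- nz$percent
      tab$pct_change_vs_prev <- c(NA, percent_change(
        utils::head(tab$mean_all, -1), utils::tail(tab$mean_all, -1)))
    }
    anova <- if (sum(lengths(vals) >= 2) >= 2) {
      anova_oneway(vals[lengths(vals) >= 2])
    }
    tukey <- if (!is.null(anova) && is.finite(anova$p)) {
      tukey_hsd(vals[lengths(vals) >= 2])
    }
    out[[m]] <- list(table = tab, anova = anova,
                     anova_line = if (!is.null(anova)) format_anova_line(anova),
                     tukey = tukey)
  }
  if ("category" %in% names(metrics)) {
    categorized <- metrics$category[metrics$category != "UNCATEGORIZED"]
    if (length(categorized)) {
      ct <- table(factor(categorized, levels = c("ON", "ON_OFF", "OFF")))
      out$categories <- data.frame(category = names(ct),
                                   n = as.integer(ct),
                                   pct = round(100 * as.integer(ct) /
                                                 sum(ct), 2))
    }
    out$n_uncategorized <- sum(metrics$category == "UNCATEGORIZED")
  }
  structure(out, class = "experiment_summary")
}

#' Run the full simulate-detect-sort-metrics-stats pipeline
#'
#' Executes the five stages in order under a single seed: simulate a
#' ground-truth population and its spike trains, detect (render + filter +
#' threshold detection in raw mode; pass-through in pre-sorted mode), sort
#' (PCA + mixture clustering in raw mode), per-unit metrics, and group
#' statistics. Retina-level quality control is applied to the lead-time
#' window before analysis; a rejected retina yields empty metrics with an
#' explicit warning. A run manifest records every stage, the QC decision and
#' the spike bookkeeping (no silent data loss). When `config$out_dir` is set,
#' units, bursts, metrics and summaries are written as CSV, the manifest as
#' JSON and the configuration as YAML.
#'
#' @param config An [experiment_config()].
#' @return A list of class `mea_pipeline_result` with elements `manifest`,
#'   `design`, `cells`, `trains`, `units`, `metrics`, `bursts`, `summary`,
#'   `qc`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  stages <- list()
  note <- function(stage, status, detail = "") {
    stages[[length(stages) + 1]] <<- data.frame(stage = stage,
                                                status = status,
                                                detail = detail)
  }
  map <- mea_channel_map()
  channels <- utils::head(recording_channels(map), config$n_channels)

  design <- do.call(build_experiment,
                    c(list(condition = config$condition,
                           profile = config$profile), config$design_args))
  simcfg <- do.call(sim_config,
                    c(list(n_cells = config$n_cells,
                           condition = config$condition,
                           noise_sd_uV = config$noise_sd_uV,
                           seed = config$seed), config$sim_args))
  cells <- simulate_population(simcfg, map, channels)
  trains <- simulate_spike_trains(cells, design, simcfg)
  note("simulate", "ok", sprintf("%d cells, %d spikes", nrow(cells),
                                 nrow(trains)))

  exclusions <- list()
  leadw <- phase_windows(design$schedule, "lead")

  if (config$input_mode == "raw") {
    raw <- render_raw(trains, cells, channels = channels, config = simcfg)
    filt <- bandpass_filter(raw, config$detection)
    ev <- detect_spikes(filt, config$detection)
    noisy <- flag_noise_channels(ev, raw = filt)
    if (length(noisy)) {
      n_drop <- sum(ev$events$channel %in% noisy)
      exclusions$noise_channels <- list(channels = noisy, n_events = n_drop)
      ev$events <- ev$events[!ev$events$channel %in% noisy, , drop = FALSE]
      ev$cutouts <- ev$cutouts[setdiff(names(ev$cutouts), noisy)]
    }
    note("detect", "ok", sprintf("%d events (%d edge-dropped, %d noise channels)",
                                 nrow(ev$events), ev$edge_dropped,
                                 length(noisy)))
    lead_counts <- vapply(channels, function(ch) {
      sum(in_windows(ev$events$time[ev$events$channel == ch], leadw))
    }, 0)
  } else {
    note("detect", "bypassed", "pre-sorted spike-train input")
    lead_counts <- vapply(channels, function(ch) {
      sum(in_windows(trains$time[trains$channel == ch], leadw))
    }, 0)
  }

  qc <- qc_retina(lead_counts, config)
  if (!qc$accept) {
    warning("retina rejected by quality control: ", qc$reason)
    note("sort", "skipped", "retina rejected")
    note("metrics", "skipped", "retina rejected")
    note("stats", "skipped", "retina rejected")
    manifest <- build_manifest(config, stages, qc, n_in = nrow(trains),
                               n_out = 0, exclusions = exclusions)
    res <- structure(list(manifest = manifest, design = design,
                          cells = cells, trains = trains, units = NULL,
                          metrics = empty_metrics(), bursts = NULL,
                          summary = NULL, qc = qc),
                     class = "mea_pipeline_result")
    write_pipeline_outputs(res, config)
    return(res)
  }

  if (config$input_mode == "raw") {
    assignments <- sort_events(ev, config$sorting, seed = config$seed)
    units <- build_spike_trains(assignments, ev)
    n_unsorted <- nrow(ev$events) - nrow(units)
    if (n_unsorted > 0) exclusions$unsorted_events <- n_unsorted
    note("sort", "ok", sprintf("%d units, %d spikes",
                               length(unique(units$unit_id)), nrow(units)))
  } else {
    units <- unit_trains(data.frame(unit_id = trains$cell_id,
                                    channel = trains$channel,
                                    time = trains$time,
                                    stringsAsFactors = FALSE))
    note("sort", "bypassed", sprintf("%d pre-sorted units",
                                     length(unique(units$unit_id))))
  }

  metrics <- compute_unit_metrics(units, design$schedule,
                                  design$light_protocol,
                                  design$electrical_protocol, map,
                                  config$windows, config$bparams)
  bursts <- burst_table(units, config$bparams)
  note("metrics", "ok", sprintf("%d units", nrow(metrics)))

  summary <- summarize_experiment(metrics, Q = config$stats_Q)
  note("stats", "ok", sprintf("%d metric summaries",
                              sum(names(summary) %in%
                                    c("firing_rate", "pct_bursts",
                                      "electrical_rr"))))

  manifest <- build_manifest(config, stages, qc, n_in = nrow(trains),
                             n_out = nrow(units), exclusions = exclusions)
  res <- structure(list(manifest = manifest, design = design, cells = cells,
                        trains = trains, units = units, metrics = metrics,
                        bursts = bursts, summary = summary, qc = qc),
                   class = "mea_pipeline_result")
  write_pipeline_outputs(res, config)
  res
}

empty_metrics <- function() {
  structure(data.frame(unit_id = character(0), channel = character(0),
                       n_spikes = integer(0)),
            class = c("unit_metrics", "data.frame"))
}

build_manifest <- function(config, stages, qc, n_in, n_out, exclusions) {
  list(package = "meapress",
       version = as.character(utils::packageVersion("meapress")),
       seed = config$seed,
       condition = config$condition,
       input_mode = config$input_mode,
       config_hash = rlang::hash(unclass(config)),
       stages = do.call(rbind, stages),
       qc = qc[c("accept", "n_active", "min_required", "reason")],
       n_spikes_in = n_in, n_spikes_out = n_out,
       exclusions = exclusions)
}

#' @export
print.mea_pipeline_result <- function(x, ...) {
  cat("MEA pressure pipeline run (", x$manifest$condition, ", seed ",
      x$manifest$seed, ")\n", sep = "")
  print(x$manifest$stages, row.names = FALSE)
  invisible(x)
}

#' Report tables for a pipeline run
#'
#' Builds per-metric tables mirroring the figure-level summaries: per-phase
#' all-data mean and SD, ROUT-cleaned mean, value normalized to the pre
#' phase, integer percent change versus the previous phase, and the ANOVA
#' caption line; plus the ON/ON-OFF/OFF distribution.
#'
#' @param result A [run_pipeline()] result (or a compatible list with a
#'   `summary` element).
#' @return A list of class `mea_report` with one element per metric plus
#'   `categories`; empty (with a warning) if the run produced no metrics.
#' @export
make_report <- function(result) {
  s <- result$summary
  if (is.null(s) || !length(s)) {
    warning("make_report: no metrics available (rejected retina or empty run)")
    return(structure(list(), class = "mea_report"))
  }
  rep <- list()
  for (m in intersect(names(s), c("firing_rate", "pct_bursts",
                                  "electrical_rr"))) {
    rep[[m]] <- list(table = s[[m]]$table, anova_line = s[[m]]$anova_line,
                     tukey = s[[m]]$tukey)
  }
  rep$categories <- s$categories
  structure(rep, class = "mea_report")
}

#' @export
print.mea_report <- function(x, ...) {
  for (m in setdiff(names(x), "categories")) {
    cat("==", m, "==\n")
    print(x[[m]]$table, row.names = FALSE, digits = 4)
    if (!is.null(x[[m]]$anova_line)) cat(x[[m]]$anova_line, "\n")
  }
  if (!is.null(x$categories)) {
    cat("== categories ==\n")
    print(x$categories, row.names = FALSE)
  }
  invisible(x)
}
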