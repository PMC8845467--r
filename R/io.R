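#' Read and write interchange files
#'
#' Unit spike trains, detected events, per-unit metrics and burst tables are
#' exchanged as plain CSV; run manifests as JSON; configurations as YAML.
#'
#' @param units A [unit_trains()] table.
#' @param path File path.
#' @return `read_unit_trains()` returns a [unit_trains()] table; the writers
#'   return `path` invisibly.
#' @name mea_io
NULL

#' @rdname mea_io
#' @export
write_unit_trains <- function(units, path) {
  df <- data.frame(unit_id = units$unit_id, channel = units$channel,
                   time_s = units$time)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mea_io
#' @export
read_unit_trains <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("unit_id", "channel", "time_s") %in% names(df)))
  unit_trains(data.frame(unit_id = df$unit_id, channel = df$channel,
                         time = df$time_s, stringsAsFactors = FALSE))
}

#' @rdname mea_io
#' @param events A [detect_spikes()] result.
#' @export
write_events <- function(events, path) {
  df <- events$events
  names(df)[names(df) == "time"] <- "time_s"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mea_io
#' @param manifest Manifest list from [run_pipeline()].
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname mea_io
#' @param config An [experiment_config()].
#' @export
write_config_yaml <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname mea_io
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  for (nm in c("windows", "bparams", "sorting", "detection")) {
    if (!is.null(lst[[nm]])) {
      ctor <- switch(nm, windows = response_windows, bparams = burst_params,
                     sorting = sorting_params, detection = detection_params)
      args <- lst[[nm]]
      # constructors validate; map stored fields back onto arguments
      lst[[nm]] <- do.call(ctor, args[names(args) %in% names(formals(ctor))])
    }
  }
  do.call(experiment_config, lst[names(lst) %in% names(formals(experiment_config))])
}

write_pipeline_outputs <- function(result, config) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(result$units)) {
    write_unit_trains(result$units, file.path(dir, "units.csv"))
  }
  utils::write.csv(as.data.frame(result$metrics),
                   file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(result$bursts)) {
    utils::write.csv(result$bursts, file.path(dir, "bursts.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$summary)) {
    for (m in intersect(names(result$summary),
                        c("firing_rate", "pct_bursts", "electrical_rr"))) {
      utils::write.csv(result$summary[[m]]$table,
                       file.path(dir, paste0("summary_", m, ".csv")),
                       row.names = FALSE)
    }
  }
  write_manifest(result$manifest, file.path(dir, "manifest.json"))
  write_config_yaml(config, file.path(dir, "config.yaml"))
  invisible(dir)
}
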