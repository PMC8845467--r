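# Small fixed experiment designs and rendering helpers shared across tests.

tiny_design <- function(condition = "90 mmHg", light = c(pre = 1, pressure = 1,
                                                         post = 1)) {
  build_experiment(condition = condition, profile = "desk",
                   spont_recordings = c(pre = 2, pressure = 2, post = 2),
                   light_recordings = light,
                   electrical_recordings = c(pre = 0, pressure = 0, post = 0))
}

# render a single channel carrying the given spike trains (list of numeric
# vectors) with per-train template amplitudes/widths
render_channel <- function(spike_times, amps, widths = NULL, noise_sd = 5,
                           duration = NULL, fs = 25000, seed = 11) {
  widths <- widths %||% rep(1.5, length(spike_times))
  duration <- duration %||% (max(unlist(spike_times)) + 0.05)
  cfg <- sim_config(n_cells = 1, sample_rate = fs, noise_sd_uV = noise_sd,
                    seed = seed)
  cells <- data.frame(
    cell_id = sprintf("cell%03d", seq_along(spike_times)),
    category = "UNCATEGORIZED",
    tonic_rate = 1, gain_on = 1, gain_off = 1, response_duration = 0.4,
    home_channel = "E21", amp_uV = amps, width_ms = widths,
    stringsAsFactors = FALSE
  )
  class(cells) <- c("sim_cells", "data.frame")
  trains <- data.frame(
    cell_id = rep(cells$cell_id, lengths(spike_times)),
    channel = "E21",
    time = unlist(spike_times)
  )
  list(raw = render_raw(trains, cells, channels = "E21", config = cfg,
                        duration = duration, noise_sd_uV = noise_sd),
       trains = trains, cells = cells, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# greedy one-to-one matching of two sorted time vectors within a tolerance
match_count <- function(a, b, tol) {
  a <- sort(a); b <- sort(b)
  i <- 1; j <- 1; m <- 0
  while (i <= length(a) && j <= length(b)) {
    d <- a[i] - b[j]
    if (abs(d) <= tol) {
      m <- m + 1; i <- i + 1; j <- j + 1
    } else if (d < 0) i <- i + 1 else j <- j + 1
  }
  m
}

# best assignment accuracy over label permutations (small k)
assignment_accuracy <- function(assigned, truth) {
  truth <- as.integer(factor(truth))
  assigned <- as.integer(factor(assigned))
  k <- max(assigned, truth)
  perms <- if (k == 1) list(1L) else asplit(gtools_perms(k), 1)
  best <- 0
  for (p in perms) best <- max(best, mean(p[assigned] == truth))
  best
}

# tiny permutation generator (avoids a dependency)
gtools_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- gtools_perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    m <- cbind(i, sub + (sub >= i))
    out <- rbind(out, m)
  }
  unname(out)
}
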