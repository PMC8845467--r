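# Independent brute-force MaxInterval oracle: a literal spike-by-spike state
# machine, kept deliberately separate from the vectorized implementation in
# the package. Returns the same (start, end, n_spikes) table.
oracle_bursts <- function(times, params = burst_params()) {
  n <- length(times)
  cand_start <- integer(0)
  cand_end <- integer(0)
  if (n >= 2) {
    in_burst <- FALSE
    bs <- 0L
    for (i in 1:(n - 1)) {
      gap <- times[i + 1] - times[i]
      if (!in_burst) {
        if (gap <= params$max_interval_start) {
          in_burst <- TRUE
          bs <- i
        }
      } else {
        if (gap > params$max_interval_end) {
          cand_start <- c(cand_start, bs)
          cand_end <- c(cand_end, i)
          in_burst <- FALSE
        }
      }
    }
    if (in_burst) {
      cand_start <- c(cand_start, bs)
      cand_end <- c(cand_end, n)
    }
  }
  # merge candidates closer than min_interval_between
  if (length(cand_start) > 1) {
    k <- 1
    for (i in 2:length(cand_start)) {
      if (times[cand_start[i]] - times[cand_end[k]] <
          params$min_interval_between) {
        cand_end[k] <- cand_end[i]
      } else {
        k <- k + 1
        cand_start[k] <- cand_start[i]
        cand_end[k] <- cand_end[i]
      }
    }
    cand_start <- cand_start[1:k]
    cand_end <- cand_end[1:k]
  }
  # retention rules
  keep <- logical(length(cand_start))
  for (i in seq_along(cand_start)) {
    keep[i] <- (cand_end[i] - cand_start[i] + 1) >= params$min_spikes &&
      (times[cand_end[i]] - times[cand_start[i]]) >= params$min_duration
  }
  data.frame(start = times[cand_start[keep]], end = times[cand_end[keep]],
             n_spikes = as.integer(cand_end[keep] - cand_start[keep] + 1),
             start_idx = cand_start[keep], end_idx = cand_end[keep])
}

burst_tables_equal <- function(a, b) {
  isTRUE(all.equal(as.data.frame(a)[c("start_idx", "end_idx")],
                   as.data.frame(b)[c("start_idx", "end_idx")],
                   check.attributes = FALSE))
}
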