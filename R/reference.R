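#' Published group means of the pressure study
#'
#' All-data group means (with SD) reported for the hydrostatic-pressure MEA
#' study that this package's analysis reproduces: per condition and phase,
#' the spontaneous RGC firing frequency (Hz), the electrical response rate
#' (unitless) and the percentage of spikes fired in bursts. These values
#' summarize real recordings and are used here as reference input for the
#' reporting conventions ([percent_change()], [normalize_to_pre()]), not as
#' quantities the simulator could reproduce.
#'
#' @return Data frame with columns `condition`, `metric` (`"firing_rate"`,
#'   `"electrical_rr"`, `"pct_bursts"`), `pre`, `pressure`, `post`,
#'   `pre_sd`, `pressure_sd`, `post_sd`.
#' @export
reference_group_means <- function() {
  conds <- c("open MEA", "0 mmHg", "10 mmHg", "30 mmHg", "60 mmHg",
             "90 mmHg", "90 mmHg + taurine")
  fr <- rbind(
    c(11.36, 8.76, 10.80, 12.08, 10.78, 11.78),
    c(8.00, 5.81, 3.32, 11.13, 10.03, 4.66),
    c(7.13, 4.08, 3.75, 9.71, 3.97, 4.25),
    c(10.90, 8.59, 6.79, 12.61, 10.84, 9.74),
    c(11.66, 7.02, 6.42, 11.39, 6.75, 8.22),
    c(6.86, 7.21, 5.30, 7.56, 10.26, 8.44),
    c(9.56, 9.56, 6.34, 13.78, 11.42, 7.47)
  )
  er <- rbind(
    c(19.00, 21.77, 20.79, 63.61, 80.06, 61.51),
    c(8.92, 12.59, 9.26, 19.04, 33.07, 9.08),
    c(8.44, 13.12, 12.10, 20.58, 24.00, 26.60),
    c(2.89, 9.49, 9.71, 4.53, 26.64, 17.57),
    c(2.74, 3.94, 8.10, 3.08, 8.31, 17.30),
    c(3.47, 5.22, 11.21, 3.37, 8.01, 19.03),
    c(12.77, 43.12, 42.43, 22.47, 108.70, 112.90)
  )
  pb <- rbind(
    c(17.38, 22.37, 21.14, 22.83, 22.53, 20.63),
    c(15.91, 16.92, 16.88, 22.00, 20.49, 19.25),
    c(12.11, 17.14, 17.77, 19.33, 20.57, 20.05),
    c(12.46, 19.37, 20.53, 18.75, 18.52, 19.59),
    c(11.02, 15.35, 13.98, 16.19, 18.13, 16.53),
    c(9.90, 20.60, 21.21, 15.58, 20.42, 20.18),
    c(17.81, 15.03, 12.09, 23.97, 21.90, 18.93)
  )
  block <- function(m, metric) {
    data.frame(condition = conds, metric = metric, pre = m[, 1],
               pressure = m[, 2], post = m[, 3], pre_sd = m[, 4],
               pressure_sd = m[, 5], post_sd = m[, 6],
               stringsAsFactors = FALSE)
  }
  rbind(block(fr, "firing_rate"), block(er, "electrical_rr"),
        block(pb, "pct_bursts"))
}
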