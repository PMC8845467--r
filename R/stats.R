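#' Robust standard deviation of residuals (RSDR)
#'
#' Estimated from the 68.27th percentile of the absolute residuals, scaled by
#' `n / (n - k)` to correct for the fitted parameters. For a Gaussian sample
#' this converges to the standard deviation while being insensitive to
#' outliers.
#'
#' @param residuals Numeric vector of residuals.
#' @param k Number of fitted parameters (1 for a location model).
#' @return The robust scale estimate.
#' @export
rsdr <- function(residuals, k = 1) {
  n <- length(residuals)
  stopifnot(n > k)
  stats::quantile(abs(residuals), 0.6827, names = FALSE, type = 7) * n / (n - k)
}

# maximum-likelihood location under a Lorentzian (Cauchy-like) error model,
# initialized at the median, with the scale re-estimated from the residuals
robust_location <- function(x, max_iter = 50, tol = 1e-10) {
  m <- stats::median(x)
  s <- rsdr(x - m)
  if (s == 0) return(list(location = m, scale = 0))
  for (i in seq_len(max_iter)) {
    m_new <- stats::optimize(function(mm) sum(log1p(((x - mm) / s)^2)),
                             interval = range(x))$minimum
    s_new <- rsdr(x - m_new)
    done <- abs(m_new - m) < tol * max(1, abs(m))
    m <- m_new
    if (s_new == 0) return(list(location = m, scale = 0))
    s <- s_new
    if (done) break
  }
  list(location = m, scale = s)
}

#' Robust outlier identification (ROUT), location model
#'
#' Robust regression and outlier removal specialized to a constant (location)
#' model, for univariate per-group samples: the location is fitted by maximum
#' likelihood under a Lorentzian error model (initialized at the median), the
#' scale is the RSDR, each point receives a t-like statistic
#' `|x - location| / RSDR` with a two-tailed p-value on `n - 1` degrees of
#' freedom, and points are flagged by a false-discovery step at rate `Q`:
#' p-values are sorted ascending and the i-th is compared with `Q * i / n`,
#' scanning from the most extreme point and stopping at the first failure.
#'
#' @param x Numeric vector (length >= 3 for any removal).
#' @param Q ROUT coefficient, the maximum desired false discovery rate
#'   (default 0.001, i.e. Q = 0.1\%).
#' @return List with `cleaned` (values with outliers removed), `outliers`
#'   (sorted indices into `x`), `location` and `rsdr`.
#' @export
rout_outliers <- function(x, Q = 0.001) {
  stopifnot(is.numeric(x), Q > 0, Q < 1)
  n <- length(x)
  none <- list(cleaned = x, outliers = integer(0),
               location = stats::median(x), rsdr = NA_real_)
  if (n < 3) {
    warning("rout_outliers: n < 3, no removal performed")
    return(none)
  }
  fit <- robust_location(x)
  if (fit$scale == 0) {
    none$location <- fit$location
    none$rsdr <- 0
    return(none)
  }
  t_stat <- abs(x - fit$location) / fit$scale
  p <- 2 * stats::pt(-t_stat, df = n - 1)
  ord <- order(p, -t_stat)
  flagged <- integer(0)
  for (i in seq_len(n)) {
    if (p[ord[i]] < Q * i / n) flagged <- c(flagged, ord[i]) else break
  }
  flagged <- sort(flagged)
  list(cleaned = if (length(flagged)) x[-flagged] else x,
       outliers = flagged, location = fit$location, rsdr = fit$scale)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition with the p-value from the F
#' distribution. Degenerate inputs (zero within-group variance with equal
#' means) yield an undefined F, reported as `NA`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return List of class `mea_anova`: `F`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(lengths(groups) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- n - k
  msw <- ssw / df2
  if (msw == 0) {
    f <- if (ssb > 0) Inf else NA_real_
    p <- if (ssb > 0) 0 else NA_real_
  } else {
    f <- (ssb / df1) / msw
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = f, df_between = df1, df_within = df2, p = p),
            class = "mea_anova")
}

#' Caption-style ANOVA line
#'
#' Formats an [anova_oneway()] result the way figure captions print it, e.g.
#' `"F(2, 1447) = 6.965, p = 0.0010"`.
#'
#' @param a An `mea_anova` object.
#' @return Character scalar.
#' @export
format_anova_line <- function(a) {
  stopifnot(inherits(a, "mea_anova"))
  ptxt <- if (is.na(a$p)) "p undefined" else if (a$p < 1e-4) {
    "p < 0.0001"
  } else sprintf("p = %.4f", a$p)
  sprintf("F(%d, %d) = %s, %s", a$df_between, a$df_within,
          formatC(signif(a$F, 4), format = "fg"), ptxt)
}

#' @export
print.mea_anova <- function(x, ...) {
  cat(format_anova_line(x), "\n")
  invisible(x)
}

#' Significance stars
#'
#' @param p Numeric vector of p-values.
#' @return `"****"` for p < 0.0001, `"***"` for p < 0.001, `"**"` for
#'   p < 0.01, `"*"` for p < 0.05, `"ns"` otherwise.
#' @export
sig_stars <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p < 1e-4, "****",
                ifelse(p < 1e-3, "***",
                       ifelse(p < 0.01, "**",
                              ifelse(p < 0.05, "*", "ns")))))
}

#' Tukey's honestly-significant-difference post hoc test
#'
#' Studentized-range based pairwise comparisons following a one-way ANOVA,
#' with star labels at the 0.05/0.01/0.001/0.0001 thresholds. For two groups
#' the adjusted p equals the equal-variance two-sample t-test p.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @return Data frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `stars`.
#' @export
tukey_hsd <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups)),
                                  levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit)$group
  out <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], stars = sig_stars(tk[, "p adj"]),
                    row.names = NULL)
  out
}

#' Two-way analysis of variance
#'
#' Standard two-factor fixed-effects ANOVA with interaction (e.g. RGC
#' category by experiment phase), reported as a term table.
#'
#' @param values Numeric vector.
#' @param factor_a,factor_b Factors (coerced) of the same length as
#'   `values`.
#' @param names Labels for the two factors.
#' @return Data frame with `term`, `df`, `F`, `p`.
#' @export
anova_twoway <- function(values, factor_a, factor_b,
                         names = c("A", "B")) {
  df <- data.frame(v = values, A = factor(factor_a), B = factor(factor_b))
  fit <- stats::aov(v ~ A * B, data = df)
  s <- summary(fit)[[1]]
  rn <- trimws(rownames(s))
  terms <- ifelse(rn == "A", names[1],
                  ifelse(rn == "B", names[2],
                         ifelse(rn == "A:B", paste(names, collapse = ":"),
                                rn)))
  data.frame(term = terms, df = s$Df, F = s$`F value`, p = s$`Pr(>F)`,
             row.names = NULL)
}

#' Group summary with dual mean reporting
#'
#' Per-group: n, the all-data mean and SD (the convention used in running
#' text), the ROUT-cleaned mean (the convention used for plotted means), and
#' the outlier indices. `mean_all` always uses every value; removing flagged
#' outliers never changes it.
#'
#' @param values Numeric vector (NAs dropped).
#' @param Q ROUT coefficient.
#' @return List with `n`, `mean_all`, `sd_all`, `mean_cleaned`, `outliers`.
#' @export
group_stats <- function(values, Q = 0.001) {
  values <- values[is.finite(values)]
  if (!length(values)) {
    return(list(n = 0L, mean_all = NA_real_, sd_all = NA_real_,
                mean_cleaned = NA_real_, outliers = integer(0)))
  }
  r <- if (length(values) >= 3) rout_outliers(values, Q) else {
    list(cleaned = values, outliers = integer(0))
  }
  list(n = length(values), mean_all = mean(values),
       sd_all = stats::sd(values), mean_cleaned = mean(r$cleaned),
       outliers = r$outliers)
}
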