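test_that("ROUT flags gross contamination and spares clean data", {
  set.seed(40)
  x <- stats::rnorm(100)
  r <- rout_outliers(x, Q = 0.001)
  expect_lte(length(r$outliers), 1)

  # a single point 10 robust SDs out is always caught
  x2 <- c(x, r$location + 10 * stats::sd(x))
  r2 <- rout_outliers(x2, Q = 0.001)
  expect_true(101 %in% r2$outliers)
  # mean of all data is unaffected by flagging
  expect_equal(mean(x2), mean(c(r2$cleaned, x2[r2$outliers])))

  # degenerate input: zero scale, no outliers
  r3 <- rout_outliers(rep(2.5, 10))
  expect_length(r3$outliers, 0)
  expect_equal(r3$rsdr, 0)
  expect_warning(rout_outliers(c(1, 2)), "n < 3")

  # false-flag proportion on clean normal data stays at or below Q
  set.seed(41)
  flags <- vapply(1:150, function(i) {
    length(rout_outliers(stats::rnorm(100), Q = 0.001)$outliers)
  }, 0L)
  expect_lte(sum(flags) / (150 * 100), 0.001)
})

test_that("the RSDR estimates the SD of Gaussian residuals", {
  set.seed(42)
  x <- stats::rnorm(20000, sd = 3)
  expect_lt(abs(rsdr(x - mean(x)) - 3) / 3, 0.03)
  # insensitive to a contaminated tail
  x[1:200] <- 100
  expect_lt(abs(rsdr(x - stats::median(x)) - 3) / 3, 0.06)
})

test_that("one-way ANOVA matches hand computation and the stats oracle", {
  a <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  # SSB = 13.5 on 1 df, MSW = 1 on 4 df
  expect_equal(a$F, 13.5)
  expect_equal(c(a$df_between, a$df_within), c(1, 4))
  ow <- stats::oneway.test(v ~ g, data.frame(v = c(1:3, 4:6),
                                             g = rep(c("a", "b"), each = 3)),
                           var.equal = TRUE)
  expect_equal(a$F, unname(ow$statistic))
  expect_equal(a$p, unname(ow$p.value))

  # identical groups: F = 0, p = 1
  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  # shift invariance and group-order invariance
  set.seed(43)
  g <- list(rnorm(10), rnorm(12, 1), rnorm(9, 2))
  expect_equal(anova_oneway(g)$F, anova_oneway(lapply(g, `+`, 100))$F)
  expect_equal(anova_oneway(g)$F, anova_oneway(rev(g))$F)
  # random-data agreement with the built-in oracle
  ow2 <- stats::oneway.test(v ~ gr,
                            data.frame(v = unlist(g),
                                       gr = rep(letters[1:3], lengths(g))),
                            var.equal = TRUE)
  expect_equal(anova_oneway(g)$F, unname(ow2$statistic))

  # degenerate: zero within-group variance
  expect_true(is.na(anova_oneway(list(c(1, 1), c(1, 1)))$F))
  expect_equal(anova_oneway(list(c(1, 1), c(2, 2)))$p, 0)
  expect_error(anova_oneway(list(1, c(1, 2))), "at least 2")
})

test_that("Tukey's test reduces to the t-test for two groups", {
  set.seed(44)
  g <- list(a = rnorm(15), b = rnorm(15, 0.8))
  tk <- tukey_hsd(g)
  tt <- stats::t.test(g$b, g$a, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)

  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$p_adj, 1)
  expect_equal(same$stars, "ns")

  expect_equal(sig_stars(c(0.2, 0.03, 0.004, 8e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("the caption formatter prints F and p in figure style", {
  a <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(format_anova_line(a), "F(1, 4) = 13.5, p = 0.0213")
  tiny <- structure(list(F = 20.54, df_between = 4, df_within = 2467,
                         p = 2e-6), class = "mea_anova")
  expect_equal(format_anova_line(tiny), "F(4, 2467) = 20.54, p < 0.0001")
})

test_that("two-way ANOVA reports the expected terms", {
  set.seed(45)
  d <- expand.grid(cat = c("ON", "ON_OFF", "OFF"),
                   phase = c("pre", "pressure", "post"), rep = 1:6)
  d$v <- rnorm(nrow(d)) + as.integer(d$phase)
  tw <- anova_twoway(d$v, d$cat, d$phase, names = c("category", "phase"))
  expect_equal(tw$term[1:3], c("category", "phase", "category:phase"))
  expect_equal(tw$df[1:3], c(2, 2, 4))
  expect_lt(tw$p[tw$term == "phase"], 0.001)
})

test_that("group summaries keep the all-data mean untouched by ROUT", {
  set.seed(46)
  vals <- c(rnorm(60, 10, 2), 60) # one far outlier
  gs <- group_stats(vals, Q = 0.001)
  expect_equal(gs$mean_all, mean(vals))
  expect_equal(gs$n, 61L)
  expect_true(61 %in% gs$outliers)
  expect_lt(gs$mean_cleaned, gs$mean_all)
})
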