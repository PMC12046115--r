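fit_with_residuals <- function(res, extra = NULL) {
  # wrap a residual vector in a minimal calibration_fit for grouping APIs
  d <- data.frame(residual = res)
  if (!is.null(extra)) d <- cbind(d, extra)
  structure(list(residuals = res, weights = rep(1, length(res)),
                 n = length(res), data = d),
            class = "calibration_fit")
}

test_that("per-group residual summaries match direct computation", {
  f <- fit_with_residuals(c(1, 1, -1, -1))
  s <- summarize_residuals(f, c("A", "A", "B", "B"))
  expect_equal(s$group_id, c("A", "B"))
  expect_equal(s$mean_residual, c(1, -1))
  expect_equal(s$sd_residual, c(0, 0))

  # single group: mean equals the overall residual mean
  s1 <- summarize_residuals(f, rep("all", 4))
  expect_equal(s1$mean_residual, mean(f$residuals))

  # two-pass variance oracle on simulated groups
  set.seed(5)
  res <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  s3 <- summarize_residuals(fit_with_residuals(res), g)
  for (grp in c("a", "b", "c")) {
    x <- res[g == grp]
    m <- sum(x) / length(x)
    expect_equal(s3$sd_residual[s3$group_id == grp],
                 sqrt(sum((x - m)^2) / (length(x) - 1)))
  }
  expect_error(summarize_residuals(f, character(0)), "exactly one group")
})

test_that("group means of an intercept-fitted model sum to zero overall", {
  env <- iso_raster(matrix(seq(0, 9), nrow = 1), xmin = 0, ymax = 40.5,
                    dx = 1)
  d <- toy_records(env, n = 40, slope = 0.5, intercept = 2, noise_sd = 1,
                   seed = 2)
  f <- calibrate(d, env, weighting = "unit")
  s <- summarize_residuals(f, rep(c("g1", "g2", "g3", "g4"), 10))
  expect_lt(abs(sum(s$n * s$mean_residual)), 1e-8)
})

test_that("Levene statistic agrees with its defining formula", {
  # identical multisets in both groups: statistic 0, p = 1
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("x", "y"), each = 4)
  t0 <- test_equal_variances(v, g)
  expect_equal(t0$statistic, 0, tolerance = 1e-12)
  expect_equal(t0$p_value, 1, tolerance = 1e-12)

  # hand evaluation, median-centered: groups {0,0,0,0} and {-3,3,-3,3}
  v2 <- c(0, 0, 0, 0, -3, 3, -3, 3)
  g2 <- rep(c("x", "y"), each = 4)
  z <- abs(v2 - ave(v2, g2, FUN = median))      # 0,0,0,0, 3,3,3,3
  zbar <- ave(z, g2); ztot <- mean(z)
  ssb <- sum((zbar - ztot)^2); ssw <- sum((z - zbar)^2)
  # ssw = 0 here: deviations are constant within groups -> F infinite
  expect_equal(ssw, 0)
  t2 <- test_equal_variances(v2, g2)
  expect_true(!is.finite(t2$statistic) || t2$statistic > 1e10)
  expect_equal(t2$df1, 1L)
  expect_equal(t2$df2, 6L)

  # a non-degenerate hand case cross-checked against the formula
  v3 <- c(0, 1, 0, 1, -3, 3, -2, 4)
  g3 <- rep(c("x", "y"), each = 4)
  z3 <- abs(v3 - ave(v3, g3, FUN = median))
  k <- 2; n <- 8
  zb <- tapply(z3, g3, mean); zt <- mean(z3)
  Fhand <- ((n - k) / (k - 1)) * sum(table(g3) * (zb - zt)^2) /
    sum((z3 - ave(z3, g3))^2)
  t3 <- test_equal_variances(v3, g3)
  expect_equal(t3$statistic, unname(Fhand), tolerance = 1e-10)

  expect_error(test_equal_variances(c(1, 1, 2, 2), c("x", "x", "y", "y")),
               "zero spread")
})

test_that("Levene test holds its nominal type-I error rate", {
  set.seed(123)
  reps <- 1000
  rejections <- vapply(seq_len(reps), function(i) {
    v <- rnorm(40)
    g <- rep(c("a", "b"), each = 20)
    test_equal_variances(v, g)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # groups {0,2} and {1,3}: SSB = 1, MSW = 2 -> F = 0.5 on (1, 2) df
  t1 <- test_equal_means(c(0, 2, 1, 3), c("a", "a", "b", "b"))
  expect_equal(t1$statistic, 0.5, tolerance = 1e-12)
  expect_equal(t1$df1, 1L)
  expect_equal(t1$df2, 2L)

  # identical group distributions: between-group F near zero
  t2 <- test_equal_means(c(0, 2, 4, 0, 2, 4), rep(c("a", "b"), each = 3))
  expect_equal(t2$statistic, 0, tolerance = 1e-12)

  # shifting one group strictly increases F
  v <- c(rnorm(10, 0), rnorm(10, 0.5))
  g <- rep(c("a", "b"), each = 10)
  f_before <- test_equal_means(v, g)$statistic
  v[g == "b"] <- v[g == "b"] + 10
  expect_gt(test_equal_means(v, g)$statistic, f_before)

  # zero within-group variance with unequal means: infinite-F sentinel
  t3 <- test_equal_means(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
  expect_identical(t3$statistic, Inf)
  expect_identical(t3$p_value, 0)
})

test_that("Shapiro-Wilk wrapper enforces its size contract", {
  expect_gt(test_normality(qnorm(ppoints(20)))$W, 0.99)
  bimodal <- c(rep(0, 25), rep(10, 25))
  expect_lt(test_normality(bimodal)$p_value, 0.01)
  expect_error(test_normality(rep(3, 10)), "constant")
  expect_error(test_normality(c(1, 2)), "3 <= n <= 5000")
  expect_error(test_normality(rnorm(5001)), "3 <= n <= 5000")
})

test_that("the three residual hypotheses run as one screen", {
  sc <- synthetic_scenario(
    seed = 19, n_sites = 60, n_per_site = 3, noise_sd = 1,
    study_biases = c(S1 = 1, S2 = 0), assumed_fraction = 0.4,
    tissue = "tooth_enamel", intercept = 29.4, slope = 0.43,
    tooth_offsets = c(G0_4 = 0.8, G2p5_7 = 0, G7p5_15 = -0.8))
  d <- synth_dataset(sc)
  f <- calibrate(d, synth_raster(sc))
  scr <- residual_hypothesis_screen(f)
  expect_named(scr, c("origin_status_variance", "study_means",
                      "tooth_group_means"))
  expect_true(all(!vapply(scr, is.null, logical(1))))
  # injected study offset and tooth offsets are detected
  expect_lt(scr$study_means$p_value, 0.05)
  expect_lt(scr$tooth_group_means$p_value, 0.05)
  expect_s3_class(attr(scr$study_means, "summary"), "data.frame")
})
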