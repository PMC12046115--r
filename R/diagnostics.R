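#' Summarize calibration residuals by group
#'
#' Residuals — observed minus regression-predicted tissue values — carry the
#' signal of any systematic, non-geographic structure in a compilation: a
#' subset measured with different laboratory protocols shows up as an offset
#' in its mean residual, and a subset with poorer origin information as
#' inflated residual spread. This tabulates per-group residual count, mean
#' and standard deviation, ordered by group id.
#'
#' @param fit a `calibration_fit`.
#' @param grouping either the name of a column in `fit$data` (e.g.
#'   `"study_id"`, `"tooth_group"`, `"origin_status"`) or a vector with one
#'   group label per fitted record.
#' @return data.frame with columns `group_id`, `n`, `mean_residual`,
#'   `sd_residual`.
#' @export
summarize_residuals <- function(fit, grouping) {
  g <- resolve_grouping(fit, grouping)
  res <- fit$residuals
  out <- do.call(rbind, lapply(split(seq_along(res), g), function(i) {
    data.frame(group_id = g[i[1L]], n = length(i),
               mean_residual = mean(res[i]),
               sd_residual = if (length(i) > 1L) stats::sd(res[i]) else 0)
  }))
  out <- out[order(out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_grouping <- function(fit, grouping) {
  g <- if (is.character(grouping) && length(grouping) == 1L &&
           grouping %in% names(fit$data)) fit$data[[grouping]]
  else grouping
  if (length(g) != length(fit$residuals))
    stop("grouping must map every fitted record to exactly one group",
         call. = FALSE)
  if (length(g) == 0L || all(is.na(g)))
    stop("empty grouping", call. = FALSE)
  as.character(g)
}

#' Levene / Brown-Forsythe test for equal group variances
#'
#' Tests homogeneity of residual dispersion across groups using Levene's
#' statistic on absolute deviations from the group center. The default
#' center is the group median (the Brown-Forsythe variant, robust to
#' non-normality); mean centering is available. Delegates to
#' [car::leveneTest()].
#'
#' @param values numeric vector (typically residuals).
#' @param groups group labels, same length.
#' @param center `"median"` (default) or `"mean"`.
#' @return list: `statistic` (F), `df1`, `df2`, `p_value`, `center`.
#' @export
test_equal_variances <- function(values, groups,
                                 center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- as.factor(as.character(groups))
  check_two_groups(values, groups)
  centers <- tapply(values, groups,
                    if (center == "median") stats::median else mean)
  z <- abs(values - centers[groups])
  if (all(z == 0))
    stop("all groups have zero spread; variance test degenerate",
         call. = FALSE)
  zbar <- tapply(z, groups, mean)
  k <- nlevels(groups); n <- length(values)
  if (sum((z - zbar[groups])^2) == 0)
    # deviations constant within every group but not between: F diverges
    return(list(statistic = Inf, df1 = k - 1L, df2 = n - k, p_value = 0,
                center = center))
  lt <- car::leveneTest(values ~ groups,
                        center = if (center == "median") stats::median
                                 else mean)
  list(statistic = lt[1L, "F value"], df1 = lt[1L, "Df"],
       df2 = lt[2L, "Df"], p_value = lt[1L, "Pr(>F)"], center = center)
}

#' One-way ANOVA for equal group means
#'
#' Fixed-effects one-way analysis of variance, `F = MSB/MSW` on
#' `(k - 1, n - k)` degrees of freedom. If every group has zero internal
#' variance but the means differ, the statistic is reported as `Inf` with
#' `p = 0`.
#'
#' @inheritParams test_equal_variances
#' @return list: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
test_equal_means <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  check_two_groups(values, groups)
  k <- nlevels(groups); n <- length(values)
  if (n <= k + 1L)
    stop("too few records for ANOVA (need n > k + 1)", call. = FALSE)
  gm <- tapply(values, groups, mean)
  ssw <- sum((values - gm[groups])^2)
  if (ssw == 0) {
    if (stats::var(as.numeric(gm)) > 0)
      return(list(statistic = Inf, df1 = k - 1L, df2 = n - k, p_value = 0))
    return(list(statistic = 0, df1 = k - 1L, df2 = n - k, p_value = 1))
  }
  a <- stats::anova(stats::lm(values ~ groups))
  list(statistic = a[1L, "F value"], df1 = a[1L, "Df"], df2 = a[2L, "Df"],
       p_value = a[1L, "Pr(>F)"])
}

check_two_groups <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have the same length", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least 2 groups with at least 2 records each",
         call. = FALSE)
  invisible(TRUE)
}

#' Shapiro-Wilk normality test
#'
#' Thin, contract-checked wrapper around [stats::shapiro.test()]; supported
#' for sample sizes 3 to 5000.
#'
#' @param values numeric sample.
#' @return list: `W`, `p_value`.
#' @export
test_normality <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk test supports 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant input; normality test degenerate", call. = FALSE)
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' Run the standard residual-bias hypothesis screen
#'
#' Convenience wrapper applying the three residual hypotheses to one fit:
#' (H1) residual dispersion differs between known- and assumed-origin
#' records (variance test over `origin_status`); (H2) mean residuals differ
#' between studies (ANOVA over `study_id`); (H3) mean residuals differ
#' between tooth mineralization-age groups (ANOVA over `tooth_group`,
#' excluding the heterogeneous `"Unknown"` group by default).
#'
#' @param fit a `calibration_fit` whose `data` carries `origin_status`,
#'   `study_id` and (for tooth tissues) `tooth_group`.
#' @param include_unknown_teeth include `"Unknown"` tooth records in H3?
#' @return named list of test results (`NULL` where a grouping is absent or
#'   degenerate), each with its group summary attached as `"summary"`.
#' @export
residual_hypothesis_screen <- function(fit, include_unknown_teeth = FALSE) {
  res <- fit$residuals
  d <- fit$data
  run <- function(groups, test) {
    keep <- !is.na(groups)
    g <- groups[keep]
    if (length(unique(g)) < 2L || any(table(g) < 2L)) return(NULL)
    out <- test(res[keep], g)
    attr(out, "summary") <- summarize_residuals(fit, groups)
    out
  }
  h3_groups <- if ("tooth_group" %in% names(d)) {
    g <- d$tooth_group
    g[g %in% c("not_tooth", if (!include_unknown_teeth) "Unknown")] <- NA
    g
  } else NULL
  list(
    origin_status_variance =
      if ("origin_status" %in% names(d))
        run(d$origin_status, test_equal_variances) else NULL,
    study_means =
      if ("study_id" %in% names(d)) run(d$study_id, test_equal_means)
      else NULL,
    tooth_group_means =
      if (!is.null(h3_groups)) run(h3_groups, test_equal_means) else NULL)
}
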