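#' Calibrate a tissue-environment regression
#'
#' Fits the weighted least squares regression `y = alpha + beta * e + r`
#' relating tissue isotope values to environmental isoscape values extracted
#' at each record's origin coordinate — the workhorse behind tissue-isoscape
#' construction and all residual diagnostics. Records falling on nodata
#' cells (or outside the raster) are excluded and counted.
#'
#' Two weighting policies are available. `"site_density"` (default) gives
#' each record weight `1 / n_site`, the inverse of the number of records
#' sharing its site, so densely sampled sites do not dominate the fit;
#' `"unit"` is ordinary least squares.
#'
#' @param dataset an `iso_dataset` (or data.frame with `longitude`,
#'   `latitude`, `value` and, for site weighting, `site_id`).
#' @param env an `iso_raster` of environmental values.
#' @param weighting `"site_density"` or `"unit"`.
#' @return object of class `calibration_fit`: `slope`, `intercept`,
#'   `r_squared` (weighted), `rse` (sqrt of weighted SSE over `dof`),
#'   `residuals`, `weights`, `n`, `dof`, `n_excluded`, and `data` (the
#'   per-record table of env value `e`, tissue value `y` and metadata used).
#' @examples
#' env <- iso_raster(matrix(seq(0, 5, length.out = 20), 4, 5),
#'                   xmin = -110, ymax = 44, dx = 1)
#' d <- data.frame(longitude = runif(30, -110, -105),
#'                 latitude = runif(30, 40, 44))
#' d$value <- 2 + 0.5 * extract_at(env, d$longitude, d$latitude) +
#'   rnorm(30, 0, 0.1)
#' calibrate(d, env, weighting = "unit")
#' @export
calibrate <- function(dataset, env,
                      weighting = c("site_density", "unit")) {
  weighting <- match.arg(weighting)
  stopifnot(is_iso_raster(env))
  e <- extract_at(env, dataset$longitude, dataset$latitude, outside = "na")
  ok <- is.finite(e) & is.finite(dataset$value)
  n <- sum(ok)
  if (n < 3L)
    stop(sprintf("need at least 3 records with environmental values (have %d)",
                 n), call. = FALSE)
  d <- dataset[ok, , drop = FALSE]
  e <- e[ok]
  y <- d$value
  if (stats::var(e) == 0)
    stop("environmental values have zero variance; slope unidentifiable",
         call. = FALSE)
  w <- if (weighting == "site_density") {
    site <- if ("site_id" %in% names(d)) d$site_id else
      sprintf("%.6f_%.6f", d$longitude, d$latitude)
    1 / as.numeric(table(site)[site])
  } else rep(1, n)

  fit <- stats::lm(y ~ e, weights = w)
  res <- stats::residuals(fit)
  sse <- sum(w * res^2)
  sst <- sum(w * (y - stats::weighted.mean(y, w))^2)
  dof <- n - 2L
  out <- list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = 1 - sse / sst,
    rse = sqrt(sse / dof),
    residuals = unname(res),
    weights = w,
    n = n, dof = dof, n_excluded = sum(!ok),
    weighting = weighting,
    data = cbind(d, data.frame(e = e, residual = unname(res), weight = w)))
  class(out) <- "calibration_fit"
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> y = %.4g + %.4g * e  (n = %d, R2 = %.3f, RSE = %.3g)\n",
    x$intercept, x$slope, x$n, x$r_squared, x$rse))
  if (x$n_excluded > 0)
    cat(sprintf("  %d record(s) excluded (missing environmental value)\n",
                x$n_excluded))
  invisible(x)
}

#' Reduced major axis slope
#'
#' The RMA (standardized major axis) slope is the ratio of the standard
#' deviations of the response and predictor, signed by their correlation.
#' It is the appropriate line when the x variable carries error of similar
#' magnitude to y, and is always steeper in magnitude than the OLS slope.
#'
#' @param env_values predictor values.
#' @param tissue_values response values.
#' @return the RMA slope (dimensionless).
#' @export
rma_slope <- function(env_values, tissue_values) {
  if (length(env_values) < 2L || length(tissue_values) < 2L)
    stop("need at least 2 values in each variable", call. = FALSE)
  sx <- stats::sd(env_values); sy <- stats::sd(tissue_values)
  if (sx == 0 || sy == 0)
    stop("zero variance; RMA slope undefined", call. = FALSE)
  r <- stats::cor(env_values, tissue_values)
  sign_r <- if (r < 0) -1 else 1
  sign_r * sy / sx
}

#' Predict a tissue isoscape from a calibration fit
#'
#' Applies the fitted affine relationship cell-wise: `mean(x) = alpha +
#' beta * env(x)`. The per-cell prediction standard deviation is the fit's
#' residual standard error, spatially constant (no per-cell combination of
#' environmental-isoscape uncertainty is attempted; pass `extra_sd` to add
#' a component in quadrature). Nodata propagates.
#'
#' @param fit a `calibration_fit`.
#' @param env environmental `iso_raster`.
#' @param extra_sd optional additional standard deviation (scalar or
#'   `iso_raster`) combined in quadrature with the RSE.
#' @param min_sd numerical floor on the sd surface, keeping the posterior
#'   well-defined for (near-)perfect fits whose RSE is zero.
#' @return object of class `tissue_isoscape`: list of `mean` and `sd`
#'   rasters plus the `fit`.
#' @export
predict_tissue_isoscape <- function(fit, env, extra_sd = 0,
                                    min_sd = 1e-6) {
  stopifnot(inherits(fit, "calibration_fit"), is_iso_raster(env))
  if (!is.finite(fit$rse) || fit$rse < 0)
    stop("fit has no valid RSE; sd surface undefined", call. = FALSE)
  mean_r <- fit$intercept + fit$slope * env
  sd_r <- env
  extra <- if (is_iso_raster(extra_sd)) extra_sd$values else extra_sd
  sd_r$values <- pmax(sqrt(fit$rse^2 + extra^2), min_sd) +
    0 * env$values  # NA propagates
  structure(list(mean = mean_r, sd = sd_r, fit = fit),
            class = "tissue_isoscape")
}

#' @export
print.tissue_isoscape <- function(x, ...) {
  cat("<tissue_isoscape>\n mean surface: ")
  print(x$mean)
  ok <- is.finite(x$sd$values)
  cat(sprintf(" sd: %.3g to %.3g\n", min(x$sd$values[ok]),
              max(x$sd$values[ok])))
  invisible(x)
}
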