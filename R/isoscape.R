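#' Empirical semivariogram of point data
#'
#' Bins half the mean squared value difference of point pairs by great-circle
#' separation: `gamma(h) = 0.5 * mean((v_i - v_j)^2)` over pairs whose
#' distance falls in the bin. Bins with no pairs are omitted. Distances are
#' haversine kilometres on WGS84.
#'
#' @param lon,lat point coordinates (decimal degrees).
#' @param values values at the points.
#' @param n_bins number of distance bins (default 15).
#' @param max_dist maximum pair separation to use, km; default half the
#'   maximum pairwise distance.
#' @return data.frame of class `iso_variogram` with columns `dist` (bin
#'   mean separation, km), `gamma` (semivariance) and `n_pairs`.
#' @export
empirical_variogram <- function(lon, lat, values, n_bins = 15,
                                max_dist = NULL) {
  n <- length(values)
  stopifnot(length(lon) == n, length(lat) == n)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  d <- geosphere::distm(cbind(lon, lat)) / 1000
  if (max(d) == 0)
    stop("all points are coincident; variogram undefined", call. = FALSE)
  if (is.null(max_dist)) max_dist <- max(d) / 2
  iu <- which(upper.tri(d), arr.ind = TRUE)
  h <- d[iu]
  g <- 0.5 * (values[iu[, 1L]] - values[iu[, 2L]])^2
  keep <- h > 0 & h <= max_dist
  h <- h[keep]; g <- g[keep]
  if (!length(h))
    stop("no point pairs within max_dist", call. = FALSE)
  breaks <- seq(0, max_dist, length.out = n_bins + 1L)
  bin <- cut(h, breaks, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(split(seq_along(h), bin), function(i) {
    data.frame(dist = mean(h[i]), gamma = mean(g[i]), n_pairs = length(i))
  }))
  rownames(out) <- NULL
  class(out) <- c("iso_variogram", "data.frame")
  out
}

#' Variogram model constructor and semivariance evaluation
#'
#' Supported isotropic families (h in km, gamma(h) for h > 0, gamma(0) = 0):
#' \describe{
#'   \item{exponential}{`nugget + psill * (1 - exp(-h / range))`}
#'   \item{spherical}{`nugget + psill * (1.5 h/a - 0.5 (h/a)^3)` for `h < a`,
#'     sill beyond}
#'   \item{gaussian}{`nugget + psill * (1 - exp(-(h / range)^2))`}
#' }
#'
#' @param model_family one of `"exponential"`, `"spherical"`, `"gaussian"`.
#' @param nugget non-negative nugget variance.
#' @param psill non-negative partial sill.
#' @param range range parameter, km (> 0).
#' @return an object of class `variogram_model`.
#' @export
variogram_model <- function(model_family = c("exponential", "spherical",
                                             "gaussian"),
                            nugget, psill, range) {
  model_family <- match.arg(model_family)
  if (!is.finite(nugget) || nugget < 0) stop("nugget must be >= 0",
                                             call. = FALSE)
  if (!is.finite(psill) || psill < 0) stop("partial sill must be >= 0",
                                           call. = FALSE)
  if (!is.finite(range) || range <= 0) stop("range must be > 0",
                                            call. = FALSE)
  structure(list(model_family = model_family, nugget = nugget,
                 psill = psill, range = range),
            class = "variogram_model")
}

#' @rdname variogram_model
#' @param model a `variogram_model`.
#' @param h distances (km).
#' @export
semivariance <- function(model, h) {
  g <- with(model, switch(
    model_family,
    exponential = psill * (1 - exp(-h / range)),
    spherical = psill * ifelse(h < range,
                               1.5 * h / range - 0.5 * (h / range)^3, 1),
    gaussian = psill * (1 - exp(-(h / range)^2))))
  ifelse(h > 0, model$nugget + g, 0)
}

# covariance form used in the kriging system: C(h) = sill - gamma(h)
model_covariance <- function(model, h) {
  (model$nugget + model$psill) - semivariance(model, h)
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, partial sill %.4g, range %.4g km\n",
              x$model_family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted least squares on the binned semivariances with the customary
#' weights `n_pairs / h^2`, which emphasize short-range bins where the fit
#' matters most for kriging. The fit is profiled: for a fixed range the
#' model is linear in (nugget, partial sill), solved in closed form with
#' non-negativity clamping, and the range is found by a log-spaced grid
#' search refined by golden-section optimization. If no usable optimum is
#' found, a pure-nugget model at the weighted mean semivariance is returned
#' with a warning.
#'
#' @param empirical an `iso_variogram` from [empirical_variogram()].
#' @param model_family family to fit (default exponential).
#' @return a `variogram_model`.
#' @export
fit_variogram <- function(empirical,
                          model_family = c("exponential", "spherical",
                                           "gaussian")) {
  model_family <- match.arg(model_family)
  if (nrow(empirical) < 3L)
    stop("need at least 3 non-empty variogram bins", call. = FALSE)
  h <- empirical$dist; g <- empirical$gamma; w <- empirical$n_pairs / h^2

  shape <- function(range) {
    m <- list(model_family = model_family, nugget = 0, psill = 1,
              range = range)
    semivariance(m, h)
  }
  # closed-form WLS in (nugget, psill) at fixed range, clamped at zero
  profile_fit <- function(range) {
    s <- shape(range)
    X <- cbind(1, s)
    A <- crossprod(X * sqrt(w))
    b <- crossprod(X, w * g)
    par <- tryCatch(drop(solve(A, b)), error = function(e) c(NA, NA))
    if (any(!is.finite(par))) return(list(par = c(0, 0), sse = Inf))
    if (par[1L] < 0) {        # nugget clamped: refit psill alone
      par <- c(0, max(sum(w * s * g) / sum(w * s^2), 0))
    } else if (par[2L] < 0) { # psill clamped: pure nugget
      par <- c(sum(w * g) / sum(w), 0)
    }
    resid <- g - (par[1L] + par[2L] * s)
    list(par = par, sse = sum(w * resid^2))
  }

  ranges <- exp(seq(log(max(h) * 1e-3), log(max(h) * 10), length.out = 60))
  sses <- vapply(ranges, function(r) profile_fit(r)$sse, numeric(1))
  if (all(!is.finite(sses))) {
    warning("variogram fit failed; falling back to pure-nugget model",
            call. = FALSE)
    return(variogram_model(model_family, nugget = sum(w * g) / sum(w),
                           psill = 0, range = max(h)))
  }
  k <- which.min(sses)
  lo <- ranges[max(k - 1L, 1L)]; hi <- ranges[min(k + 1L, length(ranges))]
  opt <- stats::optimize(function(r) profile_fit(r)$sse, c(lo, hi),
                         tol = max(h) * 1e-7)
  best_r <- if (opt$objective <= sses[k]) opt$minimum else ranges[k]
  par <- profile_fit(best_r)$par
  variogram_model(model_family, nugget = par[1L], psill = par[2L],
                  range = best_r)
}

#' Ordinary kriging onto a raster grid
#'
#' Solves the ordinary-kriging system (best linear unbiased prediction with
#' weights constrained to sum to 1) for every valid cell of the target grid.
#' Observation coordinates are snapped to the centers of the grid cells that
#' contain them and duplicate cells are averaged first (with a message), so
#' with a zero-nugget model the predicted surface reproduces each
#' observation exactly at its cell. Distances are great-circle km; the
#' kriging system treats them as planar, which is adequate at continental
#' scale.
#'
#' When more than `max_neighbors` observations are supplied, each cell is
#' predicted from its nearest `max_neighbors` observations (local kriging);
#' otherwise one global system is factored and reused for all cells.
#'
#' @param lon,lat,values observations.
#' @param variogram a `variogram_model`.
#' @param grid an `iso_raster` providing the target geometry (its nodata
#'   pattern is preserved; values are ignored).
#' @param max_neighbors neighborhood cap (default 64).
#' @return list with elements `mean` and `variance`, both `iso_raster`s, and
#'   `weights_sum_check` (max abs deviation of weight sums from 1).
#' @export
krige_ordinary <- function(lon, lat, values, variogram, grid,
                           max_neighbors = 64L) {
  stopifnot(is_iso_raster(grid), inherits(variogram, "variogram_model"))
  n0 <- length(values)
  if (n0 < 2L) stop("need at least 2 observations", call. = FALSE)
  idx <- cell_index(grid, lon, lat)
  co <- raster_coords(grid)
  px <- co$lon[idx$cell]; py <- co$lat[idx$cell]
  # average duplicates that fall in the same cell
  if (anyDuplicated(idx$cell)) {
    agg <- tapply(values, idx$cell, mean)
    cells <- as.integer(names(agg))
    message(sprintf("averaged %d observation(s) sharing grid cells",
                    n0 - length(cells)))
    values <- as.numeric(agg)
    px <- co$lon[cells]; py <- co$lat[cells]
  }
  n <- length(values)
  if (n < 2L)
    stop("fewer than 2 distinct observation cells", call. = FALSE)

  # valid target cells in row-major order (matching raster_coords)
  tgt_cells <- which(t(is.finite(grid$values)))
  tgt <- co[tgt_cells, ]

  dobs <- geosphere::distm(cbind(px, py)) / 1000
  pred <- rep(NA_real_, nrow(tgt))
  pvar <- rep(NA_real_, nrow(tgt))
  wmax <- 0
  sill <- variogram$nugget + variogram$psill

  solve_block <- function(sub, dsub, c0mat) {
    # sub: indices of observations used; c0mat: n_sub x n_tgt covariances
    m <- length(sub)
    # semivariance is 0 at h = 0, so the diagonal carries the full sill
    A <- rbind(cbind(model_covariance(variogram, dsub), 1), c(rep(1, m), 0))
    rhs <- rbind(c0mat, 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      A[seq_len(m), seq_len(m)] <- A[seq_len(m), seq_len(m)] +
        diag(1e-8 * max(sill, 1), m)
      sol <- solve(A, rhs)
    }
    sol
  }

  if (n <= max_neighbors) {
    dt <- geosphere::distm(cbind(px, py), cbind(tgt$lon, tgt$lat)) / 1000
    c0 <- model_covariance(variogram, dt)
    c0[dt == 0] <- sill   # a target coincident with an observation cell
    sol <- solve_block(seq_len(n), dobs, c0)
    lambda <- sol[seq_len(n), , drop = FALSE]
    mu <- sol[n + 1L, ]
    pred <- colSums(lambda * values)
    pvar <- pmax(sill - colSums(lambda * c0) - mu, 0)
    wmax <- max(abs(colSums(lambda) - 1))
  } else {
    dt <- geosphere::distm(cbind(tgt$lon, tgt$lat), cbind(px, py)) / 1000
    for (j in seq_len(nrow(tgt))) {
      nb <- order(dt[j, ])[seq_len(max_neighbors)]
      c0 <- model_covariance(variogram, dt[j, nb])
      c0[dt[j, nb] == 0] <- sill
      sol <- solve_block(nb, dobs[nb, nb, drop = FALSE],
                         matrix(c0, ncol = 1L))
      lambda <- sol[seq_along(nb), 1L]
      pred[j] <- sum(lambda * values[nb])
      pvar[j] <- max(sill - sum(lambda * c0) - sol[length(nb) + 1L, 1L], 0)
      wmax <- max(wmax, abs(sum(lambda) - 1))
    }
  }

  mk <- function(vals) {
    m <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
    m[cbind(tgt$row, tgt$col)] <- vals
    out <- grid; out$values <- m; out
  }
  list(mean = mk(pred), variance = mk(pvar), weights_sum_check = wmax)
}

#' Build a tap-water isoscape by difference kriging
#'
#' Constructs a tap-water delta-18O surface from a base precipitation
#' isoscape and point tap-water observations: the tap-minus-base difference
#' at each observation site is interpolated over the grid by ordinary
#' kriging and added back to the base surface. Multiple observations at the
#' same site (grid cell) are averaged first. With a zero-nugget variogram
#' the output reproduces each site's tap value at that site's cell; away
#' from all sites the difference field relaxes toward its fitted mean, so
#' the output tracks the base surface plus a regional offset.
#'
#' @param base `iso_raster` of the base (precipitation) delta-18O surface.
#' @param tap_lon,tap_lat,tap_values tap-water observations (per mil).
#' @param variogram optional `variogram_model` for the difference field;
#'   fitted from the data (exponential family, [fit_variogram()] defaults)
#'   when `NULL`.
#' @param n_bins,max_dist passed to [empirical_variogram()] when fitting.
#' @return list: `isoscape` (`iso_raster`), `uncertainty` (kriging standard
#'   deviation, `iso_raster`), `variogram` (the model used), `n_sites`.
#' @export
build_tapwater_isoscape <- function(base, tap_lon, tap_lat, tap_values,
                                    variogram = NULL, n_bins = 15,
                                    max_dist = NULL) {
  stopifnot(is_iso_raster(base))
  n <- length(tap_values)
  base_at <- extract_at(base, tap_lon, tap_lat)
  ok <- is.finite(base_at) & is.finite(tap_values)
  if (sum(ok) < 3L)
    stop(sprintf("need at least 3 usable tap points inside the base extent (have %d)",
                 sum(ok)), call. = FALSE)
  dlon <- tap_lon[ok]; dlat <- tap_lat[ok]
  diffs <- tap_values[ok] - base_at[ok]
  if (is.null(variogram)) {
    emp <- empirical_variogram(dlon, dlat, diffs, n_bins = n_bins,
                               max_dist = max_dist)
    variogram <- fit_variogram(emp, "exponential")
  }
  kr <- krige_ordinary(dlon, dlat, diffs, variogram, base)
  iso <- base + kr$mean
  unc <- kr$variance
  unc$values <- sqrt(unc$values)
  list(isoscape = iso, uncertainty = unc, variogram = variogram,
       n_sites = sum(ok))
}
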