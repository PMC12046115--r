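#' Posterior probability surface for one sample
#'
#' Computes the continuous-surface geographic assignment for a single tissue
#' measurement: per cell, the normal density of the observed value given the
#' tissue isoscape's cell mean and standard deviation, normalized so the
#' area-weighted sum over valid cells equals 1 (cell areas from
#' [cell_area_weights()]). Cells with nodata in either isoscape band are
#' excluded.
#'
#' @param obs observed tissue value (per mil or ratio).
#' @param iso a `tissue_isoscape` (or list with `mean` and `sd`
#'   `iso_raster`s).
#' @param sample_id identifier carried on the result.
#' @return object of class `posterior_surface`: `probs` (`iso_raster` of
#'   posterior densities), `area_weights` (matrix), `sample_id`.
#' @export
posterior_surface <- function(obs, iso, sample_id = "sample") {
  if (!is.finite(obs)) stop("observed value must be finite", call. = FALSE)
  mu <- iso$mean$values; sdv <- iso$sd$values
  ok <- is.finite(mu) & is.finite(sdv)
  if (any(sdv[ok] <= 0))
    stop("isoscape sd must be positive on valid cells", call. = FALSE)
  probs <- iso$mean
  probs$values[] <- NA_real_
  tmpl <- probs
  tmpl$values[ok] <- 1  # valid-cell mask for area weighting
  aw <- cell_area_weights(tmpl)
  f <- matrix(NA_real_, nrow(mu), ncol(mu))
  f[ok] <- stats::dnorm(obs, mu[ok], sdv[ok])
  tot <- sum(f * aw, na.rm = TRUE)
  if (tot <= 0)
    stop("posterior degenerate: zero total density", call. = FALSE)
  probs$values <- f / tot
  structure(list(probs = probs, area_weights = aw, sample_id = sample_id),
            class = "posterior_surface")
}

#' Highest-posterior assignment region for an area quantile
#'
#' Sorts valid cells by posterior density (descending; ties broken by
#' row-major cell index) and takes the smallest prefix whose cumulative
#' cell-area weight reaches `q`. This is the "most likely fraction q of the
#' study area" used in assignment quality metrics.
#'
#' @param post a `posterior_surface`.
#' @param q area fraction in (0, 1].
#' @return logical `iso_raster` (`TRUE` inside the region, `NA` at nodata).
#' @export
assignment_region <- function(post, q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1)
    stop("q must be a single value in (0, 1]", call. = FALSE)
  p <- post$probs$values
  aw <- post$area_weights
  # row-major cell order for deterministic tie-breaking
  nr <- nrow(p); nc <- ncol(p)
  cellord <- as.vector(t(matrix(seq_along(p), nr, nc)))  # row-major walk
  pv <- as.vector(t(p)); av <- as.vector(t(aw))
  valid <- which(is.finite(pv))
  o <- valid[order(-pv[valid])]          # stable: ties keep row-major order
  cum <- cumsum(av[o])
  k <- which(cum >= q - 1e-12)[1L]
  if (is.na(k)) k <- length(o)
  sel_cells <- cellord[o[seq_len(k)]]
  out <- post$probs
  out$values[] <- NA
  out$values[cellord[valid]] <- FALSE
  out$values[sel_cells] <- TRUE
  out$values <- out$values == 1
  out
}

# per-sample minimal area quantile at which the origin cell enters the
# assignment region; accuracy(q) is then mean(q* <= q)
origin_area_quantile <- function(post, lon, lat) {
  idx <- cell_index(post$probs, lon, lat, outside = "na")
  if (is.na(idx$row[1L])) return(NA_real_)
  p0 <- post$probs$values[idx$row[1L], idx$col[1L]]
  if (!is.finite(p0)) return(NA_real_)
  pv <- post$probs$values
  aw <- post$area_weights
  ok <- is.finite(pv)
  # area of all cells with strictly higher density, plus tied cells up to
  # and including the origin cell in row-major order
  higher <- sum(aw[ok & pv > p0])
  tv <- as.vector(t(pv)); ta <- as.vector(t(aw))
  tie <- which(is.finite(tv) & tv == p0)
  orig_rm <- (idx$row[1L] - 1L) * ncol(pv) + idx$col[1L]
  tied_before <- tie[tie <= orig_rm]
  higher + sum(ta[tied_before])
}

#' Iterated split-sample assignment quality assessment
#'
#' Quantifies how well a compilation supports geographic assignment. Per
#' iteration: records are randomly split into calibration and validation
#' sets; the calibration set fits the tissue-environment regression and
#' yields a tissue isoscape; each validation sample's posterior surface is
#' computed, and for every area quantile `q` the sample counts as correctly
#' assigned if the cell containing its reported origin lies inside the
#' most-likely-`q`-area region. Accuracy is averaged over samples and
#' iterations. Fully reproducible given `seed`.
#'
#' @param dataset an `iso_dataset` (or data.frame with `longitude`,
#'   `latitude`, `value`).
#' @param env environmental `iso_raster`.
#' @param n_iterations number of random splits (default 10).
#' @param validation_fraction fraction of records held out per split
#'   (default 0.25).
#' @param q_grid area quantiles evaluated (default 0.01 to 1 step 0.01).
#' @param weighting calibration weighting policy (see [calibrate()]).
#' @param split `"record"` (default) or `"site"` — site-level splitting
#'   keeps all records of a site together, testing spatial leakage.
#' @param seed integer seed.
#' @return object of class `qa_result`: `area_quantiles`, `accuracy`,
#'   `n_iterations`, `n_validation` (total validation samples scored),
#'   `seed`, `config`.
#' @export
qa <- function(dataset, env, n_iterations = 10, validation_fraction = 0.25,
               q_grid = seq(0.01, 1, by = 0.01),
               weighting = c("site_density", "unit"),
               split = c("record", "site"), seed = 1L) {
  weighting <- match.arg(weighting)
  split <- match.arg(split)
  stopifnot(all(q_grid > 0), all(q_grid <= 1), !is.unsorted(q_grid))
  n <- nrow(dataset)
  if (n < 8L) stop("dataset too small for split-sample QA", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  qstar_all <- numeric(0)
  n_skipped <- 0L
  for (it in seq_len(n_iterations)) {
    if (split == "record") {
      n_val <- max(1L, round(validation_fraction * n))
      val_idx <- sample.int(n, n_val)
    } else {
      sites <- unique(dataset$site_id)
      val_sites <- sample(sites, max(1L, round(validation_fraction *
                                                 length(sites))))
      val_idx <- which(dataset$site_id %in% val_sites)
    }
    cal <- dataset[-val_idx, , drop = FALSE]
    val <- dataset[val_idx, , drop = FALSE]
    fit <- tryCatch(calibrate(cal, env, weighting = weighting),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$rse)) {
      warning(sprintf("iteration %d skipped: calibration failed", it),
              call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    iso <- predict_tissue_isoscape(fit, env)
    qstar <- vapply(seq_len(nrow(val)), function(i) {
      post <- posterior_surface(val$value[i], iso)
      origin_area_quantile(post, val$longitude[i], val$latitude[i])
    }, numeric(1))
    qstar_all <- c(qstar_all, qstar[is.finite(qstar)])
  }
  if (n_skipped == n_iterations)
    stop("all QA iterations skipped; dataset cannot be calibrated",
         call. = FALSE)
  acc <- vapply(q_grid, function(q) mean(qstar_all <= q + 1e-12),
                numeric(1))
  structure(list(area_quantiles = q_grid, accuracy = acc,
                 n_iterations = n_iterations - n_skipped,
                 n_validation = length(qstar_all), seed = seed,
                 config = list(validation_fraction = validation_fraction,
                               weighting = weighting, split = split)),
            class = "qa_result")
}

#' @export
print.qa_result <- function(x, ...) {
  cat(sprintf(
    "<qa_result> %d iterations, %d validation samples (seed %d)\n",
    x$n_iterations, x$n_validation, x$seed))
  for (q in c(0.1, 0.25, 0.5)) {
    i <- which.min(abs(x$area_quantiles - q))
    cat(sprintf("  accuracy at %d%% area: %.1f%%\n",
                round(100 * x$area_quantiles[i]), 100 * x$accuracy[i]))
  }
  invisible(x)
}

#' Compare two QA accuracy curves
#'
#' Per-quantile accuracy difference `corrected - uncorrected`, the standard
#' readout for whether a bias correction improved geographic specificity.
#'
#' @param uncorrected,corrected `qa_result`s on identical `q` grids.
#' @return list: `table` (data.frame `q`, `uncorrected`, `corrected`,
#'   `delta`) and `mean_delta`.
#' @export
compare_qa <- function(uncorrected, corrected) {
  if (!isTRUE(all.equal(uncorrected$area_quantiles,
                        corrected$area_quantiles)))
    stop("QA results have mismatched area-quantile grids", call. = FALSE)
  tab <- data.frame(q = uncorrected$area_quantiles,
                    uncorrected = uncorrected$accuracy,
                    corrected = corrected$accuracy,
                    delta = corrected$accuracy - uncorrected$accuracy)
  list(table = tab, mean_delta = mean(tab$delta))
}

#' Serialize a QA result to JSON
#'
#' @param x a `qa_result`.
#' @param path output path.
#' @export
write_qa_json <- function(x, path) {
  jsonlite::write_json(
    list(area_quantiles = x$area_quantiles, accuracy = x$accuracy,
         n_iterations = x$n_iterations, n_validation = x$n_validation,
         seed = x$seed, config = x$config),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
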