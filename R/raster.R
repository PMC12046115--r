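#' Georeferenced raster of isotope values
#'
#' Lightweight single-band raster container used as the currency of all
#' isoscapes and probability surfaces in this package. Values are stored as a
#' numeric matrix whose first row is the northernmost row; the grid is
#' regular in WGS84 longitude/latitude. Missing (nodata) cells are held as
#' `NA` and are excluded from every statistic and from posterior
#' normalization.
#'
#' Cells are half-open: a cell with west edge `x` and north edge `y` covers
#' `[x, x + dx) x (y - dy, y]`-style index arithmetic, implemented as
#' `col = floor((lon - xmin)/dx) + 1`, `row = floor((ymax - lat)/dy) + 1`,
#' with points exactly on the northern/western raster edge assigned to the
#' first row/column. Point extraction returns the containing cell's value
#' (no interpolation), matching common GIS raster-extraction semantics.
#'
#' @param values numeric matrix (rows = north to south, cols = west to east).
#'   `NA` entries are nodata.
#' @param xmin western edge of the grid (decimal degrees).
#' @param ymax northern edge of the grid (decimal degrees).
#' @param dx,dy cell size in degrees (dy defaults to dx).
#' @param nodata sentinel written to disk for `NA` cells.
#' @param crs_note free-text CRS annotation.
#' @return an object of class `iso_raster`.
#' @examples
#' r <- iso_raster(matrix(1:12, 3, 4), xmin = -120, ymax = 45, dx = 1)
#' extract_at(r, lon = -119.5, lat = 44.5)
#' @export
iso_raster <- function(values, xmin, ymax, dx, dy = dx,
                       nodata = -9999, crs_note = "WGS84 lon/lat") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must be at least 1x1", call. = FALSE)
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0)
    stop("cell sizes must be positive and finite", call. = FALSE)
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         dx = as.numeric(dx), dy = as.numeric(dy),
         nodata = as.numeric(nodata), crs_note = as.character(crs_note)),
    class = "iso_raster")
}

#' @export
print.iso_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<iso_raster> %d rows x %d cols, cell %g x %g deg\n",
              nrow(v), ncol(v), x$dx, x$dy))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g] (%s)\n",
              x$xmin, x$xmin + ncol(v) * x$dx,
              x$ymax - nrow(v) * x$dy, x$ymax, x$crs_note))
  ok <- is.finite(v)
  if (any(ok))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d nodata cells)\n",
                min(v[ok]), mean(v[ok]), max(v[ok]), sum(!ok)))
  else cat("  values: all nodata\n")
  invisible(x)
}

#' @export
dim.iso_raster <- function(x) dim(x$values)

#' @rdname iso_raster
#' @param x object to test.
#' @export
is_iso_raster <- function(x) inherits(x, "iso_raster")

raster_xmax <- function(r) r$xmin + ncol(r$values) * r$dx
raster_ymin <- function(r) r$ymax - nrow(r$values) * r$dy

#' Cell-center coordinates
#'
#' @param r an `iso_raster`.
#' @return `raster_coords()` returns a data.frame with one row per cell in
#'   row-major order (`cell`, `row`, `col`, `lon`, `lat`).
#' @export
raster_coords <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  data.frame(cell = seq_len(nr * nc), row = row, col = col,
             lon = r$xmin + (col - 0.5) * r$dx,
             lat = r$ymax - (row - 0.5) * r$dy)
}

#' Locate the cells containing points
#'
#' @param r an `iso_raster`.
#' @param lon,lat point coordinates (decimal degrees, recycled together).
#' @param outside `"error"` (default) to fail on out-of-extent points,
#'   `"na"` to return `NA` indices for them.
#' @return data.frame with `row`, `col` and the row-major `cell` index.
#' @export
cell_index <- function(r, lon, lat, outside = c("error", "na")) {
  outside <- match.arg(outside)
  n <- max(length(lon), length(lat))
  lon <- rep_len(as.numeric(lon), n); lat <- rep_len(as.numeric(lat), n)
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((lon - r$xmin) / r$dx) + 1L
  row <- floor((r$ymax - lat) / r$dy) + 1L
  # points exactly on the north / west raster edge belong to the first cell
  col[lon == r$xmin] <- 1L
  row[lat == r$ymax] <- 1L
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1L | col > nc | row < 1L | row > nr
  if (any(bad)) {
    if (outside == "error")
      stop(sprintf("point(s) outside raster extent: %s",
                   paste(sprintf("(%g, %g)", lon[bad], lat[bad]),
                         collapse = ", ")), call. = FALSE)
    row[bad] <- NA_integer_; col[bad] <- NA_integer_
  }
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((row - 1L) * nc + col))
}

#' Extract raster values at point locations
#'
#' Returns the value of the cell containing each point (cell value, not
#' bilinear interpolation). Nodata cells yield `NA`, flagging the value as
#' missing rather than returning the sentinel.
#'
#' @inheritParams cell_index
#' @return numeric vector of cell values (`NA` for nodata or, with
#'   `outside = "na"`, out-of-extent points).
#' @export
extract_at <- function(r, lon, lat, outside = c("error", "na")) {
  idx <- cell_index(r, lon, lat, outside = outside)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Normalized cell-area weights
#'
#' Longitude/latitude grids are not equal-area; cell area is proportional to
#' the cosine of the cell-center latitude. Weights are normalized to sum to 1
#' over valid (non-nodata) cells so that area-quantile statements ("the most
#' likely 10% of the land area") refer to true surface area.
#'
#' @param r an `iso_raster`.
#' @return matrix of weights matching `r$values`; `NA` at nodata cells.
#' @export
cell_area_weights <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  lat <- r$ymax - (seq_len(nr) - 0.5) * r$dy
  w <- matrix(rep(cos(lat * pi / 180), times = nc), nr, nc)
  w[!is.finite(r$values)] <- NA_real_
  tot <- sum(w, na.rm = TRUE)
  if (tot <= 0) stop("raster has no valid cells", call. = FALSE)
  w / tot
}

# elementwise arithmetic between rasters (aligned grids) or raster/scalar
#' @export
Ops.iso_raster <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/"))
    stop(sprintf("operation '%s' not defined for iso_raster", .Generic),
         call. = FALSE)
  if (is_iso_raster(e1) && is_iso_raster(e2)) {
    if (!isTRUE(all.equal(dim(e1$values), dim(e2$values))) ||
        !isTRUE(all.equal(c(e1$xmin, e1$ymax, e1$dx, e1$dy),
                          c(e2$xmin, e2$ymax, e2$dx, e2$dy))))
      stop("rasters are not on the same grid", call. = FALSE)
    out <- e1
    out$values <- get(.Generic)(e1$values, e2$values)
  } else if (is_iso_raster(e1)) {
    out <- e1
    out$values <- get(.Generic)(e1$values, e2)
  } else {
    out <- e2
    out$values <- get(.Generic)(e1, e2$values)
  }
  out
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south). The
#' format requires square cells; `write_ascii_grid()` refuses rasters with
#' `dx != dy`. The nodata tag is respected in both directions.
#'
#' @param path file path.
#' @return `read_ascii_grid()` returns an `iso_raster`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body does not match declared dimensions", call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xmin <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  ymin <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  iso_raster(m, xmin = xmin, ymax = ymin + hdr$nrows * hdr$cellsize,
             dx = hdr$cellsize, nodata = nodata)
}

#' @rdname read_ascii_grid
#' @param r an `iso_raster` with square cells.
#' @export
write_ascii_grid <- function(r, path) {
  if (!isTRUE(all.equal(r$dx, r$dy)))
    stop("ESRI ASCII grids require square cells (dx == dy)", call. = FALSE)
  v <- r$values
  v[!is.finite(v)] <- r$nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", r$xmin),
           sprintf("yllcorner %.10g", raster_ymin(r)),
           sprintf("cellsize %.10g", r$dx),
           sprintf("NODATA_value %.10g", r$nodata))
  body <- apply(v, 1L, function(row) paste(format(row, trim = TRUE,
                                                  digits = 10),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
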