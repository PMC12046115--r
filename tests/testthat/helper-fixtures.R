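# shared in-code fixtures: tiny rasters and record tables built at test time

# a flat raster with every cell equal to `value`
flat_raster <- function(value = 5, nr = 4, nc = 5, xmin = -110, ymax = 44,
                        dx = 1) {
  iso_raster(matrix(value, nr, nc), xmin = xmin, ymax = ymax, dx = dx)
}

# single-row raster: all cells share a latitude, hence equal area weights
equal_area_raster <- function(values, lat = 40, xmin = -110, dx = 1) {
  iso_raster(matrix(values, nrow = 1), xmin = xmin, ymax = lat + 0.5,
             dx = dx)
}

# minimal valid record table around a raster's cell centers
toy_records <- function(env, n = 10, slope = 1, intercept = 0,
                        noise_sd = 0, seed = 1) {
  set.seed(seed)
  co <- raster_coords(env)
  pick <- co[sample.int(nrow(co), n, replace = TRUE), ]
  e <- env$values[cbind(pick$row, pick$col)]
  data.frame(sample_id = sprintf("t%03d", seq_len(n)),
             site_id = sprintf("s%03d", seq_len(n)),
             longitude = pick$lon, latitude = pick$lat,
             value = intercept + slope * e + rnorm(n, 0, noise_sd),
             study_id = "S1", origin_status = "known",
             tissue = "hair", analyte = "oxygen",
             stringsAsFactors = FALSE)
}

# write a canonical-ish compilation CSV and return its path
write_fixture_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}

valid_raw_rows <- function() {
  data.frame(
    sample_id = c("a1", "a2", "a3"),
    site_id = c("s1", "s2", "s3"),
    longitude = c(-100, -101, -102), latitude = c(40, 41, 42),
    country = "US", tissue = c("hair", "hair", "tooth_enamel"),
    analyte = c("oxygen", "oxygen", "strontium"),
    value = c(10.5, 12.0, 0.7105),
    oxygen_scale = c("VSMOW", "VSMOW", ""),
    oxygen_phase = c("keratin", "keratin", ""),
    calibration_scale = c("VSMOW_O", "VSMOW_O", ""),
    origin_status = c("known", "assumed", "known"),
    study_id = c("S1", "S1", "S2"),
    tooth_element = c("", "", "first molar"),
    stringsAsFactors = FALSE)
}
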