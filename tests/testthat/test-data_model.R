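test_that("VPDB to VSMOW conversion matches the published linear map", {
  expect_equal(vpdb_to_vsmow(0), 30.92)
  expect_equal(vpdb_to_vsmow(-10), 20.6108)
  # slope of the map
  expect_equal(vpdb_to_vsmow(1) - vpdb_to_vsmow(0), 1.03092)
  # strictly increasing, exact round trip
  v <- seq(-40, 10, by = 2.5)
  expect_true(all(diff(vpdb_to_vsmow(v)) > 0))
  expect_equal(vsmow_to_vpdb(vpdb_to_vsmow(5)), 5)
  expect_error(vpdb_to_vsmow(NaN), "finite")
  expect_error(vpdb_to_vsmow(c(1, Inf)), "finite")
})

test_that("phosphate to carbonate conversion satisfies its defining identity", {
  expect_equal(phosphate_to_carbonate(18.0), 26.821, tolerance = 1e-4)
  expect_equal(phosphate_to_carbonate(0), 9.3828, tolerance = 1e-4)
  v <- seq(-5, 30, length.out = 21)
  expect_equal(1.0322 * phosphate_to_carbonate(v) - v,
               rep(9.6849, length(v)))
  expect_equal(carbonate_to_phosphate(phosphate_to_carbonate(v)), v)
  expect_error(phosphate_to_carbonate(NA_real_), "finite")
})

test_that("dental elements map onto crown-formation age groups", {
  expect_equal(assign_tooth_group("first molar"), "G0_4")
  expect_equal(assign_tooth_group("central incisor"), "G0_4")
  expect_equal(assign_tooth_group("lateral incisor"), "G0p5_6")
  expect_equal(assign_tooth_group("canine"), "G0p5_6")
  expect_equal(assign_tooth_group(c("premolar", "second molar")),
               c("G2p5_7", "G2p5_7"))
  expect_equal(assign_tooth_group("third molar"), "G7p5_15")
  expect_equal(assign_tooth_group("M3"), "G7p5_15")
  # ambiguous labels cannot be resolved to one window
  expect_equal(assign_tooth_group("molar"), "Unknown")
  expect_equal(assign_tooth_group("incisor"), "Unknown")
  expect_error(assign_tooth_group(""), "non-empty")
  expect_error(assign_tooth_group(character(0)), "non-empty")
})

test_that("loading validates rows, converts scales and reports drops", {
  path <- write_fixture_csv(valid_raw_rows())
  d <- load_dataset(path)
  expect_s3_class(d, "iso_dataset")
  expect_equal(nrow(d), 3L)
  expect_true(validate_dataset(d))
  # analysis-type suffixing
  expect_setequal(d$sample_id, c("a1-O", "a2-O", "a3-Sr"))
  expect_equal(d$tooth_group[d$sample_id == "a3-Sr"], "G0_4")

  rows <- valid_raw_rows()
  rows$latitude[2] <- 95
  rows$value[1] <- 0
  rows$oxygen_scale[1] <- "VPDB"
  d2 <- load_dataset(write_fixture_csv(rows))
  rep <- load_report(d2)
  expect_equal(rep$n_kept, 2L)
  expect_equal(names(rep$dropped_by_reason), "coordinate out of range")
  # VPDB 0 normalized to VSMOW 30.92
  expect_equal(d2$value[d2$sample_id == "a1-O"], 30.92)
  expect_equal(d2$oxygen_scale[d2$sample_id == "a1-O"], "VSMOW")

  expect_error(load_dataset(write_fixture_csv(valid_raw_rows()[, -4])),
               "mandatory")
})

test_that("schema config remaps source column headers", {
  rows <- valid_raw_rows()
  names(rows)[names(rows) == "longitude"] <- "Long"
  names(rows)[names(rows) == "latitude"] <- "Lat"
  path <- write_fixture_csv(rows)
  expect_error(load_dataset(path), "mandatory")
  d <- load_dataset(path, schema = c(longitude = "Long", latitude = "Lat"))
  expect_equal(nrow(d), 3L)
  # same mapping through a DCF config file
  cfg <- tempfile()
  writeLines(c("longitude: Long", "latitude: Lat"), cfg)
  d2 <- load_dataset(path, schema = cfg)
  expect_equal(d2$longitude, d$longitude)
  expect_error(load_dataset(path, schema = c(longitude = "nope")),
               "missing column")
})

test_that("write/reload round-trips all fields and conversion is idempotent", {
  d <- load_dataset(write_fixture_csv(valid_raw_rows()))
  out <- tempfile(fileext = ".csv")
  write_dataset(d, out)
  d2 <- load_dataset(out)
  for (col in names(d))
    expect_identical(d2[[col]], d[[col]], label = col)
  # loading canonical output twice never re-converts values
  out2 <- tempfile(fileext = ".csv")
  write_dataset(d2, out2)
  expect_identical(load_dataset(out2)$value, d$value)
})

test_that("phosphate-analyzed oxygen is normalized and suffixed -P", {
  rows <- valid_raw_rows()[1, ]
  rows$tissue <- "tooth_enamel"; rows$oxygen_phase <- "phosphate"
  rows$value <- 18; rows$tooth_element <- "canine"
  d <- load_dataset(write_fixture_csv(rows))
  expect_equal(d$sample_id, "a1-P")
  expect_equal(d$value, (18 + 9.6849) / 1.0322)
  expect_equal(d$oxygen_phase, "carbonate")
})

test_that("duplicate sample ids after suffixing are a load error", {
  rows <- rbind(valid_raw_rows()[1, ], valid_raw_rows()[1, ])
  expect_error(load_dataset(write_fixture_csv(rows)), "duplicate sample_id")
})

test_that("every record of a loaded dataset satisfies the schema invariants", {
  sc <- synthetic_scenario(seed = 3, n_sites = 40, n_per_site = 2,
                           assumed_fraction = 0.3,
                           tissue = "tooth_enamel",
                           tooth_offsets = c(G0_4 = 0.5, G7p5_15 = -0.5),
                           intercept = 29.4, slope = 0.43)
  d <- synth_dataset(sc)
  expect_true(validate_dataset(d))
  expect_true(all(d$tooth_group != "not_tooth"))
  expect_true(any(d$origin_status == "assumed"))
})

test_that("multi-origin pre-filter drops records with distant origins", {
  origins <- data.frame(
    sample_id = c("a", "a", "b", "b", "c"),
    longitude = c(-100, -100.1, -100, -102, -95),
    latitude = c(40, 40.05, 40, 41, 33))
  out <- filter_multiorigin(origins, max_km = 25)
  expect_true(out$kept[out$sample_id == "a"])   # ~10 km apart
  expect_false(out$kept[out$sample_id == "b"])  # ~200 km apart
  expect_true(out$kept[out$sample_id == "c"])   # single origin
  expect_equal(out$longitude[out$sample_id == "a"], -100.05)
})
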