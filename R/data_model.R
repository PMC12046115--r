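#' @keywords internal
"_PACKAGE"

# canonical column order of the compilation schema
iso_schema_columns <- c(
  "sample_id", "site_id", "longitude", "latitude", "country", "tissue",
  "analyte", "value", "oxygen_scale", "oxygen_phase", "calibration_scale",
  "origin_status", "study_id", "tooth_element", "tooth_group", "sex",
  "age_class")

iso_enums <- list(
  tissue = c("hair", "nail", "bone", "tooth_enamel"),
  analyte = c("oxygen", "strontium"),
  oxygen_scale = c("VSMOW", "VPDB", "none"),
  oxygen_phase = c("carbonate", "phosphate", "keratin", "none"),
  origin_status = c("known", "assumed"),
  tooth_group = c("G0_4", "G0p5_6", "G2p5_7", "G7p5_15", "Unknown",
                  "not_tooth"),
  sex = c("M", "F", "unknown"),
  age_class = c("adult", "nonadult", "unknown"))

#' Oxygen isotope reference-scale and phase conversions
#'
#' `vpdb_to_vsmow()` converts delta-18O values reported on the VPDB scale to
#' the VSMOW(-SLAP) scale, `delta_VSMOW = 1.03092 * delta_VPDB + 30.92`.
#' `vsmow_to_vpdb()` is its exact inverse. `phosphate_to_carbonate()`
#' converts enamel phosphate delta-18O (VSMOW) to the carbonate-equivalent,
#' `delta_C = (delta_P + 9.6849) / 1.0322` (the standard enamel phosphate–carbonate calibration), so
#' that phosphate-analyzed samples are comparable with the carbonate data
#' that dominate tooth-enamel compilations; `carbonate_to_phosphate()`
#' inverts it.
#'
#' @param value numeric vector of delta-18O values in per mil.
#' @return numeric vector on the target scale/phase.
#' @examples
#' vpdb_to_vsmow(0)          # 30.92
#' phosphate_to_carbonate(18)
#' @export
vpdb_to_vsmow <- function(value) {
  check_finite(value)
  1.03092 * value + 30.92
}

#' @rdname vpdb_to_vsmow
#' @export
vsmow_to_vpdb <- function(value) {
  check_finite(value)
  (value - 30.92) / 1.03092
}

#' @rdname vpdb_to_vsmow
#' @export
phosphate_to_carbonate <- function(value) {
  check_finite(value)
  (value + 9.6849) / 1.0322
}

#' @rdname vpdb_to_vsmow
#' @export
carbonate_to_phosphate <- function(value) {
  check_finite(value)
  value * 1.0322 - 9.6849
}

check_finite <- function(value) {
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("values must be finite numbers", call. = FALSE)
  invisible(value)
}

#' Categorize dental elements by crown-formation age window
#'
#' Maps free-text dental element labels onto four mineralization-age groups:
#' 0-4 years (first molars, central incisors), 0.5-6 years (lateral
#' incisors, canines), 2.5-7 years (premolars, second molars) and 7.5-15
#' years (third molars). Labels that cannot be resolved to a single group
#' (e.g., a bare "molar") return `"Unknown"`, since their membership is
#' heterogeneous.
#'
#' @param element_label character vector of dental element names.
#' @return character vector of group codes `G0_4`, `G0p5_6`, `G2p5_7`,
#'   `G7p5_15` or `Unknown`.
#' @examples
#' assign_tooth_group(c("first molar", "canine", "third molar", "molar"))
#' @export
assign_tooth_group <- function(element_label) {
  if (length(element_label) == 0L ||
      any(is.na(element_label) | !nzchar(trimws(element_label))))
    stop("element labels must be non-empty", call. = FALSE)
  lab <- tolower(trimws(element_label))
  lab <- gsub("1st", "first", lab, fixed = TRUE)
  lab <- gsub("2nd", "second", lab, fixed = TRUE)
  lab <- gsub("3rd", "third", lab, fixed = TRUE)
  out <- rep("Unknown", length(lab))
  g0_4 <- grepl("first molar|\\bm1\\b|central incisor|\\bi1\\b", lab)
  g0p5_6 <- grepl("lateral incisor|\\bi2\\b|canine|\\bc1?\\b$", lab)
  g2p5_7 <- grepl("premolar|\\bpm?[12]\\b|second molar|\\bm2\\b", lab)
  g7p5_15 <- grepl("third molar|\\bm3\\b|wisdom", lab)
  hits <- g0_4 + g0p5_6 + g2p5_7 + g7p5_15
  out[g0_4 & hits == 1L] <- "G0_4"
  out[g0p5_6 & hits == 1L] <- "G0p5_6"
  out[g2p5_7 & hits == 1L] <- "G2p5_7"
  out[g7p5_15 & hits == 1L] <- "G7p5_15"
  out
}

#' Load and validate a tissue isotope compilation
#'
#' Reads a CSV of tissue isotope records, maps source column names onto the
#' canonical schema through a schema config, validates every row against
#' the schema invariants, and normalizes all oxygen values to
#' VSMOW / carbonate-equivalent (applying [vpdb_to_vsmow()] and
#' [phosphate_to_carbonate()] where the declared scale and phase demand it;
#' records already on VSMOW/carbonate are never re-converted, so loading a
#' canonical file twice is idempotent). Rows that fail validation are
#' dropped with a row-level diagnostic, never crash the load.
#'
#' Sample identifiers receive an analysis-type suffix (`-O`, `-Sr`, `-P`
#' for oxygen, strontium and phosphate-analyzed oxygen) if not already
#' present; identifier collisions after suffixing are a load error.
#'
#' @param path CSV file (RFC 4180, UTF-8, "." decimal separator).
#' @param schema optional mapping from canonical field names to source
#'   column names: a named character vector, or the path of a DCF file whose
#'   field names are canonical names and values the source headers. Columns
#'   already canonically named need no entry.
#' @return an `iso_dataset` (a data.frame in canonical column order) with
#'   attributes `provenance` and `report`; retrieve the load report with
#'   [load_report()].
#' @seealso [write_dataset()], [validate_dataset()]
#' @export
load_dataset <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("NA", ""))
  if (!is.null(schema)) {
    map <- if (is.character(schema) && length(schema) == 1L &&
               file.exists(schema)) read_schema_config(schema) else schema
    if (is.null(names(map)) || any(!nzchar(names(map))))
      stop("schema mapping must be named (canonical = source)", call. = FALSE)
    for (canon in names(map)) {
      src <- map[[canon]]
      if (!src %in% names(raw))
        stop(sprintf("schema maps '%s' to missing column '%s'", canon, src),
             call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  mandatory <- c("sample_id", "longitude", "latitude", "tissue", "analyte",
                 "value")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as_iso_dataset(raw, provenance = paste0("loaded from ", path))
}

read_schema_config <- function(path) {
  m <- read.dcf(path)
  stats::setNames(as.character(m[1L, ]), colnames(m))
}

#' Construct a validated dataset from a data.frame
#'
#' Workhorse behind [load_dataset()]: fills defaulted columns, coerces
#' types, validates each record, applies scale/phase normalization and
#' identifier suffixing, and attaches a load report.
#'
#' @param df data.frame with at least the mandatory schema columns.
#' @param provenance free-text source note.
#' @return an `iso_dataset`.
#' @export
as_iso_dataset <- function(df, provenance = "in-memory") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  defaults <- list(site_id = NA_character_, country = "",
                   oxygen_scale = NA_character_,
                   oxygen_phase = NA_character_,
                   calibration_scale = "", origin_status = "known",
                   study_id = "unspecified", tooth_element = "",
                   tooth_group = NA_character_, sex = "unknown",
                   age_class = "unknown")
  for (nm in names(defaults))
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df$longitude <- suppressWarnings(as.numeric(df$longitude))
  df$latitude <- suppressWarnings(as.numeric(df$latitude))
  df$value <- suppressWarnings(as.numeric(df$value))
  for (nm in c("sample_id", "site_id", "country", "tissue", "analyte",
               "oxygen_scale", "oxygen_phase", "calibration_scale",
               "origin_status", "study_id", "tooth_element", "tooth_group",
               "sex", "age_class"))
    df[[nm]] <- as.character(df[[nm]])

  # numeric donor age, when supplied, is binned at load (adult = >= 18 y)
  if ("age" %in% names(df)) {
    age <- suppressWarnings(as.numeric(df$age))
    df$age_class <- ifelse(is.na(age), df$age_class,
                           ifelse(age >= 18, "adult", "nonadult"))
  }
  df$site_id <- ifelse(is.na(df$site_id) | !nzchar(df$site_id),
                       sprintf("site_%g_%g", round(df$longitude, 4),
                               round(df$latitude, 4)), df$site_id)

  # defaulted enum fields tied to the analyte / tissue
  ox <- df$analyte %in% "oxygen"
  df$oxygen_scale[!ox] <- "none"
  df$oxygen_phase[!ox] <- "none"
  df$oxygen_scale[ox & (is.na(df$oxygen_scale) | df$oxygen_scale == "")] <-
    "VSMOW"
  df$oxygen_phase[ox & (is.na(df$oxygen_phase) | df$oxygen_phase == "")] <-
    ifelse(df$tissue[ox & (is.na(df$oxygen_phase) | df$oxygen_phase == "")] %in%
             c("hair", "nail"), "keratin", "carbonate")
  tooth <- df$tissue %in% "tooth_enamel"
  needs_group <- tooth & (is.na(df$tooth_group) | !nzchar(df$tooth_group))
  has_elem <- needs_group & nzchar(trimws(df$tooth_element))
  if (any(has_elem))
    df$tooth_group[has_elem] <- assign_tooth_group(df$tooth_element[has_elem])
  df$tooth_group[needs_group & !has_elem] <- "Unknown"
  df$tooth_group[!tooth] <- "not_tooth"
  df$sex[is.na(df$sex) | !df$sex %in% iso_enums$sex] <- "unknown"
  df$age_class[is.na(df$age_class) |
                 !df$age_class %in% iso_enums$age_class] <- "unknown"

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  flag(is.na(df$sample_id) | !nzchar(df$sample_id), "missing sample_id")
  flag(is.na(df$longitude) | is.na(df$latitude) |
         df$latitude < -90 | df$latitude > 90 |
         df$longitude < -180 | df$longitude > 180, "coordinate out of range")
  flag(!df$tissue %in% iso_enums$tissue, "unknown tissue")
  flag(!df$analyte %in% iso_enums$analyte, "unknown analyte")
  flag(!df$origin_status %in% iso_enums$origin_status,
       "unknown origin_status")
  flag(is.na(df$value), "unparseable value")
  ox <- df$analyte %in% "oxygen"
  flag(ox & !df$oxygen_scale %in% c("VSMOW", "VPDB"), "unknown oxygen scale")
  flag(ox & !df$oxygen_phase %in% c("carbonate", "phosphate", "keratin"),
       "unknown oxygen phase")
  sr <- df$analyte %in% "strontium"
  flag(sr & !is.na(df$value) & (df$value <= 0.70 | df$value >= 0.75),
       "Sr ratio out of range")

  kept <- is.na(reason)
  out <- df[kept, , drop = FALSE]

  # normalize oxygen values: VPDB -> VSMOW, then phosphate -> carbonate
  is_vpdb <- out$analyte == "oxygen" & out$oxygen_scale == "VPDB"
  out$value[is_vpdb] <- vpdb_to_vsmow(out$value[is_vpdb])
  out$oxygen_scale[is_vpdb] <- "VSMOW"
  was_phos <- out$analyte == "oxygen" & out$oxygen_phase == "phosphate"
  out$value[was_phos] <- phosphate_to_carbonate(out$value[was_phos])
  out$oxygen_phase[was_phos] <- "carbonate"

  # post-conversion range check on the VSMOW scale
  bad_ox <- out$analyte == "oxygen" &
    (out$value <= -30 | out$value >= 40)
  if (any(bad_ox)) {
    ridx <- which(kept)[bad_ox]
    reason[ridx] <- "oxygen value out of range (VSMOW)"
    out <- out[!bad_ox, , drop = FALSE]
  }

  # analysis-type suffix; `was_phos` marks phosphate-analyzed oxygen
  suffix <- ifelse(out$analyte == "strontium", "-Sr",
                   ifelse(was_phos[!bad_ox], "-P", "-O"))
  need <- !endsWith(out$sample_id, suffix)
  out$sample_id[need] <- paste0(out$sample_id[need], suffix[need])
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample_id after analysis-type suffixing: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]),
               collapse = ", "), call. = FALSE)

  keep_extra <- setdiff(names(out), c(iso_schema_columns, "age"))
  out <- out[, c(iso_schema_columns, keep_extra), drop = FALSE]
  rownames(out) <- NULL
  report <- list(
    n_input = nrow(df), n_kept = nrow(out),
    n_dropped = sum(!is.na(reason)),
    dropped_by_reason = as.list(table(reason[!is.na(reason)])),
    n_converted_vpdb = sum(is_vpdb), n_converted_phosphate = sum(was_phos))
  structure(out, provenance = provenance, report = report,
            class = c("iso_dataset", "data.frame"))
}

#' @rdname load_dataset
#' @param dataset an `iso_dataset`.
#' @export
load_report <- function(dataset) attr(dataset, "report")

#' Assert the schema invariants over a full dataset
#'
#' Scans every record: coordinate ranges, enum membership, value ranges by
#' analyte (Sr in (0.70, 0.75), delta-18O VSMOW in (-30, 40) per mil),
#' tooth-group/tissue consistency, oxygen-scale/analyte consistency, and
#' sample-id uniqueness. Errors on the first violation.
#'
#' @param dataset an `iso_dataset`.
#' @return invisibly `TRUE`.
#' @export
validate_dataset <- function(dataset) {
  d <- dataset
  stopifnot(is.data.frame(d), all(iso_schema_columns %in% names(d)))
  fail <- function(msg) stop("dataset invariant violated: ", msg,
                             call. = FALSE)
  if (anyDuplicated(d$sample_id)) fail("duplicate sample_id")
  if (any(d$latitude < -90 | d$latitude > 90 |
          d$longitude < -180 | d$longitude > 180, na.rm = TRUE))
    fail("coordinate out of range")
  for (nm in names(iso_enums))
    if (any(!d[[nm]] %in% iso_enums[[nm]])) fail(paste("bad", nm))
  sr <- d$analyte == "strontium"
  if (any(d$value[sr] <= 0.70 | d$value[sr] >= 0.75))
    fail("Sr ratio out of (0.70, 0.75)")
  if (any(d$value[!sr] <= -30 | d$value[!sr] >= 40))
    fail("delta-18O out of (-30, 40) VSMOW")
  if (any((d$tooth_group == "not_tooth") != (d$tissue != "tooth_enamel")))
    fail("tooth_group/tissue inconsistency")
  if (any((d$oxygen_scale == "none") != (d$analyte == "strontium")))
    fail("oxygen_scale/analyte inconsistency")
  invisible(TRUE)
}

#' Write a dataset as canonical CSV
#'
#' Fixed canonical column order; reloading the file with [load_dataset()]
#' reproduces all fields.
#'
#' @param dataset an `iso_dataset`.
#' @param path output CSV path.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset[, union(iso_schema_columns, names(dataset)),
                           drop = FALSE],
                   path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @export
print.iso_dataset <- function(x, ...) {
  rep <- attr(x, "report")
  cat(sprintf("<iso_dataset> %d records (%s)\n", nrow(x),
              attr(x, "provenance")))
  if (!is.null(rep))
    cat(sprintf("  load: %d input, %d kept, %d dropped\n",
                rep$n_input, rep$n_kept, rep$n_dropped))
  NextMethod()
}

#' Pre-filter records with multiple reported origins
#'
#' Individuals with residence at several locations during tissue growth are
#' only usable when all locations are in close geographic proximity. Given a
#' long table of candidate origins per sample, this keeps samples whose
#' origins all fall within `max_km` great-circle kilometres of each other
#' (collapsing them to the coordinate centroid) and drops the rest.
#'
#' @param origins data.frame with columns `sample_id`, `longitude`,
#'   `latitude` (one row per candidate origin).
#' @param max_km maximum pairwise separation in km (default 25, the midpoint
#'   of the 20-30 km proximity window used in compilation practice).
#' @return data.frame with one row per sample: `sample_id`, `longitude`,
#'   `latitude`, `n_origins`, `max_separation_km`, `kept`.
#' @export
filter_multiorigin <- function(origins, max_km = 25) {
  stopifnot(all(c("sample_id", "longitude", "latitude") %in% names(origins)))
  res <- lapply(split(origins, origins$sample_id), function(g) {
    sep <- if (nrow(g) > 1L)
      max(geosphere::distm(cbind(g$longitude, g$latitude))) / 1000 else 0
    data.frame(sample_id = g$sample_id[1L],
               longitude = mean(g$longitude), latitude = mean(g$latitude),
               n_origins = nrow(g), max_separation_km = sep,
               kept = sep <= max_km)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
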