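#' Build a residual bias table
#'
#' The correction for each group is its mean calibration residual: the
#' systematic offset of that group's tissue values from the overall
#' tissue-environment relationship. Subtracting these corrections from the
#' original data removes between-group bias while leaving the geographic
#' signal untouched.
#'
#' @param fit a `calibration_fit`.
#' @param grouping column name in `fit$data` or per-record group vector
#'   (see [summarize_residuals()]).
#' @param exclude groups never assigned a correction (default
#'   `c("Unknown", "not_tooth")`: heterogeneous or non-applicable bins).
#' @return object of class `bias_table`: data.frame with `group_id`,
#'   `correction`, `n`.
#' @export
build_bias_table <- function(fit, grouping,
                             exclude = c("Unknown", "not_tooth")) {
  s <- summarize_residuals(fit, grouping)
  s <- s[!s$group_id %in% exclude, , drop = FALSE]
  if (any(s$n == 0L)) {
    warning("omitting empty group(s) from bias table", call. = FALSE)
    s <- s[s$n > 0L, , drop = FALSE]
  }
  out <- data.frame(group_id = s$group_id, correction = s$mean_residual,
                    n = s$n)
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Apply a residual bias correction to a dataset
#'
#' Subtracts each record's group correction from its isotope value
#' (`value' = value - correction`); all other fields are untouched. Records
#' whose group has no entry in the table pass through unchanged (counted in
#' a message). Note the operation is only idempotent if the bias table is
#' rebuilt from a refit on the corrected data: applying the same table twice
#' subtracts the correction twice.
#'
#' @param dataset an `iso_dataset` or data.frame with a `value` column.
#' @param bias a `bias_table`.
#' @param grouping column name in `dataset` holding the group labels.
#' @return the corrected dataset (same class and shape).
#' @export
apply_bias_correction <- function(dataset, bias, grouping) {
  stopifnot(inherits(bias, "bias_table"),
            is.character(grouping), grouping %in% names(dataset))
  g <- as.character(dataset[[grouping]])
  corr <- bias$correction[match(g, bias$group_id)]
  unmatched <- sum(is.na(corr))
  if (unmatched > 0)
    message(sprintf("%d record(s) in group(s) without corrections left unchanged",
                    unmatched))
  corr[is.na(corr)] <- 0
  dataset$value <- dataset$value - corr
  dataset
}

#' Reference-scale transform table for keratin delta-18O
#'
#' Laboratories have calibrated keratin oxygen data against different
#' in-house reference materials; each calibration scale relates to a common
#' VSMOW realization by a linear map `common = gain * value + offset`.
#' Transforming all data onto the common frame improves comparability
#' between datasets. Coefficients are supplied by the user (e.g., from a
#' published standard chain), never invented here: values on a scale absent
#' from the table cannot be transformed and raise an error, mirroring the
#' compilation practice of excluding samples whose original calibration
#' scale cannot be determined.
#'
#' @param scale_label character vector of scale names.
#' @param gain multiplicative coefficients (> 0).
#' @param offset additive coefficients (per mil).
#' @return object of class `scale_transform`: data.frame of the three
#'   columns.
#' @export
scale_transform_table <- function(scale_label, gain, offset) {
  stopifnot(length(scale_label) == length(gain),
            length(gain) == length(offset))
  if (any(!is.finite(gain)) || any(gain <= 0))
    stop("gains must be positive and finite", call. = FALSE)
  if (anyDuplicated(scale_label))
    stop("duplicate scale labels", call. = FALSE)
  out <- data.frame(scale_label = as.character(scale_label),
                    gain = as.numeric(gain), offset = as.numeric(offset))
  class(out) <- c("scale_transform", "data.frame")
  out
}

#' @rdname scale_transform_table
#' @param path CSV with columns `scale_label`, `gain`, `offset`.
#' @export
read_scale_transforms <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  scale_transform_table(d$scale_label, d$gain, d$offset)
}

#' Transform values between calibration reference scales
#'
#' Maps values from one calibration scale to another through the common
#' frame: `common = gain_from * v + offset_from`, then
#' `v' = (common - offset_to) / gain_to`. Same-label transforms are the
#' identity; transforms compose associatively, and A->B followed by B->A
#' returns the original values. Use `to_label = "common"` to land on the
#' common VSMOW frame itself.
#'
#' @param values numeric values on the `from_label` scale.
#' @param from_label,to_label scale names present in `table` (or
#'   `"common"`).
#' @param table a `scale_transform` table.
#' @return transformed values.
#' @export
transform_reference_scale <- function(values, from_label, to_label, table) {
  stopifnot(inherits(table, "scale_transform"))
  coef_of <- function(label) {
    if (identical(label, "common")) return(c(gain = 1, offset = 0))
    i <- match(label, table$scale_label)
    if (is.na(i))
      stop(sprintf("unknown calibration scale '%s'; cannot transform",
                   label), call. = FALSE)
    c(gain = table$gain[i], offset = table$offset[i])
  }
  f <- coef_of(from_label); t <- coef_of(to_label)
  if (identical(from_label, to_label)) return(values)
  (f[["gain"]] * values + f[["offset"]] - t[["offset"]]) / t[["gain"]]
}
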