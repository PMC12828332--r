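# Geometric accuracy: MAE between reference and modeled morphometric
# measurements, with per-feature success accounting.

#' The six morphometric features
#'
#' Elytra length and width, lengths of the second and third antenna segments,
#' and lengths of the first and second tibia — standard carabid features used
#' as geometric accuracy probes. A measurement whose body segment was not
#' modeled is absent (`NA`), never zero: zero-length measurements are invalid.
#'
#' @export
morphometric_features <- c(
  "elytra_length", "elytra_width",
  "antenna_segment_2", "antenna_segment_3",
  "first_tibia", "second_tibia"
)

#' Validate a measurement table
#'
#' @param df Data frame with columns `specimen_id`, `style`, `step`, `tilts`,
#'   `feature`, `reference_mm`, `modeled_mm` (`NA` = absent).
#' @return The validated data frame.
#' @keywords internal
validate_measurements <- function(df) {
  need <- c("specimen_id", "style", "step", "tilts", "feature",
            "reference_mm", "modeled_mm")
  if (!all(need %in% names(df)))
    stop("measurement table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  bad <- !df$feature %in% morphometric_features
  if (any(bad))
    stop("unknown feature(s) at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(unique(df$feature[bad]), collapse = ", "), call. = FALSE)
  if (any(is.na(df$reference_mm) | df$reference_mm <= 0))
    stop("non-positive or missing reference_mm at row(s) ",
         paste(utils::head(which(is.na(df$reference_mm) |
                                   df$reference_mm <= 0), 5),
               collapse = ", "), call. = FALSE)
  present <- !is.na(df$modeled_mm)
  if (any(df$modeled_mm[present] <= 0))
    stop("non-positive modeled_mm at row(s) ",
         paste(utils::head(which(present & df$modeled_mm <= 0), 5),
               collapse = ", "), call. = FALSE)
  df
}

#' Read a morphometric measurement CSV
#'
#' Expected columns: `specimen_id`, `style`, `step`, `tilts`, `feature`,
#' `reference_mm`, `modeled_mm`. An empty `modeled_mm` cell encodes an absent
#' measurement (body segment not modeled). Unknown feature names and
#' non-positive lengths are rejected with the offending row number.
#'
#' @param path CSV path.
#' @return Validated data frame of measurement records.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$modeled_mm <- suppressWarnings(as.numeric(df$modeled_mm))
  validate_measurements(df)
}

#' Write a morphometric measurement CSV
#'
#' Inverse of [read_measurements()]; absent modeled values become empty cells.
#'
#' @param df Measurement data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(df, path) {
  validate_measurements(df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' MAE for one feature across specimens
#'
#' Mean of `|modeled - reference|` over the records whose modeled value is
#' present; absent records count toward the total but not the MAE. With zero
#' successes the MAE is `NA` (reported as "N/A (0/n)").
#'
#' @param reference_mm Numeric vector of reference lengths (mm).
#' @param modeled_mm Numeric vector of modeled lengths (mm), `NA` = absent.
#' @return List with `mae_mm`, `n_success`, `n_total`.
#' @export
feature_mae <- function(reference_mm, modeled_mm) {
  if (length(reference_mm) != length(modeled_mm) || length(reference_mm) < 1L)
    stop("reference and modeled vectors must have equal, positive length",
         call. = FALSE)
  ok <- !is.na(modeled_mm)
  list(
    mae_mm = if (any(ok)) mean(abs(modeled_mm[ok] - reference_mm[ok]))
             else NA_real_,
    n_success = sum(ok),
    n_total = length(modeled_mm)
  )
}

#' Geometric score for one specimen x scenario
#'
#' The overall MAE pools all present records — it is the mean of
#' `|modeled - reference|` across all measurements, not the mean of per-feature
#' MAEs (the two differ when features have unequal success counts; the pooled
#' form reads "across all measurements" literally). The per-feature breakdown
#' reports MAE and success counts for each feature.
#'
#' @param records Measurement data frame (see [read_measurements()]) for one
#'   specimen and scenario, one or more rows per feature.
#' @param aggregate `"pooled"` (default) or `"feature_means"` (mean of
#'   per-feature MAEs over features with at least one success).
#' @return A `geometric_score`: `overall_mae_mm` (`NA` when no record is
#'   present), `n_success`, `n_total`, and a `per_feature` data frame.
#' @export
geometric_score <- function(records, aggregate = c("pooled", "feature_means")) {
  aggregate <- match.arg(aggregate)
  records <- validate_measurements(records)
  if (nrow(records) < 1L) stop("no measurement records", call. = FALSE)
  feats <- unique(records$feature)
  per <- do.call(rbind, lapply(feats, function(ft) {
    r <- records[records$feature == ft, ]
    fm <- feature_mae(r$reference_mm, r$modeled_mm)
    data.frame(feature = ft, mae_mm = fm$mae_mm, n_success = fm$n_success,
               n_total = fm$n_total, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  ok <- !is.na(records$modeled_mm)
  overall <- if (!any(ok)) {
    NA_real_
  } else if (aggregate == "pooled") {
    mean(abs(records$modeled_mm[ok] - records$reference_mm[ok]))
  } else {
    mean(per$mae_mm[per$n_success > 0])
  }
  structure(
    list(overall_mae_mm = overall, n_success = sum(ok),
         n_total = nrow(records), per_feature = per, aggregate = aggregate),
    class = "geometric_score"
  )
}

#' @export
print.geometric_score <- function(x, ...) {
  cat(sprintf("<geometric_score> overall MAE %s mm (%d/%d measurements)\n",
              ifelse(is.na(x$overall_mae_mm), "N/A",
                     sprintf("%.2f", x$overall_mae_mm)),
              x$n_success, x$n_total))
  invisible(x)
}
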