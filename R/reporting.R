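# Aggregation of per-model evaluations into per-scenario summary tables,
# best-model selection, and report files.

EM_DASH <- "—"

#' Validate an evaluations data frame
#'
#' One row per planned model: `specimen_id`, `style`, `step`, `tilts`,
#' `model_created` (logical), `rgb_similarity`, `ssim`, `mae_mm` (all `NA`
#' when the model was not created).
#'
#' @param evaluations Data frame as above.
#' @return The validated data frame.
#' @keywords internal
validate_evaluations <- function(evaluations) {
  need <- c("specimen_id", "style", "step", "tilts", "model_created",
            "rgb_similarity", "ssim", "mae_mm")
  if (!all(need %in% names(evaluations)))
    stop("evaluations is missing columns: ",
         paste(setdiff(need, names(evaluations)), collapse = ", "),
         call. = FALSE)
  key <- paste(evaluations$specimen_id, evaluations$style, evaluations$step,
               evaluations$tilts)
  if (anyDuplicated(key))
    stop("duplicate (specimen, scenario) evaluation: ",
         key[anyDuplicated(key)], call. = FALSE)
  bad <- !evaluations$model_created &
    (!is.na(evaluations$rgb_similarity) | !is.na(evaluations$mae_mm))
  if (any(bad))
    stop("scores present for models that were not created (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")",
         call. = FALSE)
  evaluations
}

scenario_order_key <- function(style, step, tilts) {
  order(match(style, imaging_styles), step, match(tilts, tilt_set_names))
}

#' Summarize evaluations per scenario
#'
#' One row per scenario in grid order (style, then horizontal step, then tilt
#' set). `n_success` counts created models; the mean RGB similarity, SSIM and
#' MAE are computed over created models only and are `NA` when a scenario has
#' no successes (rendered as an em dash in reports).
#'
#' @param evaluations See [validate_evaluations()].
#' @return Data frame with `style`, `step`, `tilts`, `label`, `n_success`,
#'   `n_total`, `mean_rgb_similarity`, `mean_ssim`, `mean_mae_mm`.
#' @export
summarize_scenarios <- function(evaluations) {
  evaluations <- validate_evaluations(evaluations)
  key <- unique(evaluations[, c("style", "step", "tilts")])
  key <- key[scenario_order_key(key$style, key$step, key$tilts), ]
  out <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sel <- evaluations$style == key$style[i] &
      evaluations$step == key$step[i] & evaluations$tilts == key$tilts[i]
    ev <- evaluations[sel, ]
    created <- ev[ev$model_created, ]
    n <- nrow(created)
    data.frame(
      style = key$style[i], step = key$step[i], tilts = key$tilts[i],
      label = sprintf("%s (%s, %g)", key$style[i], key$tilts[i], key$step[i]),
      n_success = n, n_total = nrow(ev),
      mean_rgb_similarity = if (n) mean(created$rgb_similarity) else NA_real_,
      mean_ssim = if (n) mean(created$ssim) else NA_real_,
      mean_mae_mm = if (n) mean(created$mae_mm, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Select the best scenario(s) for one specimen
#'
#' Successful models are ranked on RGB similarity (descending), SSIM
#' (descending) and MAE (ascending); the three ranks are averaged and the
#' lowest mean rank wins. Ties are returned as a set. This mean-rank rule is a
#' repository convention for combining texture and geometric accuracy; a
#' weighted score is available via `weights`.
#'
#' @param evaluations See [validate_evaluations()]; rows for one specimen.
#' @param specimen_id Specimen to select for (required when `evaluations`
#'   spans several specimens).
#' @param weights Optional numeric vector `c(rgb, ssim, mae)` of rank weights.
#' @return Data frame of winning rows with a `mean_rank` column.
#' @export
select_best <- function(evaluations, specimen_id = NULL,
                        weights = c(1, 1, 1)) {
  evaluations <- validate_evaluations(evaluations)
  if (!is.null(specimen_id))
    evaluations <- evaluations[evaluations$specimen_id %in% specimen_id, ]
  if (length(unique(evaluations$specimen_id)) != 1L)
    stop("select_best() operates on one specimen; pass specimen_id",
         call. = FALSE)
  ev <- evaluations[evaluations$model_created, ]
  if (nrow(ev) == 0L)
    stop("no successful model for specimen ",
         unique(evaluations$specimen_id), call. = FALSE)
  ranks <- cbind(rank(-ev$rgb_similarity), rank(-ev$ssim), rank(ev$mae_mm))
  mean_rank <- as.numeric(ranks %*% weights) / sum(weights)
  best <- ev[mean_rank == min(mean_rank), , drop = FALSE]
  best$mean_rank <- min(mean_rank)
  rownames(best) <- NULL
  best
}

fmt2 <- function(x) ifelse(is.na(x), EM_DASH, sprintf("%.2f", x))

#' Per-feature MAE table across scenarios
#'
#' Mirrors the per-feature report layout: one row per scenario, one column per
#' morphometric feature, each cell `"MAE (successful/total)"`, with
#' `"N/A (0/n)"` when no measurement of that feature succeeded.
#'
#' @param measurements Measurement data frame (see [read_measurements()])
#'   covering the created models.
#' @return Data frame of formatted strings plus a `label` column.
#' @export
per_feature_mae_table <- function(measurements) {
  measurements <- validate_measurements(measurements)
  key <- unique(measurements[, c("style", "step", "tilts")])
  key <- key[scenario_order_key(key$style, key$step, key$tilts), ]
  out <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sel <- measurements$style == key$style[i] &
      measurements$step == key$step[i] & measurements$tilts == key$tilts[i]
    row <- data.frame(label = sprintf("%s (%s, %g)", key$style[i],
                                      key$tilts[i], key$step[i]),
                      stringsAsFactors = FALSE)
    for (ft in morphometric_features) {
      r <- measurements[sel & measurements$feature == ft, ]
      if (nrow(r) == 0L) {
        row[[ft]] <- "N/A (0/0)"
        next
      }
      fm <- feature_mae(r$reference_mm, r$modeled_mm)
      row[[ft]] <- if (fm$n_success == 0)
        sprintf("N/A (0/%d)", fm$n_total)
      else
        sprintf("%.2f (%d/%d)", fm$mae_mm, fm$n_success, fm$n_total)
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Write the report files for a study evaluation
#'
#' Writes `summary.csv` (per-scenario success counts and mean scores, 2
#' decimals, em dash for empty scenarios), `per_feature_mae.csv` (per-feature
#' MAE with success counts), `summary.json` (full precision),
#' `best_models.csv` (mean-rank winner(s) per specimen) and
#' `failed_models.csv` (planned models that were not created).
#'
#' @param summaries Output of [summarize_scenarios()].
#' @param evaluations See [validate_evaluations()].
#' @param out_dir Output directory, created if missing.
#' @param measurements Optional measurement data frame for the per-feature
#'   table.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(summaries, evaluations, out_dir,
                         measurements = NULL) {
  evaluations <- validate_evaluations(evaluations)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  disp <- data.frame(
    model_parameters = summaries$label,
    n_success = summaries$n_success,
    rgb_similarity = fmt2(summaries$mean_rgb_similarity),
    ssim = fmt2(summaries$mean_ssim),
    mae_mm = fmt2(summaries$mean_mae_mm),
    stringsAsFactors = FALSE
  )
  utils::write.csv(disp, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summaries, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(measurements))
    utils::write.csv(per_feature_mae_table(measurements),
                     file.path(out_dir, "per_feature_mae.csv"),
                     row.names = FALSE)
  best <- do.call(rbind, lapply(unique(evaluations$specimen_id),
                                function(id) {
    ok <- evaluations$model_created[evaluations$specimen_id == id]
    if (!any(ok)) return(NULL)
    select_best(evaluations, id)
  }))
  if (!is.null(best))
    utils::write.csv(best, file.path(out_dir, "best_models.csv"),
                     row.names = FALSE)
  failed <- evaluations[!evaluations$model_created,
                        c("specimen_id", "style", "step", "tilts")]
  utils::write.csv(failed, file.path(out_dir, "failed_models.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
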