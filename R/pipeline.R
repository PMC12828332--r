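# End-to-end pipeline: synthetic study -> image comparison -> geometry ->
# evaluations ready for summarize_scenarios().

#' Score one original/rendered model
#'
#' Prepares each of the three views on a common extent, computes texture
#' scores, averages them into the overall model score, and computes the
#' geometric score from the measurement records.
#'
#' @param specimen A [synthetic_specimen()] (the originals).
#' @param model A [degrade()] result (the renders and modeled measurements).
#' @param params [ssim_params()].
#' @return List with `texture` ([overall_similarity()] result) and `geometry`
#'   (a [geometric_score()]; `NULL` when no measurement records exist).
#' @export
evaluate_model <- function(specimen, model, params = ssim_params()) {
  stopifnot(inherits(specimen, "synthetic_specimen"),
            inherits(model, "rendered_model"))
  scores <- lapply(view_labels, function(vw) {
    pair <- to_common_extent(specimen$views[[vw]], model$views[[vw]])
    texture_score(pair, params)
  })
  texture <- overall_similarity(scores)
  records <- data.frame(
    specimen_id = specimen$specimen_id, style = NA_character_,
    step = NA_real_, tilts = NA_character_,
    feature = morphometric_features,
    reference_mm = unname(specimen$reference_mm),
    modeled_mm = unname(model$modeled_mm),
    stringsAsFactors = FALSE
  )
  list(texture = texture,
       geometry = geometric_score(transform_na_scenario(records)))
}

# geometric_score validates scenario columns; fill placeholders.
transform_na_scenario <- function(records) {
  records$style[is.na(records$style)] <- "NFS"
  records$step[is.na(records$step)] <- base_step_deg
  records$tilts[is.na(records$tilts)] <- "C20-40"
  records
}

#' Evaluate a synthetic study end to end
#'
#' For every created model in the study manifest, regenerates the specimen and
#' its degraded renders from their seeds, compares the three views, and
#' assembles (i) the evaluations table consumed by [summarize_scenarios()] and
#' [select_best()] and (ii) the full measurement table in the
#' [read_measurements()] schema.
#'
#' @param study A [generate_study()] result.
#' @param params [ssim_params()].
#' @param progress Print a dot per model.
#' @return List with `evaluations` and `measurements` data frames.
#' @export
evaluate_study <- function(study, params = ssim_params(), progress = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  cfg <- study$config
  specimens <- study$specimens
  sp_cache <- new.env(parent = emptyenv())
  get_specimen <- function(id) {
    if (is.null(sp_cache[[id]])) {
      i <- match(id, specimens$specimen_id)
      sp_cache[[id]] <- generate_specimen(
        specimens$seed[i], specimens$body_length_mm[i], specimen_id = id,
        height = cfg$height, width = cfg$width)
    }
    sp_cache[[id]]
  }
  scen_by_label <- stats::setNames(cfg$scenarios,
                                   scenario_grid(cfg$scenarios)$label)
  eval_rows <- vector("list", nrow(study$manifest))
  meas_rows <- list()
  for (i in seq_len(nrow(study$manifest))) {
    mf <- study$manifest[i, ]
    row <- data.frame(
      specimen_id = mf$specimen_id, style = mf$style, step = mf$step,
      tilts = mf$tilts, model_created = mf$model_created,
      rgb_similarity = NA_real_, ssim = NA_real_, mae_mm = NA_real_,
      stringsAsFactors = FALSE
    )
    if (mf$model_created) {
      sp <- get_specimen(mf$specimen_id)
      dspec <- scenario_degradation(cfg, scen_by_label[[mf$label]],
                                    mf$model_seed)
      model <- degrade(sp, dspec)
      ev <- evaluate_model(sp, model, params)
      row$rgb_similarity <- ev$texture$overall_similarity
      row$ssim <- ev$texture$overall_ssim
      row$mae_mm <- ev$geometry$overall_mae_mm
      meas_rows[[length(meas_rows) + 1L]] <- data.frame(
        specimen_id = mf$specimen_id, style = mf$style, step = mf$step,
        tilts = mf$tilts, feature = morphometric_features,
        reference_mm = unname(sp$reference_mm),
        modeled_mm = unname(model$modeled_mm),
        stringsAsFactors = FALSE
      )
    }
    eval_rows[[i]] <- row
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  evaluations <- do.call(rbind, eval_rows)
  rownames(evaluations) <- NULL
  measurements <- if (length(meas_rows)) do.call(rbind, meas_rows) else NULL
  if (!is.null(measurements)) rownames(measurements) <- NULL
  list(evaluations = evaluations, measurements = measurements)
}
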