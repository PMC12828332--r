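# Synthetic specimens, render degradations, and full study generation.
#
# The generator emulates the study design the evaluation pipeline was built
# for: masked beetle-like specimen images at three view angles, paired with
# degraded "renders" and reference/modeled morphometric measurement tables.

#' Derive a reproducible sub-seed from a root seed and a label
#'
#' One root seed drives the whole study; every operation (specimen drawing,
#' per-model degradation, success sampling) draws from its own derived stream
#' so stages are independently reproducible. Derived seeds stay below 2^31.
#'
#' @param root Integer root seed.
#' @param tag Character label of the stream.
#' @return Integer seed.
#' @export
derive_seed <- function(root, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((as.numeric(root) * 69069 + h) %% 2147483587)
}

# Distance from every pixel of a (u, v) grid to the segment p0-p1.
seg_dist <- function(u, v, p0, p1) {
  du <- p1[1] - p0[1]; dv <- p1[2] - p0[2]
  len2 <- du^2 + dv^2
  t <- ((u - p0[1]) * du + (v - p0[2]) * dv) / max(len2, 1e-12)
  t[t < 0] <- 0; t[t > 1] <- 1
  sqrt((u - (p0[1] + t * du))^2 + (v - (p0[2] + t * dv))^2)
}

# Default body-length feature proportions for a carabid-like habitus.
feature_proportions <- c(
  elytra_length = 0.58, elytra_width = 0.34,
  antenna_segment_2 = 0.055, antenna_segment_3 = 0.065,
  first_tibia = 0.17, second_tibia = 0.19
)

#' Construct a synthetic specimen
#'
#' @param specimen_id Identifier string.
#' @param body_length_mm Body length (mm), excluding antennae and legs.
#' @param reference_mm Named numeric vector of the six reference measurements
#'   (mm), names from [morphometric_features].
#' @param views Named list (`top`, `center`, `bottom`) of [masked_image()]
#'   objects.
#' @return A `synthetic_specimen`.
#' @export
synthetic_specimen <- function(specimen_id, body_length_mm, reference_mm,
                               views) {
  if (body_length_mm <= 0) stop("body_length_mm must be > 0", call. = FALSE)
  if (!setequal(names(reference_mm), morphometric_features))
    stop("reference_mm must be named by the six morphometric features",
         call. = FALSE)
  if (any(reference_mm <= 0))
    stop("reference measurements must be positive", call. = FALSE)
  if (!setequal(names(views), view_labels))
    stop("views must be a named list: top, center, bottom", call. = FALSE)
  structure(
    list(specimen_id = specimen_id, body_length_mm = body_length_mm,
         reference_mm = reference_mm[morphometric_features],
         views = views[view_labels]),
    class = "synthetic_specimen"
  )
}

#' @export
print.synthetic_specimen <- function(x, ...) {
  cat("<synthetic_specimen>", x$specimen_id, "- body",
      sprintf("%.2f mm,", x$body_length_mm),
      paste(dim(x$views$center$pixels)[1:2], collapse = "x"), "px views\n")
  invisible(x)
}

# Draw one view of the beetle figure. Coordinates (u, v) are vertical /
# horizontal offsets from the body center; tilted views foreshorten the
# figure vertically by cos(view_angle).
draw_beetle_view <- function(height, width, view, view_angle, base_col,
                             speckle) {
  squash <- cos(view_angle * pi / 180)
  cy <- 0.56 * height; cx <- 0.5 * width
  r <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  u <- (r - cy) / squash   # un-foreshortened vertical coordinate
  v <- cc - cx
  a <- 0.30 * height       # body semi-major axis (px)
  b <- 0.33 * a            # body semi-minor axis
  head_r <- 0.16 * a
  body <- (u / a)^2 + (v / b)^2 <= 1
  head <- (u + a + head_r * 0.8)^2 + (v / 0.9)^2 <= head_r^2
  thin <- list()  # antennae + legs as stroked segments
  ant_base <- -(a + head_r * 1.4)
  for (s in c(-1, 1)) {
    thin <- c(thin, list(
      list(p0 = c(ant_base, s * head_r * 0.6),
           p1 = c(ant_base - 0.16 * a, s * 0.30 * a), w = 1.1),
      list(p0 = c(ant_base - 0.16 * a, s * 0.30 * a),
           p1 = c(ant_base - 0.34 * a, s * 0.44 * a), w = 1.1)
    ))
    for (lu in c(-0.55, 0, 0.55) * a) {
      thin <- c(thin, list(
        list(p0 = c(lu, s * (b - 1)),
             p1 = c(lu + 0.18 * a, s * (b + 0.45 * a)), w = 1.6)
      ))
    }
  }
  append_mask <- body | head
  for (sg in thin)
    append_mask <- append_mask | (seg_dist(u, v, sg$p0, sg$p1) <= sg$w)
  # texture: longitudinal elytral striae + dorsal shading + fine speckle
  striae <- 18 * sin(2 * pi * v / 5.5)
  shade <- -22 * (u / a)^2
  px <- array(235, dim = c(height, width, 3))
  for (ch in 1:3) {
    plane <- matrix(base_col[ch], height, width) + striae + shade +
      speckle * 8
    plane[!append_mask] <- 235
    plane[head & !body] <- base_col[ch] * 0.75
    px[, , ch] <- plane
  }
  px[px < 0] <- 0; px[px > 255] <- 255
  masked_image(round(px), append_mask, view = view, view_angle = view_angle)
}

#' Generate a synthetic beetle specimen
#'
#' Renders a beetle-like figure (elliptical body with elytral striae, head,
#' two-segment antennae, six legs) on a plain background at three view angles
#' (center 0 degrees; top and bottom foreshortened by the tilt), with the mask
#' equal to the figure support. The six reference measurements are fixed
#' proportions of body length with seeded multiplicative jitter, so doubling
#' body length doubles every pre-jitter measurement. Fully deterministic given
#' the seed.
#'
#' @param seed Integer seed.
#' @param body_length_mm Body length (mm); must be positive.
#' @param specimen_id Identifier; defaults to a seed-derived label.
#' @param height,width Image size in pixels.
#' @param view_angles Named numeric vector of tilt angles for the `top` and
#'   `bottom` views (degrees).
#' @param measurement_jitter_sd Relative SD of the seeded jitter on the
#'   feature proportions.
#' @return A [synthetic_specimen()].
#' @export
generate_specimen <- function(seed, body_length_mm,
                              specimen_id = sprintf("S%06d", seed),
                              height = 160L, width = 120L,
                              view_angles = c(top = 20, bottom = -20),
                              measurement_jitter_sd = 0.03) {
  if (body_length_mm <= 0) stop("body_length_mm must be > 0", call. = FALSE)
  set.seed(derive_seed(seed, "specimen-appearance"))
  base_col <- 30 + round(stats::runif(3) * 90)
  speckle <- matrix(stats::rnorm(height * width), height, width)
  jit <- 1 + stats::rnorm(length(feature_proportions),
                          sd = measurement_jitter_sd)
  reference <- feature_proportions * body_length_mm * jit
  views <- list(
    top = draw_beetle_view(height, width, "top", view_angles[["top"]],
                           base_col, speckle),
    center = draw_beetle_view(height, width, "center", 0, base_col, speckle),
    bottom = draw_beetle_view(height, width, "bottom", view_angles[["bottom"]],
                              base_col, speckle)
  )
  synthetic_specimen(specimen_id, body_length_mm, reference, views)
}

#' Specify a render degradation
#'
#' Degradations are applied to each original view in a fixed order: Gaussian
#' blur, per-channel intensity shift, additive Gaussian noise, then clamping
#' to 0-255 (order matters for the scores). Modeled measurements are the
#' references scaled by `scale_error` with seeded relative jitter; features in
#' `dropout_features` come back absent, emulating body segments the model
#' failed to reconstruct.
#'
#' @param blur_sigma Gaussian blur SD in pixels, >= 0.
#' @param channel_shift Named numeric vector `c(R=, G=, B=)` of signed
#'   intensity offsets in `[-255, 255]`.
#' @param scale_error Multiplicative factor (> 0) on modeled lengths.
#' @param noise_sd SD of additive Gaussian pixel noise, >= 0.
#' @param dropout_features Subset of [morphometric_features] to report as
#'   absent.
#' @param measurement_jitter_sd Relative SD of measurement jitter.
#' @param seed Integer seed for the noise and jitter streams.
#' @return A `degradation_spec`.
#' @export
degradation_spec <- function(blur_sigma = 0,
                             channel_shift = c(R = 0, G = 0, B = 0),
                             scale_error = 1, noise_sd = 0,
                             dropout_features = character(),
                             measurement_jitter_sd = 0.02, seed = 1L) {
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (scale_error <= 0) stop("scale_error must be > 0", call. = FALSE)
  shift <- channel_shift[c("R", "G", "B")]
  if (any(is.na(shift)) || any(abs(shift) > 255))
    stop("channel_shift must name R, G, B with offsets in [-255, 255]",
         call. = FALSE)
  if (!all(dropout_features %in% morphometric_features))
    stop("unknown dropout feature(s): ",
         paste(setdiff(dropout_features, morphometric_features),
               collapse = ", "), call. = FALSE)
  structure(
    list(blur_sigma = blur_sigma, channel_shift = shift,
         scale_error = scale_error, noise_sd = noise_sd,
         dropout_features = dropout_features,
         measurement_jitter_sd = measurement_jitter_sd,
         seed = as.integer(seed)),
    class = "degradation_spec"
  )
}

# Apply the image part of a degradation to one H x W x 3 array.
degrade_pixels <- function(pixels, dspec, stream_seed) {
  px <- pixels * 1.0
  if (dspec$blur_sigma > 0) {
    for (ch in 1:3)
      px[, , ch] <- EBImage::gblur(px[, , ch], sigma = dspec$blur_sigma)
  }
  for (ch in 1:3) px[, , ch] <- px[, , ch] + dspec$channel_shift[ch]
  if (dspec$noise_sd > 0) {
    set.seed(stream_seed)
    px <- px + array(stats::rnorm(length(px), sd = dspec$noise_sd), dim(px))
  }
  px[px < 0] <- 0; px[px > 255] <- 255
  round(px)
}

#' Degrade a specimen into rendered views and modeled measurements
#'
#' @param specimen A [synthetic_specimen()].
#' @param dspec A [degradation_spec()].
#' @return A `rendered_model`: `views` (named list of degraded
#'   [masked_image()]s, masks unchanged) and `modeled_mm` (named vector, `NA`
#'   for dropped features).
#' @export
degrade <- function(specimen, dspec) {
  stopifnot(inherits(specimen, "synthetic_specimen"),
            inherits(dspec, "degradation_spec"))
  views <- lapply(view_labels, function(vw) {
    im <- specimen$views[[vw]]
    px <- degrade_pixels(im$pixels, dspec,
                         derive_seed(dspec$seed, paste0("noise-", vw)))
    masked_image(px, im$mask, view = vw, view_angle = im$view_angle)
  })
  names(views) <- view_labels
  set.seed(derive_seed(dspec$seed, "measurement-jitter"))
  jit <- 1 + stats::rnorm(length(morphometric_features),
                          sd = dspec$measurement_jitter_sd)
  modeled <- specimen$reference_mm * dspec$scale_error * jit
  modeled[morphometric_features %in% dspec$dropout_features] <- NA_real_
  structure(list(views = views, modeled_mm = modeled, spec = dspec),
            class = "rendered_model")
}

#' Study configuration for the synthetic generator
#'
#' Defaults emulate the acquisition study the pipeline targets: ten specimens
#' spanning body lengths 2.75-23.96 mm, the full 18-scenario grid, and a
#' degradation ladder whose severity grows with the horizontal step, with
#' fewer tilt rings, and with focus stacking. Model-creation success is
#' sampled from a logistic model in severity and log-body-size deviation, so
#' sparse imaging and extreme sizes fail more often. An identity ladder
#' (`identity = TRUE`) zeroes every degradation, forces success, and is the
#' ground-truth configuration for end-to-end pipeline checks.
#'
#' @param n_specimens Number of specimens.
#' @param body_length_mm Body lengths (mm), recycled/truncated to
#'   `n_specimens`.
#' @param scenarios List of [imaging_scenario()]s.
#' @param seed Root seed for every stream in the study.
#' @param height,width Image size (pixels).
#' @param base_blur,base_shift,base_noise Degradation scale at severity 1:
#'   blur sigma (px), channel shift (intensity), noise SD (intensity).
#' @param base_scale_error Relative measurement scale error at severity 1.
#' @param dropout_rate Per-feature dropout probability at severity 1 (fine
#'   features only: antenna segments and tibiae).
#' @param measurement_jitter_sd Relative SD of modeled-measurement jitter.
#' @param success_intercept,success_severity,success_size Logistic
#'   coefficients of the model-creation probability.
#' @param identity If `TRUE`, all degradations are zero and every model is
#'   created.
#' @return A `study_config` list.
#' @export
study_config <- function(n_specimens = 10L,
                         body_length_mm = c(12.20, 15.85, 18.65, 23.96, 10.54,
                                            2.75, 13.69, 13.58, 13.98, 6.70),
                         scenarios = enumerate_scenarios(),
                         seed = 20260922L,
                         height = 160L, width = 120L,
                         base_blur = 1.2, base_shift = 8, base_noise = 5,
                         base_scale_error = 0.03, dropout_rate = 0.12,
                         measurement_jitter_sd = 0.02,
                         success_intercept = 3.2, success_severity = 2.0,
                         success_size = 2.2,
                         identity = FALSE) {
  body_length_mm <- rep_len(body_length_mm, n_specimens)
  structure(
    list(n_specimens = as.integer(n_specimens),
         body_length_mm = body_length_mm, scenarios = scenarios,
         seed = as.integer(seed), height = as.integer(height),
         width = as.integer(width),
         base_blur = base_blur, base_shift = base_shift,
         base_noise = base_noise, base_scale_error = base_scale_error,
         dropout_rate = dropout_rate,
         measurement_jitter_sd = measurement_jitter_sd,
         success_intercept = success_intercept,
         success_severity = success_severity, success_size = success_size,
         identity = identity),
    class = "study_config"
  )
}

#' Degradation severity of a scenario
#'
#' Severity in roughly `[0, 1.15]`: grows with the horizontal decimation
#' factor (0, 0.3, 0.6 for steps 11.25/22.5/33.75), with the drop from five to
#' three tilt rings (+0.25), and with focus stacking (+0.3, emulating the
#' texture distortion stacking artifacts introduce).
#'
#' @param scenario An [imaging_scenario()].
#' @return Numeric severity.
#' @export
scenario_severity <- function(scenario) {
  m <- scenario$horizontal_step / base_step_deg
  0.3 * (m - 1) + 0.25 * (5 - length(scenario$tilts)) / 2 +
    0.3 * (scenario$style == "FS")
}

scenario_degradation <- function(config, scenario, model_seed) {
  sev <- scenario_severity(scenario)
  if (config$identity) sev <- 0
  drop_feats <- character()
  if (!config$identity && config$dropout_rate > 0) {
    fine <- c("antenna_segment_2", "antenna_segment_3",
              "first_tibia", "second_tibia")
    set.seed(derive_seed(model_seed, "dropout"))
    drop_feats <- fine[stats::runif(length(fine)) < config$dropout_rate * sev]
  }
  degradation_spec(
    blur_sigma = config$base_blur * sev,
    channel_shift = c(R = config$base_shift * sev,
                      G = -config$base_shift * sev * 0.5,
                      B = config$base_shift * sev * 0.75),
    scale_error = 1 + config$base_scale_error * sev,
    noise_sd = config$base_noise * sev,
    dropout_features = drop_feats,
    measurement_jitter_sd = if (config$identity) 0
                            else config$measurement_jitter_sd,
    seed = model_seed
  )
}

#' Generate a synthetic acquisition study
#'
#' Lays out the full specimen x scenario design (default 10 x 18 = 180
#' planned models), assigns each model its degradation and a seeded
#' model-creation outcome, and returns a manifest; images are regenerated on
#' demand by [evaluate_study()] rather than held in memory. With `out_dir`
#' set, the manifest (JSON), the specimen table and the reference-measurement
#' CSV are written; `write_images = TRUE` additionally writes original/mask
#' PNGs per specimen and view.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param write_images Write per-view original and mask PNGs (only sensible
#'   for small configurations).
#' @return A `synthetic_study`: `config`, `specimens` data frame
#'   (`specimen_id`, `body_length_mm`, `seed`), `reference` measurement data
#'   frame, and the `manifest` data frame (one row per planned model with
#'   scenario, severity, `model_seed`, `model_created`).
#' @export
generate_study <- function(config = study_config(), out_dir = NULL,
                           write_images = FALSE) {
  stopifnot(inherits(config, "study_config"))
  ids <- sprintf("SP%02d", seq_len(config$n_specimens))
  specimens <- data.frame(
    specimen_id = ids, body_length_mm = config$body_length_mm,
    seed = vapply(ids, function(id) derive_seed(config$seed,
                                                paste0("specimen-", id)),
                  integer(1)),
    stringsAsFactors = FALSE
  )
  grid <- scenario_grid(config$scenarios)
  med_len <- stats::median(config$body_length_mm)
  rows <- list()
  for (i in seq_len(nrow(specimens))) {
    sp <- specimens[i, ]
    size_dev <- abs(log(sp$body_length_mm / med_len))
    for (j in seq_along(config$scenarios)) {
      sc <- config$scenarios[[j]]
      sev <- scenario_severity(sc)
      model_seed <- derive_seed(config$seed,
                                paste0("model-", sp$specimen_id, "-",
                                       grid$label[j]))
      if (config$identity) {
        created <- TRUE
      } else {
        p <- stats::plogis(config$success_intercept -
                             config$success_severity * sev -
                             config$success_size * size_dev)
        set.seed(derive_seed(model_seed, "success"))
        created <- stats::runif(1) < p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = sp$specimen_id, style = grid$style[j],
        step = grid$step[j], tilts = grid$tilts[j], label = grid$label[j],
        severity = if (config$identity) 0 else sev,
        model_seed = model_seed, model_created = created,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  reference <- do.call(rbind, lapply(seq_len(nrow(specimens)), function(i) {
    sp <- generate_specimen(specimens$seed[i], specimens$body_length_mm[i],
                            specimen_id = specimens$specimen_id[i],
                            height = config$height, width = config$width)
    data.frame(specimen_id = specimens$specimen_id[i],
               feature = morphometric_features,
               reference_mm = unname(sp$reference_mm),
               stringsAsFactors = FALSE)
  }))
  study <- structure(
    list(config = config, specimens = specimens, reference = reference,
         manifest = manifest),
    class = "synthetic_study"
  )
  if (!is.null(out_dir)) write_study(study, out_dir, write_images)
  study
}

write_study <- function(study, out_dir, write_images = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$specimens, file.path(out_dir, "specimens.csv"),
                   row.names = FALSE)
  utils::write.csv(study$reference, file.path(out_dir, "reference_mm.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (write_images) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(study$specimens))) {
      sp <- generate_specimen(study$specimens$seed[i],
                              study$specimens$body_length_mm[i],
                              specimen_id = study$specimens$specimen_id[i],
                              height = study$config$height,
                              width = study$config$width)
      for (vw in view_labels) {
        stem <- file.path(img_dir, paste0(sp$specimen_id, "_", vw))
        png::writePNG(sp$views[[vw]]$pixels / 255, paste0(stem, ".png"))
        png::writePNG(sp$views[[vw]]$mask * 1, paste0(stem, "_mask.png"))
      }
    }
  }
  invisible(out_dir)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", nrow(x$specimens), "specimens x",
      length(x$config$scenarios), "scenarios =", nrow(x$manifest),
      "planned models (", sum(x$manifest$model_created), "created )\n")
  invisible(x)
}
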