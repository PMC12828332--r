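# Shared fixture builders and independent oracles.

# Build a masked_image with constant per-channel values.
flat_image <- function(h, w, rgb, mask = matrix(TRUE, h, w),
                       view = "center", view_angle = 0) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  masked_image(px, mask, view = view, view_angle = view_angle)
}

# Build a masked_image from explicit per-channel matrices.
image_from_channels <- function(R, G, B, mask = NULL, view = "center",
                                view_angle = 0) {
  h <- nrow(R); w <- ncol(R)
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- R; px[, , 2] <- G; px[, , 3] <- B
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  masked_image(px, mask, view = view, view_angle = view_angle)
}

# Prepared pair of two flat images over a full-frame mask.
flat_pair <- function(h, w, rgb_a, rgb_b, view = "center") {
  to_common_extent(flat_image(h, w, rgb_a, view = view),
                   flat_image(h, w, rgb_b, view = view))
}

# Independent oracle: percent channel similarity by explicit double loop.
naive_channel_similarity <- function(a, b, mask) {
  total <- 0; n <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        total <- total + abs(a[i, j] - b[i, j])
        n <- n + 1
      }
    }
  }
  (1 - total / (255 * n)) * 100
}

# Random 8-bit image pair of the same size, prepared on a full mask.
random_pair <- function(h, w, seed) {
  set.seed(seed)
  a <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  b <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  to_common_extent(masked_image(a, matrix(TRUE, h, w)),
                   masked_image(b, matrix(TRUE, h, w)))
}

# A small measurement data frame for one specimen x scenario.
meas_df <- function(reference, modeled,
                    feature = morphometric_features[seq_along(reference)],
                    specimen_id = "SP01", style = "NFS", step = 11.25,
                    tilts = "C20-40") {
  data.frame(specimen_id = specimen_id, style = style, step = step,
             tilts = tilts, feature = feature, reference_mm = reference,
             modeled_mm = modeled, stringsAsFactors = FALSE)
}

# One evaluations row.
eval_row <- function(specimen_id, style, step, tilts, created = TRUE,
                     rgb = 96, ssim = 0.9, mae = 0.2) {
  data.frame(specimen_id = specimen_id, style = style, step = step,
             tilts = tilts, model_created = created,
             rgb_similarity = if (created) rgb else NA_real_,
             ssim = if (created) ssim else NA_real_,
             mae_mm = if (created) mae else NA_real_,
             stringsAsFactors = FALSE)
}
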