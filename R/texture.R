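# Texture-accuracy metrics: per-channel difference maps, percent RGB
# similarity, SSIM, and thresholded difference highlights.

channel_names <- c("R", "G", "B")

#' Per-channel absolute difference map
#'
#' For channel C the difference at pixel (i, j) is
#' `delta_C(i,j) = |A_C(i,j) - B_C(i,j)|`, computed inside the common mask and
#' zero outside. Arithmetic is done in doubles, so 8-bit wraparound cannot
#' occur.
#'
#' @param pair An [to_common_extent()] image pair.
#' @param channel `"R"`, `"G"` or `"B"`.
#' @return A `channel_difference`: the `delta` matrix, the `channel`, and
#'   `n_pixels`, the number of compared (mask) pixels.
#' @export
channel_difference <- function(pair, channel) {
  if (!inherits(pair, "image_pair"))
    stop("pair must be an image_pair prepared by to_common_extent()",
         call. = FALSE)
  channel <- match.arg(channel, channel_names)
  ch <- match(channel, channel_names)
  delta <- matrix(abs(pair$original[, , ch] - pair$rendered[, , ch]),
                  nrow(pair$common_mask), ncol(pair$common_mask))
  delta[!pair$common_mask] <- 0
  structure(
    list(channel = channel, delta = delta, n_pixels = pair$n_pixels,
         mask = pair$common_mask),
    class = "channel_difference"
  )
}

#' Percent similarity of one channel
#'
#' `(1 - sum(delta) / (255 * n_pixels)) * 100`, the sum running over mask
#' pixels only. `255 * n_pixels` is the maximum possible total difference, so
#' identical channels score 100 and maximally different channels score 0.
#' The denominator counts specimen (mask) pixels, not the full frame:
#' masking exists to remove background bias, and counting zeroed background
#' would inflate similarity.
#'
#' @param diff A [channel_difference()].
#' @return Percent similarity in `[0, 100]`.
#' @export
channel_similarity <- function(diff) {
  if (!inherits(diff, "channel_difference"))
    stop("diff must be a channel_difference", call. = FALSE)
  if (diff$n_pixels <= 0)
    stop("similarity undefined: no compared pixels", call. = FALSE)
  (1 - sum(diff$delta[diff$mask]) / (255 * diff$n_pixels)) * 100
}

#' Percent RGB similarity of an image pair
#'
#' Per-channel percent similarities and their arithmetic mean,
#' `Similarity_RGB = mean(Similarity_R, Similarity_G, Similarity_B)`.
#'
#' @param pair An [to_common_extent()] image pair.
#' @return A `texture_score` with `per_channel_similarity` (named vector),
#'   `rgb_similarity`, `ssim` (`NA`, see [texture_score()]), and the `view`.
#' @export
rgb_similarity <- function(pair) {
  per <- vapply(channel_names,
                function(ch) channel_similarity(channel_difference(pair, ch)),
                numeric(1))
  structure(
    list(per_channel_similarity = per, rgb_similarity = mean(per),
         ssim = NA_real_, view = pair$view),
    class = "texture_score"
  )
}

#' Full texture score for one view
#'
#' Percent RGB similarity plus SSIM for a prepared pair.
#'
#' @inheritParams rgb_similarity
#' @param params [ssim_params()].
#' @return A `texture_score` with `per_channel_similarity`, `rgb_similarity`,
#'   `ssim` and `view`.
#' @export
texture_score <- function(pair, params = ssim_params()) {
  out <- rgb_similarity(pair)
  out$ssim <- ssim(pair, params)
  out
}

#' @export
print.texture_score <- function(x, ...) {
  cat(sprintf("<texture_score> view %s: RGB %.2f%% (R %.2f, G %.2f, B %.2f), SSIM %s\n",
              x$view, x$rgb_similarity, x$per_channel_similarity["R"],
              x$per_channel_similarity["G"], x$per_channel_similarity["B"],
              ifelse(is.na(x$ssim), "NA", sprintf("%.2f", x$ssim))))
  invisible(x)
}

#' Overall (per-model) texture score from the three views
#'
#' Averages the per-view RGB similarities across the top, center and bottom
#' views: `Overall = mean(RGB_top, RGB_center, RGB_bottom)`; the same rule is
#' applied to SSIM. Exactly one score per view is required.
#'
#' @param views List of three `texture_score` objects, one per view label,
#'   in any order.
#' @return A `model_texture_score` with `per_view` (named by view),
#'   `overall_similarity` and `overall_ssim`.
#' @export
overall_similarity <- function(views) {
  if (!is.list(views) || !all(vapply(views, inherits, logical(1),
                                     "texture_score")))
    stop("views must be a list of texture_score objects", call. = FALSE)
  labs <- vapply(views, `[[`, character(1), "view")
  if (!setequal(labs, view_labels) || length(labs) != 3L)
    stop("need exactly one score per view (top, center, bottom); got: ",
         paste(labs, collapse = ", "), call. = FALSE)
  names(views) <- labs
  views <- views[view_labels]
  structure(
    list(per_view = views,
         overall_similarity = mean(vapply(views, `[[`, numeric(1),
                                          "rgb_similarity")),
         overall_ssim = mean(vapply(views, `[[`, numeric(1), "ssim"))),
    class = "model_texture_score"
  )
}

#' @export
print.model_texture_score <- function(x, ...) {
  cat(sprintf("<model_texture_score> overall RGB %.2f%%, overall SSIM %s\n",
              x$overall_similarity,
              ifelse(is.na(x$overall_ssim), "NA",
                     sprintf("%.2f", x$overall_ssim))))
  invisible(x)
}

#' SSIM parameters
#'
#' Defaults follow the standard Wang et al. formulation: dynamic range
#' `L = 255`, stabilizers `k1 = 0.01`, `k2 = 0.03` (so `C1 = (k1 L)^2`,
#' `C2 = (k2 L)^2`), and an 11 x 11 Gaussian window with sigma 1.5, applied to
#' Rec. 601 luminance.
#'
#' @param L Dynamic range of the intensities.
#' @param k1,k2 Unitless stabilizer constants; must give `C2 > 0`.
#' @param window Odd window size in pixels.
#' @param window_kind `"gaussian"` (sigma 1.5) or `"uniform"`.
#' @param per_channel If `TRUE`, SSIM is computed on each RGB channel and
#'   averaged instead of on luminance.
#' @return An `ssim_params` list.
#' @export
ssim_params <- function(L = 255, k1 = 0.01, k2 = 0.03, window = 11L,
                        window_kind = c("gaussian", "uniform"),
                        per_channel = FALSE) {
  window_kind <- match.arg(window_kind)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (k2 <= 0) stop("k2 must be positive (C2 > 0)", call. = FALSE)
  structure(list(L = L, k1 = k1, k2 = k2, window = window,
                 window_kind = window_kind, per_channel = per_channel),
            class = "ssim_params")
}

ssim_window <- function(params) {
  if (params$window_kind == "gaussian") {
    w <- EBImage::makeBrush(params$window, shape = "gaussian", sigma = 1.5)
  } else {
    w <- matrix(1, params$window, params$window)
  }
  w / sum(w)
}

# SSIM map for two equally-sized intensity matrices on [0, L].
ssim_map <- function(x, y, params) {
  w <- ssim_window(params)
  f <- function(m) EBImage::filter2(m, w, boundary = "replicate")
  mux <- f(x); muy <- f(y)
  sxx <- pmax(f(x * x) - mux^2, 0)
  syy <- pmax(f(y * y) - muy^2, 0)
  sxy <- f(x * y) - mux * muy
  C1 <- (params$k1 * params$L)^2
  C2 <- (params$k2 * params$L)^2
  ((2 * mux * muy + C1) * (2 * sxy + C2)) /
    ((mux^2 + muy^2 + C1) * (sxx + syy + C2))
}

#' Structural similarity index of an image pair
#'
#' Images are converted to Rec. 601 luminance (0.299 R + 0.587 G + 0.114 B),
#' local means, variances and covariance are computed over a sliding window,
#' the SSIM equation
#' `(2 mu_x mu_y + C1)(2 sigma_xy + C2) / ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' is evaluated per window, and the result is the mean over windows whose
#' center lies in the common mask. SSIM lies in `[-1, 1]`; 1 means perfect
#' similarity. With `per_channel = TRUE` the map is computed per RGB channel
#' and the three masked means averaged.
#'
#' @inheritParams rgb_similarity
#' @param params [ssim_params()].
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(pair, params = ssim_params()) {
  if (!inherits(pair, "image_pair"))
    stop("pair must be an image_pair prepared by to_common_extent()",
         call. = FALSE)
  d <- dim(pair$common_mask)
  if (params$window > min(d))
    stop("SSIM window (", params$window, ") exceeds cropped image extent (",
         paste(d, collapse = "x"), ")", call. = FALSE)
  if (params$per_channel) {
    vals <- vapply(1:3, function(ch) {
      m <- ssim_map(pair$original[, , ch], pair$rendered[, , ch], params)
      mean(m[pair$common_mask])
    }, numeric(1))
    return(mean(vals))
  }
  lum <- function(px) 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  m <- ssim_map(lum(pair$original), lum(pair$rendered), params)
  mean(m[pair$common_mask])
}

#' Thresholded difference highlight
#'
#' Per-pixel maximum over the three channel difference maps, with values less
#' than or equal to the threshold set to zero, so only differences strictly
#' exceeding the threshold survive. The default threshold of 30 suppresses
#' noise and leaves only regions of significant error; the brightest surviving
#' pixels mark the largest differences.
#'
#' @inheritParams rgb_similarity
#' @param threshold Intensity threshold in `[0, 255]`.
#' @param combine How to collapse the three channel maps: `"max"` (most
#'   sensitive, default) or `"mean"`.
#' @return A `difference_highlight` with the `threshold` and the `highlight`
#'   matrix.
#' @export
difference_highlight <- function(pair, threshold = 30,
                                 combine = c("max", "mean")) {
  if (!inherits(pair, "image_pair"))
    stop("pair must be an image_pair", call. = FALSE)
  combine <- match.arg(combine)
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]", call. = FALSE)
  deltas <- lapply(channel_names,
                   function(ch) channel_difference(pair, ch)$delta)
  comb <- if (combine == "max") pmax(deltas[[1]], deltas[[2]], deltas[[3]])
          else (deltas[[1]] + deltas[[2]] + deltas[[3]]) / 3
  comb[comb <= threshold] <- 0
  structure(list(threshold = threshold, highlight = comb, combine = combine),
            class = "difference_highlight")
}

#' Write a difference highlight as a single-channel PNG
#'
#' @param highlight A [difference_highlight()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_highlight_png <- function(highlight, path) {
  stopifnot(inherits(highlight, "difference_highlight"))
  png::writePNG(highlight$highlight / 255, path)
  invisible(path)
}
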