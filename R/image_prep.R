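# Loading masked image pairs and clipping them to a common extent.

view_labels <- c("top", "center", "bottom")
view_angles_allowed <- c(-40, -20, 0, 20, 40)

#' Construct a masked specimen image
#'
#' Pixels are an `H x W x 3` array of 8-bit intensities (0-255); the mask is a
#' logical `H x W` matrix marking specimen pixels. Row-major convention with
#' origin at the top-left.
#'
#' @param pixels Numeric or integer `H x W x 3` array, integer values in
#'   0-255.
#' @param mask Logical (or 0/1) `H x W` matrix with at least one `TRUE` pixel.
#' @param view One of `"top"`, `"center"`, `"bottom"`.
#' @param view_angle Camera tilt in degrees, one of -40, -20, 0, 20, 40.
#' @return A `masked_image` object.
#' @export
masked_image <- function(pixels, mask, view = "center", view_angle = 0) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  if (any(is.na(pixels)) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  if (any(abs(pixels - round(pixels)) > 1e-9))
    stop("pixels must be 8-bit integers (integer-valued in 0-255)",
         call. = FALSE)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(pixels)[1:2]))
    stop("mask dimensions (", paste(dim(mask), collapse = "x"),
         ") do not match image dimensions (",
         paste(dim(pixels)[1:2], collapse = "x"), ")", call. = FALSE)
  mask <- mask > 0
  if (!any(mask))
    stop("mask is empty: no specimen pixels", call. = FALSE)
  view <- match.arg(view, view_labels)
  if (!view_angle %in% view_angles_allowed)
    stop("view_angle must be one of ",
         paste(view_angles_allowed, collapse = ", "), call. = FALSE)
  structure(
    list(pixels = round(pixels), mask = mask, view = view,
         view_angle = view_angle),
    class = "masked_image"
  )
}

#' @export
print.masked_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<masked_image>", d[1], "x", d[2], "RGB,", sum(x$mask),
      "mask px, view", x$view, sprintf("(%+g deg)\n", x$view_angle))
  invisible(x)
}

# Read an image file into an H x W x 3 array scaled to 0-255 integers.
# PNG goes through the png package; other formats through EBImage.
read_rgb_255 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    # EBImage stores x (width) first; transpose to row-major H x W
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  }
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Load an image and its binary mask from files
#'
#' The image must decode to 3-channel 8-bit RGB; the mask to a single channel,
#' binarized at the midpoint (values >= 128 are specimen). PNG and JPEG are
#' supported.
#'
#' @param image_path Path to the RGB image.
#' @param mask_path Path to the single-channel mask image.
#' @inheritParams masked_image
#' @return A [masked_image()].
#' @export
load_masked_image <- function(image_path, mask_path, view = "center",
                              view_angle = 0) {
  px <- read_rgb_255(image_path)
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("image is not 3-channel RGB: ", image_path, call. = FALSE)
  mk <- read_rgb_255(mask_path)
  if (length(dim(mk)) == 3L) {
    if (any(mk[, , 1] != mk[, , 2]) || any(mk[, , 1] != mk[, , 3]))
      stop("mask is not single-channel: ", mask_path, call. = FALSE)
    mk <- mk[, , 1]
  }
  masked_image(px, mk >= 128, view = view, view_angle = view_angle)
}

mask_bbox <- function(mask) {
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  list(r0 = rows[1], r1 = rows[2], c0 = cols[1], c1 = cols[2])
}

#' Prepare an original/rendered pair on a common extent
#'
#' The common mask is the intersection of the two specimen masks, so every
#' compared location holds specimen pixels in both images. Both rasters are
#' cropped to the tight bounding box of the common mask and the background
#' (outside the common mask) is zeroed. All similarity computations are
#' restricted to the common mask, so the background fill never enters a score.
#'
#' @param original,rendered [masked_image()] objects with identical pixel
#'   dimensions.
#' @param resize If `TRUE`, a rendered image whose dimensions differ from the
#'   original is bilinearly resized to match before masking. Off by default
#'   because silent resampling changes scores.
#' @return An `image_pair`: cropped `original` and `rendered` arrays, the
#'   logical `common_mask`, `n_pixels` compared, and the view label.
#' @export
to_common_extent <- function(original, rendered, resize = FALSE) {
  stopifnot(inherits(original, "masked_image"),
            inherits(rendered, "masked_image"))
  do <- dim(original$pixels)[1:2]
  dr <- dim(rendered$pixels)[1:2]
  if (!all(do == dr)) {
    if (!resize)
      stop("image dimensions differ (", paste(do, collapse = "x"), " vs ",
           paste(dr, collapse = "x"), "); pass resize = TRUE to resample ",
           "the rendered image", call. = FALSE)
    rp <- EBImage::resize(EBImage::Image(aperm(rendered$pixels / 255,
                                               c(2, 1, 3)),
                                         colormode = "Color"),
                          w = do[2], h = do[1])
    rpx <- round(aperm(EBImage::imageData(rp), c(2, 1, 3)) * 255)
    rpx[rpx < 0] <- 0; rpx[rpx > 255] <- 255
    rmk <- EBImage::resize(EBImage::Image(t(rendered$mask * 1)),
                           w = do[2], h = do[1]) |>
      EBImage::imageData() |> t()
    rendered <- masked_image(rpx, rmk >= 0.5, rendered$view,
                             rendered$view_angle)
  }
  common <- original$mask & rendered$mask
  if (!any(common))
    stop("specimen masks do not overlap: empty intersection", call. = FALSE)
  bb <- mask_bbox(common)
  crop <- function(px) px[bb$r0:bb$r1, bb$c0:bb$c1, , drop = FALSE]
  cm <- common[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE]
  zero_bg <- function(px) {
    for (ch in 1:3) {
      plane <- matrix(px[, , ch], nrow(cm), ncol(cm))
      plane[!cm] <- 0
      px[, , ch] <- plane
    }
    px
  }
  structure(
    list(original = zero_bg(crop(original$pixels)),
         rendered = zero_bg(crop(rendered$pixels)),
         common_mask = cm, n_pixels = sum(cm), view = original$view),
    class = "image_pair"
  )
}

#' @export
print.image_pair <- function(x, ...) {
  d <- dim(x$original)
  cat("<image_pair>", d[1], "x", d[2], "crop,", x$n_pixels,
      "compared pixels, view", x$view, "\n")
  invisible(x)
}
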