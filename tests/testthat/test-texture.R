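test_that("channel difference maps are exact element-wise |A - B|", {
  A <- matrix(c(0, 20, 10, 30), 2, 2)  # column-major: [[0,10],[20,30]]
  pair <- to_common_extent(
    image_from_channels(A, A, A),
    image_from_channels(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  )
  d <- channel_difference(pair, "R")
  expect_equal(d$delta, A)
  expect_equal(d$n_pixels, 4)
  # identical images: all-zero delta; opposite extremes: 255 everywhere
  same <- flat_pair(3, 3, c(7, 8, 9), c(7, 8, 9))
  expect_true(all(channel_difference(same, "G")$delta == 0))
  extreme <- flat_pair(3, 3, c(255, 255, 255), c(0, 0, 0))
  expect_true(all(channel_difference(extreme, "B")$delta == 255))
  expect_error(channel_difference(list(), "R"), "image_pair")
})

test_that("percent channel similarity matches hand arithmetic", {
  A <- matrix(c(0, 20, 10, 30), 2, 2)
  pair <- to_common_extent(
    image_from_channels(A, A, A),
    image_from_channels(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  )
  expect_equal(channel_similarity(channel_difference(pair, "R")),
               (1 - 60 / 1020) * 100)
  same <- flat_pair(4, 4, c(50, 60, 70), c(50, 60, 70))
  expect_equal(channel_similarity(channel_difference(same, "R")), 100)
  extreme <- flat_pair(4, 4, c(255, 255, 255), c(0, 0, 0))
  expect_equal(channel_similarity(channel_difference(extreme, "R")), 0)
})

test_that("similarity denominator counts mask pixels only", {
  h <- 10; w <- 10
  m <- matrix(FALSE, h, w); m[3:6, 3:6] <- TRUE   # 16 specimen pixels
  a <- flat_image(h, w, c(100, 100, 100), mask = m)
  b <- flat_image(h, w, c(151, 100, 100), mask = m)
  pair <- to_common_extent(a, b)
  expect_equal(pair$n_pixels, 16)
  expect_equal(channel_similarity(channel_difference(pair, "R")),
               (1 - 51 / 255) * 100)
})

test_that("RGB similarity averages the three channels", {
  # per-channel deltas 0 / 25.5 -> impossible (non-integer); use 0, 51, 102:
  # sims 100, 80, 60 -> mean 80
  pair <- flat_pair(5, 5, c(100, 100, 100), c(100, 151, 202))
  ts <- rgb_similarity(pair)
  expect_equal(unname(ts$per_channel_similarity), c(100, 80, 60))
  expect_equal(ts$rgb_similarity, 80)
  # same permutation of channels applied to both images leaves it unchanged
  perm <- flat_pair(5, 5, c(100, 100, 100)[c(2, 3, 1)],
                    c(100, 151, 202)[c(2, 3, 1)])
  expect_equal(rgb_similarity(perm)$rgb_similarity, ts$rgb_similarity)
})

test_that("production similarity matches the double-loop oracle exactly", {
  set.seed(402)
  for (h in 1:3) for (w in 1:3) {
    for (rep in 1:3) {
      a <- array(sample(0:255, h * w * 3, TRUE), c(h, w, 3))
      b <- array(sample(0:255, h * w * 3, TRUE), c(h, w, 3))
      mask <- matrix(TRUE, h, w)
      pair <- to_common_extent(masked_image(a, mask), masked_image(b, mask))
      for (ch in 1:3) {
        got <- channel_similarity(channel_difference(pair, c("R", "G", "B")[ch]))
        expect_identical(got, naive_channel_similarity(matrix(a[, , ch], h, w),
                                                       matrix(b[, , ch], h, w),
                                                       mask))
      }
    }
  }
})

test_that("overall similarity averages the three views and checks labels", {
  mk_score <- function(view, rgb, ss = 0.9) {
    structure(list(per_channel_similarity = c(R = rgb, G = rgb, B = rgb),
                   rgb_similarity = rgb, ssim = ss, view = view),
              class = "texture_score")
  }
  views <- list(mk_score("top", 96, 0.8), mk_score("center", 97, 0.9),
                mk_score("bottom", 98, 1.0))
  ms <- overall_similarity(views)
  expect_equal(ms$overall_similarity, 97)
  expect_equal(ms$overall_ssim, 0.9)
  # symmetric in input order
  expect_equal(overall_similarity(rev(views))$overall_similarity, 97)
  # idempotent on identical views
  expect_equal(overall_similarity(list(mk_score("top", 95),
                                       mk_score("center", 95),
                                       mk_score("bottom", 95)))$overall_similarity,
               95)
  expect_error(overall_similarity(views[1:2]), "one score per view")
  expect_error(overall_similarity(c(views[1:2], views[1])),
               "one score per view")
})

test_that("SSIM hits its closed forms and stays in range", {
  # identical images: 1 to floating tolerance
  p <- random_pair(24, 24, 31)
  same <- to_common_extent(masked_image(p$original, p$common_mask),
                           masked_image(p$original, p$common_mask))
  expect_equal(ssim(same), 1, tolerance = 1e-12)
  # constant 0 vs constant 255: sigma = 0, so SSIM = C1 / (255^2 + C1)
  black_white <- flat_pair(15, 15, c(0, 0, 0), c(255, 255, 255))
  expect_equal(ssim(black_white), 6.5025 / 65031.5025, tolerance = 1e-9)
  # symmetry and range on random fixtures
  for (seed in c(1, 2, 3)) {
    pr <- random_pair(20, 18, seed)
    rv <- to_common_extent(masked_image(pr$rendered, pr$common_mask),
                           masked_image(pr$original, pr$common_mask))
    s1 <- ssim(pr); s2 <- ssim(rv)
    expect_equal(s1, s2, tolerance = 1e-12)
    expect_true(s1 >= -1 && s1 <= 1)
  }
  expect_error(ssim(flat_pair(5, 5, c(0, 0, 0), c(1, 1, 1))), "window")
  expect_error(ssim_params(window = 10), "odd")
})

test_that("per-channel SSIM agrees with luminance SSIM on gray images", {
  g1 <- matrix(sample(0:255, 20 * 20, TRUE), 20, 20)
  g2 <- matrix(sample(0:255, 20 * 20, TRUE), 20, 20)
  pair <- to_common_extent(image_from_channels(g1, g1, g1),
                           image_from_channels(g2, g2, g2))
  expect_equal(ssim(pair, ssim_params(per_channel = TRUE)), ssim(pair),
               tolerance = 1e-9)
})

test_that("difference highlights keep only strict exceedances", {
  # deltas 29, 30, 31 at threshold 30: only 31 survives
  A <- matrix(c(29, 30, 31, 0), 2, 2)
  pair <- to_common_extent(
    image_from_channels(A, matrix(0, 2, 2), matrix(0, 2, 2)),
    image_from_channels(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  )
  hl <- difference_highlight(pair, 30)
  expect_equal(sum(hl$highlight > 0), 1)
  expect_equal(hl$highlight[A == 31], 31)
  # all deltas at the threshold: empty highlight
  at30 <- flat_pair(4, 4, c(130, 130, 130), c(100, 100, 100))
  expect_true(all(difference_highlight(at30, 30)$highlight == 0))
  # single pixel above
  B <- matrix(0, 3, 3); B[2, 2] <- 40
  one <- to_common_extent(
    image_from_channels(B, matrix(0, 3, 3), matrix(0, 3, 3)),
    image_from_channels(matrix(0, 3, 3), matrix(0, 3, 3), matrix(0, 3, 3))
  )
  h1 <- difference_highlight(one, 30)
  expect_equal(sum(h1$highlight > 0), 1)
  expect_equal(h1$highlight[2, 2], 40)
  expect_error(difference_highlight(one, 300), "255")
  # channel combination is the per-pixel max by default
  mixed <- flat_pair(3, 3, c(100, 100, 100), c(140, 110, 100))
  expect_true(all(difference_highlight(mixed, 30)$highlight == 40))
  path <- withr::local_tempfile(fileext = ".png")
  write_highlight_png(h1, path)
  expect_true(file.exists(path))
})
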