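test_that("arc masks match brute-force per-pixel membership", {
  roi <- arc_roi("blue", radius = 4, width = 2, theta = 10, span = 120)
  shape <- c(24, 32); mm <- 0.375; origin <- c(1.5, -4.5)
  m <- arc_roi_mask(roi, shape, mm, origin)
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    x <- origin[1] + (j - 0.5) * mm
    y <- origin[2] + (i - 0.5) * mm
    r <- sqrt(x^2 + y^2)
    ang <- atan2(y, x) * 180 / pi
    dang <- abs(((ang - roi$theta + 180) %% 360) - 180)
    expect_identical(m[i, j],
                     r >= 3 && r <= 5 && dang <= 60)
  }
})

test_that("a full annulus covering the FOV equals the brute-force annulus", {
  roi <- arc_roi("red", radius = 7, width = 13.8, theta = 0, span = 360)
  m <- arc_roi_mask(roi, c(24, 32), 0.375, c(1.5, -4.5))
  img <- list(rgb = array(0, c(24, 32, 1)), mm_per_px = 0.375,
              origin = c(1.5, -4.5))
  co <- biliphone:::pixel_coords(img)
  r <- sqrt(co$x^2 + co$y^2)
  expect_identical(m, r >= 7 - 6.9 & r <= 7 + 6.9)
})

test_that("mirrored arcs are disjoint with equal pixel counts on a symmetric grid", {
  shape <- c(24, 32); mm <- 0.375; origin <- c(1.5, -4.5)
  a <- arc_roi("green", radius = 4, width = 2, theta = 20, span = 90)
  b <- arc_roi("green", radius = 4, width = 2, theta = -20, span = 90)
  ma <- arc_roi_mask(a, shape, mm, origin)
  mb <- arc_roi_mask(b, shape, mm, origin)
  expect_equal(sum(ma), sum(mb))
  # 180-degree shifted arcs with limited span cannot overlap
  c1 <- arc_roi("green", radius = 4, width = 2, theta = 0, span = 90)
  c2 <- arc_roi("green", radius = 4, width = 2, theta = 180, span = 90)
  m1 <- arc_roi_mask(c1, shape, mm, origin)
  expect_error(arc_roi_mask(c2, shape, mm, origin), "degenerate-roi")
  expect_true(any(m1))
})

test_that("arcs outside the image raise degenerate-roi errors", {
  expect_error(arc_roi_mask(arc_roi("red", radius = 40, width = 1),
                            c(24, 32), 0.375, c(1.5, -4.5)),
               "degenerate-roi")
  expect_error(arc_roi("red", radius = 0.4, width = 1), "invalid-parameter")
  expect_error(arc_roi("red", radius = 4, width = 0), "invalid-parameter")
  expect_error(arc_roi("red", radius = 4, width = 1, span = 400),
               "invalid-parameter")
})

test_that("features are masked means over valid pixels, in ROI-set order", {
  rgb <- array(0, dim = c(24, 32, 3))
  img0 <- make_calibrated(rgb)
  co <- biliphone:::pixel_coords(img0)
  r <- sqrt(co$x^2 + co$y^2)
  for (ch in 1:3) img0$rgb[, , ch] <- ch * r   # radial ramp per channel
  rs <- roi_set(list(arc_roi("blue", 4, 2, 0, 120),
                     arc_roi("red", 5, 1.5, 0, 90)))
  f <- extract_features(img0, rs)
  m1 <- arc_roi_mask(rs$rois[[1]], c(24, 32), 0.375, c(1.5, -4.5))
  m2 <- arc_roi_mask(rs$rois[[2]], c(24, 32), 0.375, c(1.5, -4.5))
  expect_equal(unname(f), c(mean((3 * r)[m1]), mean((1 * r)[m2])))
  # constant image: every feature equals the constant
  imgc <- make_calibrated(array(0.42, dim = c(24, 32, 3)))
  expect_equal(unname(extract_features(imgc, rs)), c(0.42, 0.42))
})

test_that("saturated regions are excluded from feature means", {
  rgb <- array(1, dim = c(24, 32, 3))
  left_half <- matrix(rep(seq_len(32) <= 16, each = 24), 24, 32)
  rgb[, , 3][!left_half] <- 5
  mask <- left_half          # right half unusable
  img <- make_calibrated(rgb, mask = mask)
  rs <- roi_set(list(arc_roi("blue", 4, 2, 0, 120)))
  m <- arc_roi_mask(rs$rois[[1]], c(24, 32), 0.375, c(1.5, -4.5))
  expect_equal(unname(extract_features(img, rs)),
               mean(rgb[, , 3][m & mask]))
  # fully saturated ROI errors with the ROI named
  img_all_bad <- make_calibrated(rgb, mask = matrix(FALSE, 24, 32))
  expect_error(extract_features(img_all_bad, rs), "masked-roi")
})

test_that("the default ROI set has the 4/3/2 composition within bounds", {
  rs <- default_roi_set()
  ch <- vapply(rs$rois, `[[`, "", "channel")
  expect_equal(as.integer(table(factor(ch, c("blue", "green", "red")))),
               c(4L, 3L, 2L))
  expect_length(rs$rois, 9L)
  par <- biliphone:::roi_params(rs)
  bv <- biliphone:::roi_bounds_vec(rs)
  expect_true(all(par >= bv$lower & par <= bv$upper))
})
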