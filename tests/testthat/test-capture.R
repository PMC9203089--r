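bayer_frame <- function(px) raw_frame(px, mosaic = "bayer_rggb")

test_that("demosaicing a constant mosaic gives constant channels", {
  f <- bayer_frame(matrix(1234, 8, 8))
  out <- demosaic(f)
  expect_equal(dim(out), c(8, 8, 3))
  expect_true(all(out == 1234))
})

test_that("per-plane constants recover the plane values exactly", {
  px <- matrix(0, 8, 8)
  odd <- (1:8) %% 2 == 1
  px[outer(odd, odd, "&")] <- 100          # R sites
  px[outer(!odd, !odd, "&")] <- 300        # B sites
  px[outer(odd, !odd, "&") | outer(!odd, odd, "&")] <- 200  # G sites
  out <- demosaic(bayer_frame(px))
  expect_true(all(out[, , 1] == 100))
  expect_true(all(out[, , 2] == 200))
  expect_true(all(out[, , 3] == 300))
})

test_that("bilinear interpolation matches a per-pixel brute-force oracle", {
  set.seed(21)
  px <- matrix(round(runif(100, 0, 60000)), 10, 10)
  out <- demosaic(bayer_frame(px))
  # independent oracle: gather 3x3 neighbours of each colour plane with
  # bilinear weights (interior pixels only, away from edge replication)
  site <- matrix("", 10, 10)
  for (i in 1:10) for (j in 1:10)
    site[i, j] <- if (i %% 2 == 1 && j %% 2 == 1) "R"
      else if (i %% 2 == 0 && j %% 2 == 0) "B" else "G"
  chans <- c(R = 1, G = 2, B = 3)
  for (ch in names(chans)) {
    for (i in 3:8) for (j in 3:8) {
      num <- 0; den <- 0
      for (di in -1:1) for (dj in -1:1) {
        if (site[i + di, j + dj] == ch) {
          w <- (2 - abs(di)) * (2 - abs(dj))
          num <- num + w * px[i + di, j + dj]
          den <- den + w
        }
      }
      expect_equal(out[i, j, chans[[ch]]], num / den, tolerance = 1e-12)
    }
  }
})

test_that("planar frames pass through the demosaicer unchanged", {
  arr <- array(runif(24, 0, 65535), dim = c(2, 4, 3))
  f <- raw_frame(arr, mosaic = "rgb_planar")
  expect_equal(demosaic(f), arr)
})

test_that("raw frame validation catches bad inputs", {
  expect_error(raw_frame(matrix(-1, 4, 4)), "invalid-parameter")
  expect_error(raw_frame(matrix(1, 3, 4), mosaic = "bayer_rggb"),
               "invalid-mosaic")
})

test_that("quarter downsampling is exact 2x2 block averaging", {
  m <- matrix(c(1, 3, 2, 5), 2, 2)   # block [1,2;3,5]
  expect_equal(quarter_downsample(m), matrix(2.75, 1, 1))
  const <- array(7, dim = c(6, 8, 3))
  down <- quarter_downsample(const)
  expect_equal(dim(down), c(3, 4, 3))
  expect_true(all(down == 7))
  # brute-force block means on a random image
  set.seed(4)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  down <- quarter_downsample(img)
  for (ch in 1:3) for (i in 1:4) for (j in 1:4)
    expect_equal(down[i, j, ch],
                 mean(img[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch]),
                 tolerance = 1e-12)
  expect_warning(quarter_downsample(matrix(1, 5, 4)), "trimming")
})

test_that("kNN outlier flagging matches a brute-force recomputation", {
  base <- array(1000, dim = c(4, 4, 3))
  frames <- list(base, base, base * 2)
  keep <- flag_outlier_frames(frames, k = 1, threshold_mads = 3)
  expect_identical(keep, c(TRUE, TRUE, FALSE))
  # brute force: feature vectors, pairwise distances, median + 3 MAD rule
  feats <- t(sapply(frames, function(f) c(apply(f, 3, mean),
                                          apply(f, 3, sd))))
  d <- as.matrix(dist(feats))
  knn <- sapply(1:3, function(i) min(d[i, -i]))
  thr <- median(knn) + 3 * mad(knn)
  expect_identical(unname(knn <= thr), keep)
  # identical frames: nothing flagged
  expect_identical(flag_outlier_frames(list(base, base, base)),
                   rep(TRUE, 3))
  expect_error(flag_outlier_frames(list(base)), "insufficient-data")
  expect_error(flag_outlier_frames(list(base, base), k = 2),
               "invalid-parameter")
})

test_that("frame averaging respects the keep-mask", {
  f <- function(v) array(v, dim = c(2, 2, 3))
  frames <- list(f(1), f(2), f(9))
  expect_equal(average_frames(frames), f(4))
  expect_equal(average_frames(frames, c(TRUE, TRUE, FALSE)), f(1.5))
  expect_equal(average_frames(frames[1]), f(1))
  expect_error(average_frames(frames, rep(FALSE, 3)), "insufficient-data")
})

test_that("saturation mask marks any pixel reaching the limit in any frame", {
  a <- matrix(0, 4, 4)
  b <- a; b[2, 3] <- 65535
  m <- saturation_mask(list(bayer_frame(a), bayer_frame(b)))
  expect_false(m[2, 3])
  expect_equal(sum(!m), 1)
  expect_true(all(saturation_mask(list(bayer_frame(a)))))
  # a larger limit can only enlarge the usable area
  m95 <- saturation_mask(list(bayer_frame(b)), limit = 0.95 * 65535)
  m99 <- saturation_mask(list(bayer_frame(b)), limit = 0.999 * 65535)
  expect_true(all(m99 >= m95))
})

test_that("calibration is a per-pixel background-subtracted ratio", {
  on <- array(runif(48, 1000, 60000), dim = c(4, 4, 3))
  off <- array(500, dim = c(4, 4, 3))
  # self-calibration: tissue frames equal calibration frames
  ci <- calibrate_reflectance(on, off, on, off)
  expect_true(all(abs(ci$rgb[array(rep(ci$mask, 3), dim(ci$rgb))] - 1) < 1e-12))
  # linearity
  on2 <- off + 2 * (on - off)
  ci2 <- calibrate_reflectance(on2, off, on, off)
  expect_true(all(abs(ci2$rgb - 2) < 1e-12, na.rm = TRUE))
  # degenerate calibration
  expect_error(calibrate_reflectance(on, off, off, off),
               "calibration-failure")
})

test_that("calibration is invariant to gain and dark offset", {
  set.seed(8)
  tissue <- array(runif(48, 2000, 30000), dim = c(4, 4, 3))
  cal <- array(runif(48, 20000, 50000), dim = c(4, 4, 3))
  dark <- array(800, dim = c(4, 4, 3))
  base <- calibrate_reflectance(tissue + dark, dark, cal + dark, dark)
  gained <- calibrate_reflectance(3 * (tissue + dark), 3 * dark,
                                  3 * (cal + dark), 3 * dark)
  shifted <- calibrate_reflectance(tissue + dark + 100, dark + 100,
                                   cal + dark + 100, dark + 100)
  expect_equal(base$rgb, gained$rgb, tolerance = 1e-12)
  expect_equal(base$rgb, shifted$rgb, tolerance = 1e-12)
})

test_that("averaging is invariant to consistent frame permutations", {
  set.seed(9)
  frames <- lapply(1:3, function(i) array(runif(12), dim = c(2, 2, 3)))
  keep <- c(TRUE, FALSE, TRUE)
  perm <- c(3, 1, 2)
  expect_equal(average_frames(frames, keep),
               average_frames(frames[perm], keep[perm]))
})
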