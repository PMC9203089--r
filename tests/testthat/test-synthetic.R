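test_that("sampled TSB is right-skewed with its bulk between 5 and 10 mg/dL", {
  cfg <- cohort_config()
  tsb <- sample_tsb(cfg, n = 1000, seed = 2)
  expect_true(all(tsb > 0 & tsb <= 25))
  med <- median(tsb)
  expect_gte(med, 5); expect_lte(med, 10)
  expect_gt(mean(tsb) , med * 0.99)  # right skew: mean above (or near) median
  expect_identical(tsb, sample_tsb(cfg, n = 1000, seed = 2))
})

test_that("the forward field encodes bilirubin in blue and melanin everywhere", {
  geo <- adapter_geometry(edge_offset = 0)
  f0 <- forward_reflectance_image(0, 0.02, geo, shape = c(24L, 32L))
  f20 <- forward_reflectance_image(20, 0.02, geo, shape = c(24L, 32L))
  expect_lt(mean(f20[, , 3]), mean(f0[, , 3]))               # blue drops
  expect_lt(abs(mean(f20[, , 1]) / mean(f0[, , 1]) - 1), 0.01)  # red stable
  fd <- forward_reflectance_image(0, 0.10, geo, shape = c(24L, 32L))
  for (ch in 1:3) expect_lt(mean(fd[, , ch]), mean(f0[, , ch]))
  expect_true(all(f0 > 0))
  # radially decreasing along the FOV axis
  mid <- nrow(f0[, , 1]) %/% 2
  expect_true(all(diff(f0[mid, , 3]) < 0))
})

test_that("the forward field matches the diffusion profile at 5 mm", {
  geo <- adapter_geometry(edge_offset = 0)
  shape <- c(24L, 32L)
  f <- forward_reflectance_image(8, 0.02, geo, shape = shape)
  model <- biliphone:::homogenize_skin(
    build_default_skin(melanosome_fraction = 0.02, bilirubin_mg_dl = 8))
  g <- biliphone:::raw_grid(geo, shape)
  r <- sqrt(g$x^2 + g$y^2)
  i <- which.min(abs(r - 5))
  expect_equal(f[, , 3][i],
               as.numeric(diffusion_reflectance(model, r[i], 474)),
               tolerance = 1e-12)
})

test_that("noiseless captures invert exactly through the pipeline", {
  cfg <- cohort_config(n_patients = 1L, shot_noise = 0, read_noise = 0,
                       corrupted_frame_rate = 0, saturation_radius = 0,
                       quantize = FALSE, raw_shape = c(48L, 64L), seed = 6)
  co <- generate_cohort(cfg)
  img <- preprocess_cohort(co)$images[[1]]
  truth <- synthetic_truth_field(co$patients$tsb_mg_dl[1],
                                 co$ground_truth[[1]]$melanosome_fraction, cfg)
  rel <- abs(img$rgb - truth) / truth
  expect_lt(max(rel[array(rep(img$mask, 3), dim(rel))]), 1e-6)
})

test_that("calibration cancels the sensor gain", {
  cfg <- cohort_config(n_patients = 1L, shot_noise = 0, read_noise = 0,
                       corrupted_frame_rate = 0, saturation_radius = 0,
                       quantize = FALSE, raw_shape = c(24L, 32L), seed = 6)
  fld <- forward_reflectance_image(8, 0.02, cfg$geometry, cfg$bank,
                                   cfg$raw_shape)
  cs <- render_capture_stack(fld, cfg, seed = 1)
  img1 <- process_capture_set(cs, geometry = cfg$geometry)
  # doubling every frame (gain change) leaves the calibrated image alone
  cs2 <- cs
  for (part in c("tissue_on", "tissue_off", "cal_on", "cal_off"))
    cs2[[part]] <- lapply(cs[[part]], function(f) {
      f$pixels <- f$pixels * 2; f
    })
  img2 <- process_capture_set(cs2, geometry = cfg$geometry)
  # compare where both are valid (doubling can push bright calibration
  # pixels over the saturation limit, shrinking the second mask)
  joint <- array(rep(img1$mask & img2$mask, 3), dim(img1$rgb))
  expect_equal(img1$rgb[joint], img2$rgb[joint], tolerance = 1e-10)
  expect_gt(sum(joint), 0.5 * length(joint))
})

test_that("injected non-contact frames are detected at their recorded index", {
  cfg <- cohort_config(n_patients = 1L, shot_noise = 0.5, read_noise = 2,
                       corrupted_frame_rate = 1, raw_shape = c(24L, 32L),
                       seed = 8)
  fld <- forward_reflectance_image(8, 0.02, cfg$geometry, cfg$bank,
                                   cfg$raw_shape)
  # rate 1 corrupts every frame; force exactly one by splicing a clean set
  cfg_clean <- cfg; cfg_clean$corrupted_frame_rate <- 0
  cs <- render_capture_stack(fld, cfg_clean, seed = 9)
  bad <- render_capture_stack(fld, cfg, seed = 9)
  cs$tissue_on[[2]] <- bad$tissue_on[[2]]
  dec <- lapply(cs$tissue_on, function(f)
    quarter_downsample(demosaic(f)))
  keep <- flag_outlier_frames(dec, k = 1, threshold_mads = 3)
  expect_identical(keep, c(TRUE, FALSE, TRUE))
})

test_that("saturation appears as a masked disc near the source", {
  cfg <- cohort_config(n_patients = 1L, shot_noise = 0, read_noise = 0,
                       corrupted_frame_rate = 0, saturation_radius = 3,
                       quantize = FALSE, raw_shape = c(48L, 64L), seed = 6)
  co <- generate_cohort(cfg)
  img <- preprocess_cohort(co)$images[[1]]
  co_px <- biliphone:::pixel_coords(img)
  r <- sqrt(co_px$x^2 + co_px$y^2)
  # all masked-out pixels concentrate at the saturated corner (plus the
  # one-pixel demosaic guard band)
  expect_true(all(r[!img$mask] < 3 + 3 * img$mm_per_px))
  expect_true(any(!img$mask))
  expect_true(all(img$mask[r > 4]))
})

test_that("cohort generation is reproducible and populates the strata", {
  co <- low_noise_cohort()$raw
  expect_equal(nrow(co$patients), 60L)
  s1 <- stratified_split(co$patients, stage1_strata(), seed = 1)
  s2 <- stratified_split(co$patients, stage2_strata(), seed = 1)
  expect_length(s1$train, 8L); expect_length(s1$test, 7L)
  expect_length(s2$test, 5L); expect_length(s2$train, 55L)
  cfg <- cohort_config(n_patients = 6L, raw_shape = c(24L, 32L), seed = 4)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$captures[[1]]$tissue_on[[1]]$pixels,
                   b$captures[[1]]$tissue_on[[1]]$pixels)
})

test_that("a written cohort loads back identically", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 3L, raw_shape = c(24L, 32L), seed = 13)
  co <- generate_cohort(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "patients.csv")))
  expect_equal(nrow(read.csv(file.path(dir, "patients.csv"))), 3L)
  back <- load_raw_cohort(dir)
  expect_equal(back$patients$tsb_mg_dl, co$patients$tsb_mg_dl,
               tolerance = 1e-12)
  expect_identical(back$captures[["p001"]]$tissue_on[[1]]$pixels,
                   co$captures[["p001"]]$tissue_on[[1]]$pixels)
})
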