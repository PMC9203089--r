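#' Synthetic cohort configuration
#'
#' Describes the statistical population and sensor model emulated by the
#' synthetic-data generator: a right-skewed newborn TSB distribution
#' (gamma, bulk between 5 and 10 mg/dL, truncated at 25 mg/dL, tail
#' reaching ~24), two pigmentation levels enrolled near-evenly, a
#' radially decaying diffuse-reflectance field per RGB channel whose blue
#' channel attenuates with TSB, shot and read noise on a 16-bit sensor
#' with a dark offset, saturation near the source, and occasional
#' corrupted (non-contact) frames.
#'
#' @param n_patients Cohort size.
#' @param tsb_shape,tsb_scale,tsb_max Gamma shape/scale of the TSB
#'   distribution (mg/dL) and its truncation point.
#' @param pigmentation_levels Named melanosome fractions for the skin
#'   groups.
#' @param pigmentation_weights Sampling weights of the groups.
#' @param shot_noise Signal-proportional variance per count.
#' @param read_noise Gaussian read-noise standard deviation, counts.
#' @param dark_offset Sensor dark level, counts.
#' @param corrupted_frame_rate Probability that a flash-on tissue frame
#'   is replaced by a near-dark non-contact frame.
#' @param saturation_radius Radius (mm) around the source centre inside
#'   which flash-on pixels are driven to full scale.
#' @param raw_shape Raw frame dimensions `c(rows, cols)` before
#'   downsampling.
#' @param n_frames Frames per burst.
#' @param mosaic `"rgb_planar"` (decoded frames; the generator is exactly
#'   invertible) or `"bayer_rggb"` (mosaicked frames exercising the
#'   demosaicer).
#' @param quantize Round frames to integer counts (`TRUE`, the sensor
#'   behaviour). `FALSE` keeps continuous values so a noiseless cohort
#'   round-trips through the pipeline to machine precision.
#' @param geometry Capture [adapter_geometry()].
#' @param bank Filter [channel_bank()].
#' @param seed Generator seed.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 37L, tsb_shape = 3.2, tsb_scale = 2.6,
                          tsb_max = 25,
                          pigmentation_levels = c(light = 0.02, dark = 0.10),
                          pigmentation_weights = c(0.5, 0.5),
                          shot_noise = 4, read_noise = 10, dark_offset = 800,
                          corrupted_frame_rate = 0.03,
                          saturation_radius = 2.5,
                          raw_shape = c(96L, 128L), n_frames = 3L,
                          mosaic = c("rgb_planar", "bayer_rggb"),
                          quantize = TRUE,
                          geometry = adapter_geometry(edge_offset = 0),
                          bank = channel_bank(), seed = 1L) {
  mosaic <- match.arg(mosaic)
  if (n_patients < 1L) stop("invalid-parameter: n_patients must be >= 1")
  if (corrupted_frame_rate < 0 || corrupted_frame_rate > 1)
    stop("invalid-parameter: corrupted_frame_rate must be in [0, 1]")
  if (tsb_max <= 0) stop("invalid-parameter: tsb_max must be positive")
  cfg <- list(n_patients = as.integer(n_patients), tsb_shape = tsb_shape,
              tsb_scale = tsb_scale, tsb_max = tsb_max,
              pigmentation_levels = pigmentation_levels,
              pigmentation_weights = pigmentation_weights,
              shot_noise = shot_noise, read_noise = read_noise,
              dark_offset = dark_offset,
              corrupted_frame_rate = corrupted_frame_rate,
              saturation_radius = saturation_radius,
              raw_shape = as.integer(raw_shape), n_frames = as.integer(n_frames),
              mosaic = mosaic, quantize = isTRUE(quantize),
              geometry = geometry, bank = bank,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Sample TSB values from the configured right-skewed distribution
#'
#' Exact inverse-CDF sampling from the gamma family truncated to
#' `(0, tsb_max]`; deterministic under the seed.
#'
#' @param config A [cohort_config()].
#' @param n Number of draws (default `config$n_patients`).
#' @param seed Seed (default `config$seed`).
#' @return TSB values, mg/dL.
#' @export
sample_tsb <- function(config, n = config$n_patients, seed = config$seed) {
  with_seed(seed, {
    u <- stats::runif(n, 0, stats::pgamma(config$tsb_max, config$tsb_shape,
                                          scale = config$tsb_scale))
    stats::qgamma(u, config$tsb_shape, scale = config$tsb_scale)
  })
}

# redistribute samples so every analysis stratum is populated: for each
# deficient TSB bin, move a draw from the bin with the largest surplus and
# redraw it inside the deficient range (inverse-CDF, so still from the
# configured family). Applied only when the cohort is large enough to
# satisfy the floors at all.
ensure_strata <- function(tsb, config, strata_floors) {
  for (sf in strata_floors) {
    if (length(tsb) < sum(sf$min)) next
    repeat {
      bins <- cut(tsb, breaks = sf$edges, include.lowest = TRUE)
      counts <- table(bins)
      deficit <- which(counts < sf$min)
      if (!length(deficit)) break
      b <- deficit[1]
      surplus <- counts - sf$min
      donor <- which.max(surplus)
      idx <- which(as.integer(bins) == donor)
      i <- idx[length(idx)]
      lo <- sf$edges[b]; hi <- sf$edges[b + 1]
      u <- stats::runif(1, stats::pgamma(lo, config$tsb_shape,
                                         scale = config$tsb_scale),
                        stats::pgamma(hi, config$tsb_shape,
                                      scale = config$tsb_scale))
      tsb[i] <- stats::qgamma(u, config$tsb_shape, scale = config$tsb_scale)
    }
  }
  tsb
}

default_strata_floors <- function() {
  list(list(edges = stage1_strata()$edges, min = c(4L, 4L, 4L, 3L)),
       list(edges = stage2_strata()$edges, min = rep(2L, 5L)))
}

# pixel-centre mm coordinates of a raw frame over the FOV
raw_grid <- function(geometry, shape) {
  rect <- fov_rect(geometry)
  mm <- geometry$fov[2] / shape[2]
  x <- rect[1] + (seq_len(shape[2]) - 0.5) * mm
  y <- rect[3] + (seq_len(shape[1]) - 0.5) * mm
  list(x = matrix(x, shape[1], shape[2], byrow = TRUE),
       y = matrix(y, shape[1], shape[2]), mm_per_px = mm)
}

#' Noiseless synthetic reflectance field of one patient
#'
#' Evaluates the diffusion-theory radial profile over the FOV per RGB
#' band, with the effective attenuation of each channel computed from
#' the chromophore skin model at the band centre: bilirubin raises the
#' blue-channel attenuation, melanin raises all channels. The field is
#' radially symmetric about the source centre, strictly positive, and
#' strictly decreasing in radius beyond the beam edge.
#'
#' @param tsb TSB, mg/dL.
#' @param melanosome_fraction Epidermal melanosome fractional volume.
#' @param geometry An [adapter_geometry()].
#' @param bank A [channel_bank()].
#' @param shape Output dimensions `c(rows, cols)`.
#' @return `h x w x 3` array (R, G, B) of reflectance per unit area.
#' @export
forward_reflectance_image <- function(tsb, melanosome_fraction,
                                      geometry = adapter_geometry(edge_offset = 0),
                                      bank = channel_bank(),
                                      shape = c(96L, 128L)) {
  model <- homogenize_skin(build_default_skin(
    melanosome_fraction = melanosome_fraction, bilirubin_mg_dl = tsb))
  g <- raw_grid(geometry, shape)
  r <- sqrt(g$x^2 + g$y^2)
  out <- array(0, dim = c(shape[1], shape[2], 3L))
  for (i in seq_len(nrow(bank))) {
    ch <- channel_index(bank$name[i])
    out[, , ch] <- diffusion_reflectance(model, r, bank$center[i])
  }
  out
}

# HDPE-like reflectance standard: low absorption, strong flat scattering
hdpe_model <- function() {
  layered_skin(list(skin_layer("hdpe", Inf, 0.002, 25, g = 0.9, n = 1.4)))
}

# flash-on field of the calibration standard (shared by all patients)
hdpe_field <- function(geometry, bank, shape) {
  m <- hdpe_model()
  g <- raw_grid(geometry, shape)
  r <- sqrt(g$x^2 + g$y^2)
  out <- array(0, dim = c(shape[1], shape[2], 3L))
  for (i in seq_len(nrow(bank)))
    out[, , channel_index(bank$name[i])] <- diffusion_reflectance(m, r, bank$center[i])
  out
}

# per-channel sensor gains placing the calibration standard's proximal
# edge at ~60% of full scale
sensor_gains <- function(config) {
  cf <- hdpe_field(config$geometry, config$bank, config$raw_shape)
  vapply(1:3, function(ch) 0.6 * 65535 / max(cf[, , ch]), 0)
}

clamp16 <- function(x, quantize = TRUE) {
  if (quantize) x <- round(x)
  pmin(pmax(x, 0), 65535)
}

mosaic_bayer <- function(img) {
  nr <- dim(img)[1]; nc <- dim(img)[2]
  odd_r <- (seq_len(nr) %% 2L) == 1L
  odd_c <- (seq_len(nc) %% 2L) == 1L
  out <- img[, , 2]                       # G sites
  rs <- outer(odd_r, odd_c, "&")
  bs <- outer(!odd_r, !odd_c, "&")
  out[rs] <- img[, , 1][rs]               # R sites
  out[bs] <- img[, , 3][bs]               # B sites
  out
}

#' Render a raw 16-bit capture set from a reflectance field
#'
#' Tissue flash-on frames are `gain * field + dark_offset` plus
#' signal-proportional shot noise and Gaussian read noise, clipped to 16
#' bits, with pixels inside `saturation_radius` driven to full scale;
#' flash-off frames contain the dark offset and read noise; calibration
#' frames are rendered from the HDPE-standard field with the same gains,
#' offset and noise. With probability `corrupted_frame_rate` a flash-on
#' tissue frame is replaced by a near-dark non-contact frame and its
#' index recorded in `attr(, "corrupted")`.
#'
#' @param field `h x w x 3` tissue reflectance field
#'   ([forward_reflectance_image()]).
#' @param config A [cohort_config()].
#' @param seed Seed for this capture set.
#' @param patient_id Identifier stored in the capture set.
#' @return A [capture_set()]; corrupted tissue-frame indices in
#'   `attr(, "corrupted")`.
#' @export
render_capture_stack <- function(field, config, seed, patient_id = "p1") {
  gains <- sensor_gains(config)
  cal <- hdpe_field(config$geometry, config$bank, config$raw_shape)
  g <- raw_grid(config$geometry, config$raw_shape)
  r <- sqrt(g$x^2 + g$y^2)
  sat_zone <- r < config$saturation_radius
  shape <- config$raw_shape

  with_seed(seed, {
    signal_frame <- function(fld, saturate) {
      counts <- array(0, dim = c(shape[1], shape[2], 3L))
      for (ch in 1:3) {
        s <- gains[ch] * fld[, , ch]
        sdev <- sqrt(pmax(config$shot_noise * s, 0) + config$read_noise^2)
        noisy <- s + config$dark_offset +
          stats::rnorm(length(s), 0, 1) * sdev
        m <- matrix(noisy, shape[1], shape[2])
        if (saturate) m[sat_zone] <- 65535
        counts[, , ch] <- clamp16(m, config$quantize)
      }
      counts
    }
    dark_frame <- function() {
      counts <- array(stats::rnorm(prod(shape) * 3, config$dark_offset,
                                   config$read_noise),
                      dim = c(shape[1], shape[2], 3L))
      clamp16(counts, config$quantize)
    }
    as_raw <- function(px, flash) {
      if (config$mosaic == "bayer_rggb") px <- mosaic_bayer(px)
      raw_frame(px, mosaic = config$mosaic, flash = flash)
    }
    corrupted <- integer(0)
    tissue_on <- lapply(seq_len(config$n_frames), function(i) {
      if (stats::runif(1) < config$corrupted_frame_rate) {
        corrupted <<- c(corrupted, i)
        as_raw(dark_frame(), flash = TRUE)
      } else as_raw(signal_frame(field, saturate = TRUE), flash = TRUE)
    })
    tissue_off <- lapply(seq_len(config$n_frames), function(i)
      as_raw(dark_frame(), flash = FALSE))
    cal_on <- lapply(seq_len(config$n_frames), function(i)
      as_raw(signal_frame(cal, saturate = TRUE), flash = TRUE))
    cal_off <- lapply(seq_len(config$n_frames), function(i)
      as_raw(dark_frame(), flash = FALSE))
    cs <- capture_set(tissue_on, tissue_off, cal_on, cal_off, patient_id)
    attr(cs, "corrupted") <- corrupted
    cs
  })
}

#' Expected calibrated reflectance of a synthetic patient
#'
#' The analytic field the capture pipeline should recover after
#' downsampling: block-averaged tissue field divided by the
#' block-averaged calibration-standard field. Used as ground truth in
#' round-trip tests.
#'
#' @param tsb,melanosome_fraction Patient parameters.
#' @param config A [cohort_config()].
#' @param downsample Block factor used in preprocessing.
#' @return `h x w x 3` array at the downsampled resolution.
#' @export
synthetic_truth_field <- function(tsb, melanosome_fraction, config,
                                  downsample = 2L) {
  tf <- forward_reflectance_image(tsb, melanosome_fraction, config$geometry,
                                  config$bank, config$raw_shape)
  cf <- hdpe_field(config$geometry, config$bank, config$raw_shape)
  quarter_downsample(tf, downsample) / quarter_downsample(cf, downsample)
}

#' Generate a fully synthetic capture cohort
#'
#' Samples TSB and pigmentation per patient, renders raw capture sets
#' with the configured sensor model, and records the ground truth
#' (true TSB, melanosome fraction, per-channel effective attenuation,
#' corrupted-frame indices). When the cohort is large enough, TSB draws
#' are redistributed so that every stratified-analysis bin is populated.
#' Fully reproducible under `config$seed`; optionally written to disk in
#' the standard dataset layout (`patients.csv`, per-patient 16-bit
#' TIFFs, `ground_truth.json`).
#'
#' @param config A [cohort_config()].
#' @param dir Optional output directory.
#' @return Object of class `"raw_cohort"`: `patients` data frame,
#'   `captures` (named list of capture sets), `ground_truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  tsb <- sample_tsb(config)
  tsb <- with_seed(config$seed + 1L,
                   ensure_strata(tsb, config, default_strata_floors()))
  meta <- with_seed(config$seed + 2L, {
    grp <- sample(names(config$pigmentation_levels), n, replace = TRUE,
                  prob = config$pigmentation_weights)
    site <- sample(c("site1", "site2"), n, replace = TRUE)
    list(grp = grp, site = site)
  })
  ids <- sprintf("p%03d", seq_len(n))
  patients <- data.frame(patient_id = ids, tsb_mg_dl = tsb,
                         site = meta$site, skin_group = meta$grp,
                         stringsAsFactors = FALSE)

  cap_seeds <- with_seed(config$seed + 3L,
                         sample.int(.Machine$integer.max - 1L, n))
  captures <- list()
  gt <- list()
  bank <- config$bank
  for (i in seq_len(n)) {
    mel <- config$pigmentation_levels[[meta$grp[i]]]
    fld <- forward_reflectance_image(tsb[i], mel, config$geometry, bank,
                                     config$raw_shape)
    cs <- render_capture_stack(fld, config, cap_seeds[i], ids[i])
    captures[[ids[i]]] <- cs
    hom <- homogenize_skin(build_default_skin(melanosome_fraction = mel,
                                              bilirubin_mg_dl = tsb[i]))
    lay <- hom$layers[[1]]
    mueff <- vapply(seq_len(nrow(bank)), function(b) {
      wl <- bank$center[b]
      mu_eff(lay$mua(wl), lay$mus(wl) * (1 - lay$g))
    }, 0)
    names(mueff) <- bank$name
    gt[[ids[i]]] <- list(tsb_mg_dl = tsb[i], melanosome_fraction = mel,
                         skin_group = meta$grp[i],
                         mueff_per_channel = as.list(mueff),
                         corrupted_frames = attr(cs, "corrupted"))
  }
  cohort <- structure(list(patients = patients, captures = captures,
                           ground_truth = gt, config = config),
                      class = "raw_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat(sprintf("Synthetic raw cohort: %d patients, %d+%d frames each, %s\n",
              nrow(x$patients), x$config$n_frames, x$config$n_frames,
              x$config$mosaic))
  cat(sprintf("  TSB %.1f-%.1f mg/dL (median %.1f)\n",
              min(x$patients$tsb_mg_dl), max(x$patients$tsb_mg_dl),
              stats::median(x$patients$tsb_mg_dl)))
  invisible(x)
}

#' Preprocess a raw cohort into a calibrated cohort
#'
#' Runs [process_capture_set()] on every patient of a
#' [generate_cohort()] result or an on-disk dataset directory.
#'
#' @param x A `"raw_cohort"` or a dataset directory path.
#' @param ... Passed to [process_capture_set()].
#' @return A [bili_cohort()].
#' @export
preprocess_cohort <- function(x, ...) {
  if (is.character(x)) x <- load_raw_cohort(x)
  stopifnot(inherits(x, "raw_cohort"))
  geometry <- x$config$geometry
  images <- lapply(x$captures, process_capture_set, geometry = geometry, ...)
  bili_cohort(x$patients, images)
}
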