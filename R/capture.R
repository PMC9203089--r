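#' Raw sensor frame
#'
#' A single 16-bit capture straight off the sensor: either an undecoded
#' RGGB Bayer mosaic (one value per photosite) or an already-decoded
#' planar RGB array.
#'
#' @param pixels Numeric matrix (Bayer) or `h x w x 3` array (planar),
#'   values in `[0, 65535]`.
#' @param mosaic `"bayer_rggb"` or `"rgb_planar"`.
#' @param exposure_ms Exposure time, ms.
#' @param iso Sensor gain index.
#' @param flash `TRUE` for an illuminated frame, `FALSE` for a dark frame.
#' @return Object of class `"raw_frame"`.
#' @export
raw_frame <- function(pixels, mosaic = c("bayer_rggb", "rgb_planar"),
                      exposure_ms = 400, iso = 4500, flash = TRUE) {
  mosaic <- match.arg(mosaic)
  if (min(pixels) < 0 || max(pixels) > 65535)
    stop("invalid-parameter: pixel values must lie in [0, 65535]")
  if (mosaic == "bayer_rggb") {
    if (!is.matrix(pixels)) stop("invalid-mosaic: Bayer frame must be a matrix")
    if (nrow(pixels) %% 2L != 0L || ncol(pixels) %% 2L != 0L)
      stop("invalid-mosaic: Bayer dimensions must be even")
  } else {
    if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
      stop("invalid-parameter: planar frame must be h x w x 3")
  }
  structure(list(pixels = pixels, mosaic = mosaic, exposure_ms = exposure_ms,
                 iso = iso, flash = flash),
            class = "raw_frame")
}

#' Per-patient capture set
#'
#' Three flash-on and three flash-off tissue frames plus the paired
#' capture set of the reflectance calibration standard.
#'
#' @param tissue_on,tissue_off,cal_on,cal_off Lists of [raw_frame()]s.
#' @param patient_id Identifier.
#' @return Object of class `"capture_set"`.
#' @export
capture_set <- function(tissue_on, tissue_off, cal_on, cal_off, patient_id) {
  all_frames <- c(tissue_on, tissue_off, cal_on, cal_off)
  stopifnot(all(vapply(all_frames, inherits, logical(1), "raw_frame")))
  dims <- vapply(all_frames, function(f) paste(dim(f$pixels)[1:2], collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("invalid-parameter: all frames in a capture set must share dimensions")
  structure(list(tissue_on = tissue_on, tissue_off = tissue_off,
                 cal_on = cal_on, cal_off = cal_off, patient_id = patient_id),
            class = "capture_set")
}

# 2-D shift with edge replication; dx/dy in {-1,0,1}
shift2 <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Demosaic a Bayer frame
#'
#' Bilinear interpolation per colour plane of an RGGB mosaic; output has
#' the input dimensions. Planar RGB frames pass through unchanged.
#'
#' @param frame A [raw_frame()].
#' @return `h x w x 3` double array (R, G, B).
#' @export
demosaic <- function(frame) {
  stopifnot(inherits(frame, "raw_frame"))
  if (frame$mosaic == "rgb_planar") return(frame$pixels * 1.0)
  px <- frame$pixels
  nr <- nrow(px); nc <- ncol(px)
  odd_r <- (seq_len(nr) %% 2L) == 1L
  odd_c <- (seq_len(nc) %% 2L) == 1L
  site_r <- outer(odd_r, odd_c, "&")       # R at (odd, odd)
  site_b <- outer(!odd_r, !odd_c, "&")     # B at (even, even)
  site_g <- !(site_r | site_b)

  interp <- function(mask, kern) {
    v <- px * mask
    w <- mask * 1.0
    acc_v <- 0; acc_w <- 0
    for (k in seq_len(nrow(kern))) {
      dy <- kern[k, 1]; dx <- kern[k, 2]; wt <- kern[k, 3]
      acc_v <- acc_v + wt * shift2(v, dy, dx)
      acc_w <- acc_w + wt * shift2(w, dy, dx)
    }
    acc_v / pmax(acc_w, .Machine$double.eps)
  }
  # 3x3 bilinear kernels: corners weight 1, edges 2, centre 4
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  wts <- (2 - abs(offs$dy)) * (2 - abs(offs$dx))
  kern <- cbind(offs$dy, offs$dx, wts)

  out <- array(0, dim = c(nr, nc, 3))
  out[, , 1] <- interp(site_r, kern)
  out[, , 2] <- interp(site_g, kern)
  out[, , 3] <- interp(site_b, kern)
  out
}

#' Quarter-area downsample
#'
#' 2x2 block averaging per channel (quarter of the original pixel count).
#' Dimensions not divisible by the block factor are trimmed with a
#' warning.
#'
#' @param image `h x w x 3` array (or matrix).
#' @param factor Block edge length, default 2.
#' @return Downsampled array.
#' @export
quarter_downsample <- function(image, factor = 2L) {
  is_mat <- is.matrix(image)
  if (is_mat) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  nr <- (d[1] %/% factor) * factor
  nc <- (d[2] %/% factor) * factor
  if (nr != d[1] || nc != d[2]) {
    warning("dimensions not divisible by ", factor, "; trimming to ",
            nr, " x ", nc)
    image <- image[seq_len(nr), seq_len(nc), , drop = FALSE]
  }
  out <- array(0, dim = c(nr %/% factor, nc %/% factor, d[3]))
  ri <- rep(seq_len(nr %/% factor), each = factor)
  ci <- rep(seq_len(nc %/% factor), each = factor)
  for (ch in seq_len(d[3])) {
    s <- rowsum(image[, , ch], ri)              # sum over row blocks
    s <- t(rowsum(t(s), ci))                    # then column blocks
    out[, , ch] <- s / factor^2
  }
  if (is_mat) matrix(out[, , 1], dim(out)[1], dim(out)[2]) else out
}

# summary features of one decoded frame: per-channel mean and sd
frame_features <- function(img) {
  c(apply(img, 3, mean), apply(img, 3, stats::sd))
}

#' Flag outlier frames by k-nearest-neighbour distance
#'
#' Screens a burst of nominally identical frames for corrupted captures
#' (infant motion, loss of skin contact). Each frame is summarized by its
#' per-channel mean and standard deviation; a frame is flagged when the
#' mean Euclidean distance to its `k` nearest neighbours exceeds the
#' median plus `threshold_mads` scaled median absolute deviations of all
#' such distances. The minimum-distance frame is always retained.
#'
#' @param frames List of decoded `h x w x 3` frames.
#' @param k Neighbour count, `k < length(frames)`.
#' @param threshold_mads Threshold in MAD units (MAD scaled by 1.4826).
#' @return Logical keep-mask, `TRUE` for retained frames.
#' @export
flag_outlier_frames <- function(frames, k = 1L, threshold_mads = 3) {
  n <- length(frames)
  if (n < 2L) stop("insufficient-data: need at least 2 frames")
  if (k >= n) stop("invalid-parameter: k must be < number of frames")
  feats <- t(vapply(frames, frame_features, numeric(6)))
  d <- as.matrix(stats::dist(feats))
  knn_dist <- vapply(seq_len(n), function(i) {
    mean(sort(d[i, -i])[seq_len(k)])
  }, 0)
  thr <- stats::median(knn_dist) + threshold_mads * stats::mad(knn_dist)
  keep <- knn_dist <= thr
  keep[which.min(knn_dist)] <- TRUE
  keep
}

#' Average frames under a keep-mask
#'
#' @param frames List of `h x w x 3` arrays.
#' @param keep Logical mask; at least one frame must be kept.
#' @return Pixelwise mean over the kept frames.
#' @export
average_frames <- function(frames, keep = rep(TRUE, length(frames))) {
  stopifnot(length(keep) == length(frames))
  if (!any(keep)) stop("insufficient-data: no frames retained")
  kept <- frames[keep]
  Reduce(`+`, kept) / length(kept)
}

#' Saturation mask from raw flash-on frames
#'
#' @param frames List of [raw_frame()]s sharing dimensions.
#' @param limit Saturation threshold; default `0.98 * 65535`.
#' @return Logical matrix at raw resolution, `TRUE` = usable, `FALSE`
#'   where any frame reaches the limit.
#' @export
saturation_mask <- function(frames, limit = 0.98 * 65535) {
  raw_px <- function(f) {
    p <- if (inherits(f, "raw_frame")) f$pixels else f
    if (length(dim(p)) == 3L) apply(p, c(1, 2), max) else p
  }
  sat <- Reduce(`|`, lapply(frames, function(f) raw_px(f) >= limit))
  !sat
}

# propagate a raw-resolution usable mask through demosaicing (3x3 spill)
# and block downsampling (a block is usable only if all members are)
propagate_mask <- function(mask, factor = 2L) {
  bad <- !mask
  grown <- bad
  for (dy in -1:1) for (dx in -1:1)
    grown <- grown | shift2(bad, dy, dx)
  m <- !grown
  nr <- (nrow(m) %/% factor) * factor
  nc <- (ncol(m) %/% factor) * factor
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  down <- quarter_downsample(m * 1.0, factor)
  down >= 1 - 1e-9
}

#' Background-subtract and standard-normalize reflectance
#'
#' `rgb = (tissue_on - tissue_off) / (cal_on - cal_off)` per pixel per
#' channel. Pixels whose denominator falls at or below `floor_eps` in any
#' channel are marked invalid rather than clipped.
#'
#' @param tissue_on,tissue_off,cal_on,cal_off Averaged `h x w x 3` images.
#' @param mask Optional logical usable-pixel matrix (e.g. the propagated
#'   saturation mask).
#' @param floor_eps Denominator floor; default `1e-6 * 65535`.
#' @param mm_per_px,origin Spatial metadata: scale (mm per pixel) and mm
#'   coordinates `c(x, y)` of the outer corner of pixel `[1, 1]` in the
#'   adapter frame.
#' @param provenance Named list of retained frame counts.
#' @return Object of class `"calibrated_image"` with fields `rgb`
#'   (reflectance relative to the standard; `NA` where invalid), `mask`,
#'   `mm_per_px`, `origin`, `provenance`.
#' @export
calibrate_reflectance <- function(tissue_on, tissue_off, cal_on, cal_off,
                                  mask = NULL, floor_eps = 1e-6 * 65535,
                                  mm_per_px = NA_real_,
                                  origin = c(NA_real_, NA_real_),
                                  provenance = list()) {
  stopifnot(identical(dim(tissue_on), dim(tissue_off)),
            identical(dim(tissue_on), dim(cal_on)),
            identical(dim(tissue_on), dim(cal_off)))
  denom <- cal_on - cal_off
  if (all(denom <= floor_eps))
    stop("calibration-failure: calibration signal does not exceed background")
  ok_denom <- apply(denom > floor_eps, c(1, 2), all)
  if (is.null(mask)) mask <- matrix(TRUE, dim(tissue_on)[1], dim(tissue_on)[2])
  valid <- mask & ok_denom
  rgb <- (tissue_on - tissue_off) / denom
  rgb[!is.finite(rgb)] <- NA_real_
  invalid3 <- array(rep(!valid, 3L), dim = dim(rgb))
  rgb[invalid3] <- NA_real_
  structure(list(rgb = rgb, mask = valid, mm_per_px = mm_per_px,
                 origin = origin, provenance = provenance),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("Calibrated reflectance image %d x %d px (%.4g mm/px), %.1f%% valid\n",
              d[1], d[2], x$mm_per_px, 100 * mean(x$mask)))
  invisible(x)
}

#' Run the full capture pipeline on one capture set
#'
#' Demosaic (if needed), quarter-area downsample, flag outlier frames per
#' burst, average retained frames, build and propagate the saturation
#' mask, and calibrate against the reflectance standard.
#'
#' @param cs A [capture_set()].
#' @param geometry The [adapter_geometry()] used during capture; sets the
#'   pixel-to-mm mapping (FOV width divided by image width after
#'   downsampling) and the mm origin of the image.
#' @param downsample Block factor for [quarter_downsample()].
#' @param k,threshold_mads Parameters of [flag_outlier_frames()].
#' @param sat_limit Saturation threshold for [saturation_mask()].
#' @return A `"calibrated_image"`.
#' @export
process_capture_set <- function(cs, geometry = adapter_geometry(edge_offset = 0),
                                downsample = 2L, k = 1L, threshold_mads = 3,
                                sat_limit = 0.98 * 65535) {
  stopifnot(inherits(cs, "capture_set"))
  dec <- function(frames) lapply(frames, function(f)
    quarter_downsample(demosaic(f), downsample))
  lists <- list(tissue_on = dec(cs$tissue_on), tissue_off = dec(cs$tissue_off),
                cal_on = dec(cs$cal_on), cal_off = dec(cs$cal_off))
  keeps <- lapply(lists, function(fr)
    if (length(fr) >= 2L) flag_outlier_frames(fr, k, threshold_mads)
    else rep(TRUE, length(fr)))
  avgs <- Map(average_frames, lists, keeps)

  sat_raw <- saturation_mask(c(cs$tissue_on, cs$cal_on), sat_limit)
  sat <- propagate_mask(sat_raw, downsample)

  wpx <- dim(avgs$tissue_on)[2]
  mm_per_px <- geometry$fov[2] / wpx
  rect <- fov_rect(geometry)
  calibrate_reflectance(avgs$tissue_on, avgs$tissue_off,
                        avgs$cal_on, avgs$cal_off,
                        mask = sat, mm_per_px = mm_per_px,
                        origin = c(rect[1], rect[3]),
                        provenance = lapply(keeps, sum))
}

# mm coordinates of pixel centres of a calibrated image, relative to the
# illumination-spot centre; returns list(x = matrix, y = matrix)
pixel_coords <- function(image) {
  d <- dim(image$rgb)
  x <- image$origin[1] + (seq_len(d[2]) - 0.5) * image$mm_per_px
  y <- image$origin[2] + (seq_len(d[1]) - 0.5) * image$mm_per_px
  list(x = matrix(x, d[1], d[2], byrow = TRUE),
       y = matrix(y, d[1], d[2]))
}
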