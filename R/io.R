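# ---- dataset layout -------------------------------------------------------
# dir/
#   patients.csv                      patient_id, tsb_mg_dl, site, skin_group
#   config.json                       generator / capture metadata
#   ground_truth.json                 (synthetic cohorts only)
#   <patient_id>/{tissue|cal}_{on|off}_{1..n}.tif    16-bit TIFF frames

write_frame_tiff <- function(frame, path) {
  tiff::writeTIFF(frame$pixels / 65535, path, bits.per.sample = 16,
                  compression = "none")
}

read_frame_tiff <- function(path, mosaic, flash) {
  px <- tiff::readTIFF(path)
  raw_frame(round(px * 65535), mosaic = mosaic, flash = flash)
}

#' Write a raw cohort to disk
#'
#' @param cohort A `"raw_cohort"` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "raw_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  geo <- cfg$geometry
  meta <- list(mosaic = cfg$mosaic, raw_shape = cfg$raw_shape,
               n_frames = cfg$n_frames, seed = cfg$seed,
               geometry = list(spot_radius = geo$spot_radius,
                               edge_offset = geo$edge_offset, fov = geo$fov,
                               acceptance_half_angle = geo$acceptance_half_angle,
                               incidence_angle = geo$incidence_angle,
                               adapter_thickness = geo$adapter_thickness))
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(cohort$ground_truth))
    jsonlite::write_json(cohort$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (id in names(cohort$captures)) {
    pdir <- file.path(dir, id)
    dir.create(pdir, showWarnings = FALSE)
    cs <- cohort$captures[[id]]
    for (part in c("tissue_on", "tissue_off", "cal_on", "cal_off")) {
      frames <- cs[[part]]
      for (i in seq_along(frames))
        write_frame_tiff(frames[[i]],
                         file.path(pdir, sprintf("%s_%d.tif",
                                                 sub("tissue", "tissue",
                                                     part), i)))
    }
  }
  invisible(dir)
}

#' Load a raw cohort from disk
#'
#' @param dir Dataset directory written by [write_cohort()] (or assembled
#'   by hand in the same layout).
#' @return A `"raw_cohort"`.
#' @export
load_raw_cohort <- function(dir) {
  pfile <- file.path(dir, "patients.csv")
  if (!file.exists(pfile)) stop("no patients.csv in ", dir)
  patients <- utils::read.csv(pfile, stringsAsFactors = FALSE)
  patients$patient_id <- as.character(patients$patient_id)
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  geometry <- adapter_geometry(spot_radius = meta$geometry$spot_radius,
                               edge_offset = meta$geometry$edge_offset,
                               fov = meta$geometry$fov,
                               acceptance_half_angle = meta$geometry$acceptance_half_angle,
                               incidence_angle = meta$geometry$incidence_angle,
                               adapter_thickness = meta$geometry$adapter_thickness)
  config <- cohort_config(n_patients = nrow(patients),
                          raw_shape = meta$raw_shape,
                          n_frames = meta$n_frames, mosaic = meta$mosaic,
                          geometry = geometry, seed = meta$seed)
  captures <- list()
  for (id in patients$patient_id) {
    pdir <- file.path(dir, id)
    rd <- function(part, flash) lapply(seq_len(meta$n_frames), function(i)
      read_frame_tiff(file.path(pdir, sprintf("%s_%d.tif", part, i)),
                      meta$mosaic, flash))
    captures[[id]] <- capture_set(rd("tissue_on", TRUE), rd("tissue_off", FALSE),
                                  rd("cal_on", TRUE), rd("cal_off", FALSE), id)
  }
  gt_file <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_file))
    jsonlite::read_json(gt_file, simplifyVector = TRUE) else list()
  structure(list(patients = patients, captures = captures,
                 ground_truth = gt, config = config),
            class = "raw_cohort")
}

#' Read and write ROI sets as JSON
#'
#' @param rois A [roi_set()].
#' @param path JSON file path.
#' @return `write_roi_set` returns `path` invisibly; `read_roi_set`
#'   returns a [roi_set()].
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  obj <- list(rois = lapply(rois$rois, function(r)
    list(channel = r$channel, radius_mm = r$radius, width_mm = r$width,
         theta_deg = r$theta, span_deg = r$span)),
    bounds = rois$bounds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- lapply(seq_len(nrow(obj$rois)), function(i)
    arc_roi(obj$rois$channel[i], obj$rois$radius_mm[i], obj$rois$width_mm[i],
            obj$rois$theta_deg[i], obj$rois$span_deg[i]))
  roi_set(rois, bounds = obj$bounds)
}

#' Write cross-validation predictions as CSV
#'
#' Columns: `patient_id`, `tsb_mg_dl`, `median_prediction`,
#' `n_test_appearances`.
#'
#' @param cv A `"cv_result"`.
#' @param cohort The matching [bili_cohort()].
#' @param path CSV path.
#' @return The predictions data frame, invisibly.
#' @export
write_predictions <- function(cv, cohort, path) {
  stopifnot(inherits(cv, "cv_result"))
  df <- data.frame(patient_id = cohort$patients$patient_id,
                   tsb_mg_dl = cohort$patients$tsb_mg_dl,
                   median_prediction = unname(
                     cv$median_prediction[cohort$patients$patient_id]),
                   n_test_appearances = unname(
                     cv$n_test_appearances[cohort$patients$patient_id]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Persist a Monte-Carlo reflectance map
#'
#' Writes the per-wavelength FOV maps as a multi-page 32-bit float TIFF
#' plus a JSON sidecar with geometry, seed, wavelengths and tallies;
#' per-channel maps from [integrate_channels()] can be written the same
#' way.
#'
#' @param map A `"reflectance_map"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_reflectance_map <- function(map, dir) {
  stopifnot(inherits(map, "reflectance_map"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pages <- lapply(seq_along(map$wavelengths), function(i) map$values[, , i])
  tiff::writeTIFF(pages, file.path(dir, "reflectance.tif"),
                  bits.per.sample = 32, compression = "none")
  geo <- map$geometry
  side <- list(wavelengths_nm = map$wavelengths, bin_mm = map$bin_mm,
               n_photons = map$n_photons, seed = map$seed,
               tallies = as.data.frame(t(map$tallies)),
               geometry = list(spot_radius = geo$spot_radius,
                               edge_offset = geo$edge_offset, fov = geo$fov,
                               acceptance_half_angle = geo$acceptance_half_angle,
                               incidence_angle = geo$incidence_angle))
  jsonlite::write_json(side, file.path(dir, "reflectance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Persist and reload a calibrated cohort
#'
#' Each patient's reflectance is written as a 32-bit float TIFF (scaled
#' into `[0, 1]`; the scale lives in the JSON sidecar together with the
#' spatial metadata and retention counts) plus an 8-bit mask TIFF.
#'
#' @param cohort A [bili_cohort()].
#' @param dir Output directory.
#' @return `dir` (write) / a [bili_cohort()] (load).
#' @export
write_calibrated_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bili_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  for (id in names(cohort$images)) {
    img <- cohort$images[[id]]
    rgb <- img$rgb
    rgb[is.na(rgb)] <- 0
    rgb[rgb < 0] <- 0
    scale <- max(rgb, 1e-12)
    tiff::writeTIFF(rgb / scale, file.path(dir, paste0(id, "_rgb.tif")),
                    bits.per.sample = 32, compression = "none")
    tiff::writeTIFF(img$mask * 1.0, file.path(dir, paste0(id, "_mask.tif")),
                    bits.per.sample = 8, compression = "none")
    jsonlite::write_json(list(scale = scale, mm_per_px = img$mm_per_px,
                              origin = img$origin,
                              provenance = img$provenance),
                         file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_calibrated_cohort
#' @export
load_calibrated_cohort <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  patients$patient_id <- as.character(patients$patient_id)
  images <- lapply(patients$patient_id, function(id) {
    side <- jsonlite::read_json(file.path(dir, paste0(id, ".json")),
                                simplifyVector = TRUE)
    rgb <- tiff::readTIFF(file.path(dir, paste0(id, "_rgb.tif"))) * side$scale
    mask <- tiff::readTIFF(file.path(dir, paste0(id, "_mask.tif"))) >= 0.5
    rgb[array(rep(!mask, 3L), dim = dim(rgb))] <- NA_real_
    structure(list(rgb = rgb, mask = mask, mm_per_px = side$mm_per_px,
                   origin = side$origin, provenance = side$provenance),
              class = "calibrated_image")
  })
  names(images) <- patients$patient_id
  bili_cohort(patients, images)
}
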