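# run expr with a private RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# lower-median convention: for even n, the lower of the two middle values
lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]

#' Calibrated cohort container
#'
#' @param patients Data frame with at least `patient_id` and `tsb_mg_dl`
#'   (and optionally `site`, `skin_group`).
#' @param images Named list of `"calibrated_image"`s, names matching
#'   `patients$patient_id`.
#' @return Object of class `"bili_cohort"`.
#' @export
bili_cohort <- function(patients, images) {
  stopifnot(is.data.frame(patients),
            all(c("patient_id", "tsb_mg_dl") %in% names(patients)))
  patients$patient_id <- as.character(patients$patient_id)
  if (!all(patients$patient_id %in% names(images)))
    stop("invalid-parameter: every patient needs a calibrated image")
  images <- images[patients$patient_id]
  structure(list(patients = patients, images = images),
            class = "bili_cohort")
}

#' @export
print.bili_cohort <- function(x, ...) {
  cat(sprintf("Calibrated cohort: %d patients, TSB %.1f-%.1f mg/dL\n",
              nrow(x$patients), min(x$patients$tsb_mg_dl),
              max(x$patients$tsb_mg_dl)))
  if ("skin_group" %in% names(x$patients))
    print(table(x$patients$skin_group))
  invisible(x)
}

#' TSB stratification specifications
#'
#' `stage1_strata()` gives the ROI-optimization resampling design: four
#' TSB bins (0-5, 5-10, 10-15, 15-25 mg/dL), two training patients drawn
#' per bin (8 in total) and test patients 2/2/2/1 from the remainder
#' (7 in total). `stage2_strata()` gives the cross-validation design:
#' five bins (0-3.5, 3.5-6.5, 6.5-10, 10-15, 15-25 mg/dL) with one test
#' patient per bin and all remaining patients used for training.
#'
#' @return List with `edges`, `n_train_per_bin`, `n_test_per_bin`.
#' @export
stage1_strata <- function() {
  list(edges = c(0, 5, 10, 15, 25), n_train_per_bin = 2L,
       n_test_per_bin = c(2L, 2L, 2L, 1L))
}

#' @rdname stage1_strata
#' @export
stage2_strata <- function() {
  list(edges = c(0, 3.5, 6.5, 10, 15, 25), n_train_per_bin = NULL,
       n_test_per_bin = 1L)
}

#' Stratified train/test split over TSB bins
#'
#' Samples without replacement within TSB bins. With a per-bin training
#' count, training patients are drawn first and test patients from the
#' remainder; with `n_train_per_bin = NULL`, test patients are drawn and
#' all remaining patients form the training set.
#'
#' @param patients Data frame with `patient_id` and `tsb_mg_dl`.
#' @param strata A [stage1_strata()]-style list.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with character vectors `train` and `test`.
#' @export
stratified_split <- function(patients, strata, seed) {
  edges <- strata$edges
  bins <- cut(patients$tsb_mg_dl, breaks = edges, include.lowest = TRUE)
  labs <- levels(bins)
  n_test <- rep_len(strata$n_test_per_bin, length(labs))
  n_train <- strata$n_train_per_bin
  with_seed(seed, {
    train <- character(0); test <- character(0)
    for (b in seq_along(labs)) {
      ids <- patients$patient_id[which(bins == labs[b])]
      if (!is.null(n_train)) {
        if (length(ids) < n_train)
          stop("stratification error: bin ", labs[b], " has ", length(ids),
               " patients, needs ", n_train, " for training")
        tr <- sample(ids, n_train)
        rest <- setdiff(ids, tr)
        if (length(rest) < n_test[b])
          stop("stratification error: bin ", labs[b],
               " cannot supply ", n_test[b], " test patients")
        te <- sample(rest, n_test[b])
        train <- c(train, tr); test <- c(test, te)
      } else {
        if (length(ids) < n_test[b] + 1L)
          stop("stratification error: bin ", labs[b], " has ", length(ids),
               " patients, needs ", n_test[b] + 1L)
        te <- sample(ids, n_test[b])
        test <- c(test, te)
      }
    }
    if (is.null(n_train)) train <- setdiff(patients$patient_id, test)
    list(train = train, test = test)
  })
}

# per-arc feature column over a fixed set of images; NULL on degeneracy
feature_column <- function(images, roi) {
  tryCatch(
    vapply(images, function(img) {
      m <- arc_roi_mask(roi, dim(img$rgb)[1:2], img$mm_per_px, img$origin)
      m <- m & img$mask
      if (!any(m)) stop("masked-roi")
      mean(img$rgb[, , channel_index(roi$channel)][m])
    }, 0),
    error = function(e) NULL)
}

#' Stage-1 objective: held-out sum of squared prediction errors
#'
#' Fits the gamma GLM on the training patients' ROI features and returns
#' the sum of squared prediction errors (mg/dL squared) on the
#' evaluation patients. Degenerate ROI sets (an arc missing the image or
#' fully saturated) and failed fits return `Inf`, acting as the pattern
#' search barrier.
#'
#' @param rois A [roi_set()].
#' @param cohort A [bili_cohort()].
#' @param train_ids,eval_ids Patient id vectors.
#' @return Scalar SSE, or `Inf`.
#' @export
roi_objective <- function(rois, cohort, train_ids, eval_ids) {
  ids <- c(train_ids, eval_ids)
  imgs <- cohort$images[ids]
  cols <- lapply(rois$rois, function(r) feature_column(imgs, r))
  if (any(vapply(cols, is.null, logical(1)))) return(Inf)
  feats <- do.call(cbind, cols)
  rownames(feats) <- ids
  tsb <- stats::setNames(cohort$patients$tsb_mg_dl, cohort$patients$patient_id)
  fit <- tryCatch(suppressWarnings(
    fit_gamma_glm(feats[train_ids, , drop = FALSE], tsb[train_ids])),
    error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  pred <- predict(fit, feats[eval_ids, , drop = FALSE])
  sse <- sum((pred - tsb[eval_ids])^2)
  if (!is.finite(sse)) Inf else sse
}

# cached objective over the flattened parameter vector: one memo slot per
# arc, so coordinate polls that move a single arc only recompute that
# arc's feature column
make_roi_objective <- function(template, cohort, train_ids, eval_ids) {
  ids <- c(train_ids, eval_ids)
  imgs <- cohort$images[ids]
  tsb <- stats::setNames(cohort$patients$tsb_mg_dl, cohort$patients$patient_id)
  n_roi <- length(template$rois)
  cache_par <- vector("list", n_roi)
  cache_col <- vector("list", n_roi)
  is_train <- seq_along(ids) <= length(train_ids)

  function(par) {
    cols <- vector("list", n_roi)
    for (i in seq_len(n_roi)) {
      p <- par[(3L * (i - 1L) + 1L):(3L * i)]
      if (!is.null(cache_par[[i]]) && identical(cache_par[[i]], p)) {
        cols[[i]] <- cache_col[[i]]
      } else {
        roi <- template$rois[[i]]
        roi$radius <- p[1]; roi$width <- p[2]; roi$theta <- p[3]
        col <- feature_column(imgs, roi)
        if (is.null(col)) return(Inf)
        cache_par[[i]] <<- p
        cache_col[[i]] <<- col
        cols[[i]] <- col
      }
    }
    feats <- do.call(cbind, cols)
    fit <- tryCatch(suppressWarnings(
      fit_gamma_glm(feats[is_train, , drop = FALSE], tsb[ids[is_train]])),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    pred <- predict(fit, feats[!is_train, , drop = FALSE])
    sse <- sum((pred - tsb[ids[!is_train]])^2)
    if (!is.finite(sse)) Inf else sse
  }
}

#' Stage 1: resampled pattern-search optimization of ROI placements
#'
#' For each resample, draws a stratified train/test split, optimizes the
#' arc parameters (radius, width, angular centre per arc) by bounded
#' pattern search of the held-out SSE objective, and finally aggregates
#' the per-resample optima by the parameter-wise median over all
#' resamples (lower-median convention on even counts).
#'
#' @param cohort A [bili_cohort()].
#' @param init Starting [roi_set()]; also fixes composition, spans and
#'   bounds.
#' @param strata Resampling design, default [stage1_strata()].
#' @param n_resamples Number of resampled optimizations (3000 at full
#'   scale).
#' @param budget Objective evaluations per pattern search.
#' @param seed Integer seed; the full run is reproducible.
#' @return Object of class `"roi_stage1"`: `table` (resamples x
#'   parameters matrix of optimized values), `rois` (the median ROI
#'   set), `values` (final objective per resample), `seeds`.
#' @export
optimize_rois_stage1 <- function(cohort, init = default_roi_set(),
                                 strata = stage1_strata(),
                                 n_resamples = 3000L, budget = 500L,
                                 seed = 1L) {
  stopifnot(inherits(cohort, "bili_cohort"), inherits(init, "roi_set"))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_resamples))
  par0 <- roi_params(init)
  bv <- roi_bounds_vec(init)
  tab <- matrix(NA_real_, n_resamples, length(par0))
  vals <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    split <- stratified_split(cohort$patients, strata, seeds[r])
    obj <- make_roi_objective(init, cohort, split$train, split$test)
    ps <- pattern_search(obj, par0, bv$lower, bv$upper, budget = budget)
    tab[r, ] <- ps$par
    vals[r] <- ps$value
  }
  med <- apply(tab, 2, lower_median)
  structure(list(table = tab, rois = roi_from_params(init, med),
                 values = vals, seeds = seeds, init = init,
                 n_resamples = n_resamples, budget = budget, seed = seed),
            class = "roi_stage1")
}

#' @export
print.roi_stage1 <- function(x, ...) {
  cat(sprintf("Stage-1 ROI optimization: %d resamples, budget %d\n",
              x$n_resamples, x$budget))
  cat("Median ROI set:\n")
  print(x$rois)
  invisible(x)
}

#' Stage 2: stratified cross-validation of the gamma GLM
#'
#' Per iteration, draws a stratified test set (one patient per TSB bin),
#' fits the gamma GLM of TSB on the final-ROI features of the remaining
#' patients, and records the test predictions. After all iterations the
#' per-patient median prediction is computed.
#'
#' @param cohort A [bili_cohort()].
#' @param rois The final [roi_set()] (e.g. `stage1$rois`).
#' @param strata Cross-validation design, default [stage2_strata()].
#' @param n_iterations Number of cross-validations (10000 at full scale).
#' @param seed Integer seed.
#' @return Object of class `"cv_result"`: `per_patient_predictions`
#'   (named list of prediction vectors), `median_prediction` (named),
#'   `n_test_appearances`, `n_iterations`, `seed`.
#' @export
cross_validate_stage2 <- function(cohort, rois, strata = stage2_strata(),
                                  n_iterations = 10000L, seed = 1L) {
  stopifnot(inherits(cohort, "bili_cohort"), inherits(rois, "roi_set"))
  ids <- cohort$patients$patient_id
  feats <- t(vapply(cohort$images, extract_features,
                    numeric(length(rois$rois)), rois = rois))
  rownames(feats) <- ids
  tsb <- stats::setNames(cohort$patients$tsb_mg_dl, ids)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_iterations))

  pred_id <- character(0)
  pred_val <- numeric(0)
  n_skipped <- 0L
  for (it in seq_len(n_iterations)) {
    split <- stratified_split(cohort$patients, strata, seeds[it])
    fit <- tryCatch(suppressWarnings(
      fit_gamma_glm(feats[split$train, , drop = FALSE], tsb[split$train])),
      error = function(e) NULL)
    if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
    p <- predict(fit, feats[split$test, , drop = FALSE])
    pred_id <- c(pred_id, split$test)
    pred_val <- c(pred_val, p)
  }
  per_patient <- split(pred_val, factor(pred_id, levels = ids))
  medians <- vapply(per_patient, function(v)
    if (length(v)) stats::median(v) else NA_real_, 0)
  appearances <- lengths(per_patient)
  uncovered <- ids[appearances == 0L]
  if (length(uncovered))
    warning("coverage warning: patients never sampled into a test set: ",
            paste(uncovered, collapse = ", "))
  structure(list(per_patient_predictions = per_patient,
                 median_prediction = medians,
                 n_test_appearances = appearances,
                 n_iterations = n_iterations, n_skipped = n_skipped,
                 seed = seed, features = feats),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Stage-2 cross-validation: %d iterations (%d skipped), %d patients\n",
              x$n_iterations, x$n_skipped, length(x$median_prediction)))
  cat(sprintf("  test appearances per patient: %d-%d (median %.0f)\n",
              min(x$n_test_appearances), max(x$n_test_appearances),
              stats::median(x$n_test_appearances)))
  invisible(x)
}
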