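#' Fit the two-stage arc-ROI transcutaneous bilirubin estimator
#'
#' The central fitting function. Stage 1 optimizes the placement of
#' arc-shaped regions of interest (four blue, three green, two red by
#' default) by bounded pattern search of the held-out prediction error
#' under stratified resampling, aggregating the per-resample optima by
#' the parameter-wise median. Stage 2 cross-validates a gamma GLM of TSB
#' on the final-ROI features over stratified test sets and takes each
#' patient's median prediction. A full-data gamma GLM is also fitted for
#' prediction on new images, and agreement statistics (correlation,
#' Bland-Altman, RMSE by range and skin group) are computed from the
#' cross-validated medians.
#'
#' @param cohort A [bili_cohort()] of calibrated images with TSB values.
#' @param rois Optional fixed [roi_set()]; when supplied, stage 1 is
#'   skipped.
#' @param init Stage-1 starting ROI set.
#' @param n_resamples Stage-1 resampled optimizations (3000 at full
#'   scale).
#' @param budget Objective evaluations per pattern search.
#' @param n_iterations Stage-2 cross-validations (10000 at full scale).
#' @param seed Integer seed; the whole fit is reproducible.
#' @param range_edges TSB bin edges for the RMSE-by-range report.
#' @return Object of class `"tcb_fit"`.
#' @seealso [optimize_rois_stage1()], [cross_validate_stage2()],
#'   [agreement_report()]
#' @export
tcb_fit <- function(cohort, rois = NULL, init = default_roi_set(),
                    n_resamples = 3000L, budget = 500L,
                    n_iterations = 10000L, seed = 1L,
                    range_edges = c(0, 10, 25)) {
  stopifnot(inherits(cohort, "bili_cohort"))
  stage1 <- NULL
  if (is.null(rois)) {
    stage1 <- optimize_rois_stage1(cohort, init = init,
                                   n_resamples = n_resamples,
                                   budget = budget, seed = seed)
    rois <- stage1$rois
  }
  cv <- cross_validate_stage2(cohort, rois, n_iterations = n_iterations,
                              seed = seed + 1L)
  feats <- cv$features
  tsb <- cohort$patients$tsb_mg_dl
  glm_full <- suppressWarnings(fit_gamma_glm(feats, tsb))
  grp <- if ("skin_group" %in% names(cohort$patients))
    cohort$patients$skin_group else NULL
  agreement <- agreement_report(unname(cv$median_prediction), tsb,
                                range_edges = range_edges, group = grp)
  structure(list(cohort = cohort, rois = rois, stage1 = stage1, cv = cv,
                 glm_full = glm_full, agreement = agreement, seed = seed,
                 call = match.call()),
            class = "tcb_fit")
}

#' @export
print.tcb_fit <- function(x, ...) {
  cat("Two-stage arc-ROI TSB estimator\n")
  cat(sprintf("  %d patients, %d ROIs (%s)\n", nrow(x$cohort$patients),
              length(x$rois$rois),
              paste(names(table(vapply(x$rois$rois, `[[`, "", "channel"))),
                    table(vapply(x$rois$rois, `[[`, "", "channel")),
                    sep = ":", collapse = " ")))
  if (!is.null(x$stage1))
    cat(sprintf("  stage 1: %d resamples, budget %d\n",
                x$stage1$n_resamples, x$stage1$budget))
  cat(sprintf("  stage 2: %d cross-validations\n", x$cv$n_iterations))
  cat(sprintf("  r^2 = %.3f, bias = %.2f mg/dL, LOA %.2f to %.2f mg/dL\n",
              x$agreement$r_squared, x$agreement$bias,
              x$agreement$loa_upper, x$agreement$loa_lower))
  invisible(x)
}

#' @export
summary.tcb_fit <- function(object, ...) {
  print(object)
  cat("\nFinal ROI set:\n")
  print(object$rois)
  cat("\n")
  print(object$agreement)
  cat("\nFull-data gamma GLM:\n")
  print(object$glm_full)
  invisible(object)
}

#' @export
coef.tcb_fit <- function(object, ...) coef(object$glm_full)

#' @export
fitted.tcb_fit <- function(object, ...) object$cv$median_prediction

#' @export
residuals.tcb_fit <- function(object, ...) {
  object$cv$median_prediction -
    stats::setNames(object$cohort$patients$tsb_mg_dl,
                    object$cohort$patients$patient_id)
}

#' Predict TSB for new calibrated images
#'
#' Extracts the fitted arc-ROI features from each new image and applies
#' the full-data gamma GLM.
#'
#' @param object A `"tcb_fit"`.
#' @param newdata A `"calibrated_image"`, a list of them, or a feature
#'   matrix with one column per ROI.
#' @param ... Unused.
#' @return Predicted TSB, mg/dL (strictly positive).
#' @export
predict.tcb_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "calibrated_image")) newdata <- list(newdata)
  if (is.list(newdata) && !is.data.frame(newdata)) {
    feats <- t(vapply(newdata, extract_features,
                      numeric(length(object$rois$rois)), rois = object$rois))
  } else feats <- as.matrix(newdata)
  predict(object$glm_full, feats)
}

#' Diagnostic plots: correlation and Bland-Altman
#'
#' Left: cross-validated median predictions against TSB with the
#' identity line. Right: Bland-Altman plot of the differences with bias
#' and 95% limits of agreement.
#'
#' @param x A `"tcb_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tcb_fit <- function(x, ...) {
  tsb <- x$cohort$patients$tsb_mg_dl
  pred <- unname(x$cv$median_prediction)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  lim <- range(c(tsb, pred), na.rm = TRUE)
  graphics::plot(tsb, pred, xlim = lim, ylim = lim,
                 xlab = "TSB (mg/dL)", ylab = "Predicted TSB (mg/dL)",
                 main = sprintf("r^2 = %.2f", x$agreement$r_squared), ...)
  graphics::abline(0, 1, lty = 2)
  m <- (pred + tsb) / 2
  d <- pred - tsb
  graphics::plot(m, d, xlab = "Mean of methods (mg/dL)",
                 ylab = "Prediction - TSB (mg/dL)", main = "Bland-Altman",
                 ...)
  graphics::abline(h = x$agreement$bias, col = "blue")
  graphics::abline(h = c(x$agreement$loa_lower, x$agreement$loa_upper),
                   col = "red", lty = 2)
  invisible(x)
}
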