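#' Squared Pearson correlation between predictions and TSB
#'
#' @param pred,tsb Equal-length numeric vectors (mg/dL), length >= 3,
#'   each with nonzero variance.
#' @return List with `r_squared` and `p` (from the correlation
#'   t-statistic).
#' @export
r_squared <- function(pred, tsb) {
  if (length(pred) != length(tsb) || length(pred) < 3L)
    stop("insufficient-data: need equal lengths >= 3")
  if (stats::sd(pred) == 0 || stats::sd(tsb) == 0)
    stop("undefined-correlation: zero variance")
  ct <- stats::cor.test(pred, tsb, method = "pearson")
  list(r_squared = unname(ct$estimate^2), p = ct$p.value)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken as `pred - tsb`, so a negative bias means the
#' device under-predicts the blood value. Limits of agreement are
#' `bias +/- 1.96 * sd` with the sample (n-1) standard deviation.
#'
#' @param pred,tsb Equal-length numeric vectors, length >= 2.
#' @return List with `bias`, `loa_upper`, `loa_lower`, `loa_span`
#'   (= upper - lower = `2 * 1.96 * sd`), `sd_diff`, and `bias_p` (two
#'   sided one-sample t-test of the differences against zero; `NA` when
#'   the differences are constant).
#' @export
bland_altman <- function(pred, tsb) {
  if (length(pred) != length(tsb) || length(pred) < 2L)
    stop("insufficient-data: need equal lengths >= 2")
  d <- pred - tsb
  bias <- mean(d)
  s <- stats::sd(d)
  bias_p <- if (s > 0) stats::t.test(d)$p.value else NA_real_
  list(bias = bias, loa_upper = bias + 1.96 * s, loa_lower = bias - 1.96 * s,
       loa_span = 2 * 1.96 * s, sd_diff = s, bias_p = bias_p)
}

#' RMSE within TSB ranges
#'
#' @param pred,tsb Numeric vectors; binning is by the TSB value.
#' @param edges Increasing bin edges, mg/dL.
#' @return Named numeric vector of per-bin RMSE; empty bins are absent.
#' @export
rmse_by_range <- function(pred, tsb, edges = c(0, 10, 25)) {
  stopifnot(length(pred) == length(tsb), all(diff(edges) > 0))
  bins <- cut(tsb, breaks = edges, include.lowest = TRUE)
  err2 <- (pred - tsb)^2
  out <- tapply(err2, bins, function(e) sqrt(mean(e)))
  out[!is.na(out)]
}

#' RMSE by skin group with a between-group error test
#'
#' Per-group RMSE plus a Welch two-sided two-sample t-test on the
#' absolute errors of the two compared groups. Groups with fewer than
#' two members are excluded from the test with a warning.
#'
#' @param pred,tsb Numeric vectors.
#' @param group Group labels (same length).
#' @param compare Two group labels to test against each other; defaults
#'   to the two largest groups.
#' @return List with `rmse` (named), `test_groups`, `t`, `p`.
#' @export
rmse_by_group <- function(pred, tsb, group, compare = NULL) {
  stopifnot(length(pred) == length(tsb), length(group) == length(pred))
  group <- as.character(group)
  abs_err <- abs(pred - tsb)
  rmse <- tapply((pred - tsb)^2, group, function(e) sqrt(mean(e)))
  sizes <- table(group)
  eligible <- names(sizes)[sizes >= 2L]
  if (length(eligible) < length(sizes))
    warning("groups excluded from the test (< 2 members): ",
            paste(setdiff(names(sizes), eligible), collapse = ", "))
  if (is.null(compare))
    compare <- names(sort(sizes[eligible], decreasing = TRUE))[1:2]
  if (length(compare) != 2L || any(!compare %in% eligible))
    stop("insufficient-data: need two groups with >= 2 members")
  a <- abs_err[group == compare[1]]
  b <- abs_err[group == compare[2]]
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # Welch statistic degenerates with two constant samples
    t_stat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(rmse = rmse, test_groups = compare, t = t_stat, p = p)
}

#' Full agreement report
#'
#' Correlation, Bland-Altman statistics, RMSE by TSB range and (when
#' group labels are supplied) RMSE by skin group with the between-group
#' error test.
#'
#' @param pred,tsb Numeric vectors, mg/dL.
#' @param range_edges TSB bin edges for [rmse_by_range()].
#' @param group Optional skin-group labels.
#' @return Object of class `"agreement_report"`.
#' @export
agreement_report <- function(pred, tsb, range_edges = c(0, 10, 25),
                             group = NULL) {
  rs <- r_squared(pred, tsb)
  ba <- bland_altman(pred, tsb)
  out <- list(r_squared = rs$r_squared, p_value = rs$p,
              bias = ba$bias, loa_upper = ba$loa_upper,
              loa_lower = ba$loa_lower, loa_span = ba$loa_span,
              bias_p = ba$bias_p,
              rmse_by_range = rmse_by_range(pred, tsb, range_edges))
  if (!is.null(group)) {
    g <- rmse_by_group(pred, tsb, group)
    out$rmse_by_group <- g$rmse
    out$group_test_p <- g$p
    out$group_test_groups <- g$test_groups
  }
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report (prediction - TSB)\n")
  cat(sprintf("  r^2 = %.3f (p = %.3g)\n", x$r_squared, x$p_value))
  cat(sprintf("  bias = %.2f mg/dL (p = %.2g), LOA %.2f to %.2f (span %.2f)\n",
              x$bias, x$bias_p, x$loa_upper, x$loa_lower, x$loa_span))
  cat("  RMSE by TSB range (mg/dL):\n")
  print(round(x$rmse_by_range, 2))
  if (!is.null(x$rmse_by_group)) {
    cat("  RMSE by skin group (mg/dL):\n")
    print(round(x$rmse_by_group, 2))
    cat(sprintf("  group error test (%s vs %s): p = %.3g\n",
                x$group_test_groups[1], x$group_test_groups[2],
                x$group_test_p))
  }
  invisible(x)
}
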