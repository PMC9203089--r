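#' Fit a gamma GLM of TSB on ROI features
#'
#' Gamma-family generalized linear model (non-negative response) fitted
#' by iteratively reweighted least squares, by default with a log link so
#' predictions are strictly positive. This wraps [stats::glm()] behind
#' the estimator's interface.
#'
#' With fewer observations than coefficients -- as happens in the
#' stage-1 resamples, where eight training patients inform nine ROI
#' features plus an intercept -- the fit is computed on the pivoted
#' column basis (aliased coefficients dropped) and flagged
#' `underdetermined`; such a fit interpolates its training data and is
#' only meaningful through its held-out predictions. A design that is
#' rank-deficient despite having enough rows raises a singular-design
#' error so callers can discard the resample.
#'
#' @param x Feature matrix (rows = patients).
#' @param y Positive response vector (TSB, mg/dL).
#' @param link `"log"` (default) or `"inverse"`.
#' @param maxit IRLS iteration cap.
#' @return Object of class `"gamma_glm"` with `coefficients` (intercept
#'   first), `dispersion`, `converged`, `underdetermined`, `link`.
#' @export
fit_gamma_glm <- function(x, y, link = c("log", "inverse"), maxit = 100L) {
  link <- match.arg(link)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("dimension error: length(y) != nrow(x)")
  if (any(!is.finite(y)) || any(y <= 0))
    stop("invalid-response: gamma GLM requires strictly positive TSB")
  underdetermined <- nrow(x) < ncol(x) + 1L
  if (ncol(x) == 0L) {
    dat <- data.frame(y = y)
    form <- y ~ 1
  } else {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    dat <- data.frame(y = y, x)
    form <- y ~ .
  }
  fit <- stats::glm(form, data = dat, family = stats::Gamma(link = link),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = maxit))
  aliased <- is.na(stats::coef(fit))
  if (any(aliased) && !underdetermined)
    stop("singular-design: aliased columns ",
         paste(names(stats::coef(fit))[aliased], collapse = ", "))
  df_r <- stats::df.residual(fit)
  dispersion <- if (df_r > 0) {
    mu <- stats::fitted(fit)
    sum(((y - mu) / mu)^2) / df_r
  } else NA_real_
  structure(list(coefficients = stats::coef(fit), link = link,
                 dispersion = dispersion, converged = fit$converged,
                 underdetermined = underdetermined, glm = fit,
                 n = nrow(x), p = ncol(x)),
            class = "gamma_glm")
}

#' Predict TSB from a gamma GLM fit
#'
#' Inverse link of the linear predictor; strictly positive under the log
#' link. The linear predictor is clamped to `[-30, 30]` on the log scale
#' to keep interpolating stage-1 fits from overflowing.
#'
#' @param object A `"gamma_glm"`.
#' @param newdata Feature matrix or vector with `object$p` columns.
#' @param ... Unused.
#' @return Predicted TSB, mg/dL.
#' @export
predict.gamma_glm <- function(object, newdata, ...) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = if (object$p == 0L) length(newdata) else 1L,
                      ncol = max(object$p, 0L))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("dimension error: expected ", object$p, " features, got ",
         ncol(newdata))
  beta <- object$coefficients
  beta[is.na(beta)] <- 0
  eta <- if (object$p == 0L) rep(beta[1], max(nrow(newdata), 1L))
         else drop(cbind(1, newdata) %*% beta)
  if (object$link == "log") {
    exp(pmin(pmax(eta, -30), 30))
  } else {
    1 / pmax(eta, 1e-8)
  }
}

#' @export
print.gamma_glm <- function(x, ...) {
  cat(sprintf("Gamma GLM (%s link), %d obs, %d features%s%s\n", x$link, x$n,
              x$p, if (x$converged) ", converged" else ", NOT converged",
              if (x$underdetermined) ", underdetermined" else ""))
  print(round(x$coefficients, 4))
  if (!is.na(x$dispersion))
    cat(sprintf("  dispersion: %.4f\n", x$dispersion))
  invisible(x)
}

#' @export
coef.gamma_glm <- function(object, ...) object$coefficients
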