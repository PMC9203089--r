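#' Diffusion-theory spatially resolved reflectance
#'
#' Steady-state diffuse reflectance from a homogeneous semi-infinite
#' medium at radial distance `rho` from a pencil source, using the
#' standard two-term dipole (image source) expression with the effective
#' attenuation coefficient `mueff = sqrt(3 * mua * (mua + mus'))`,
#' `mus' = mus * (1 - g)`. The extrapolated boundary accounts for the
#' refractive-index mismatch through the internal-reflection parameter
#' `A`. This closed form serves as the independent cross-check for the
#' Monte-Carlo transport kernel and as the fast forward model of the
#' synthetic-cohort generator.
#'
#' Results carry a logical attribute `"near_field"`, set where `rho` is
#' within one transport mean free path of the source, flagging distances
#' where the diffusion approximation is not trustworthy.
#'
#' @param model A single-layer semi-infinite [layered_skin()] model (use
#'   the output of [build_default_skin()] only after homogenizing, or any
#'   one-layer model).
#' @param rho Radial distance(s) from the source, mm.
#' @param wavelength Single wavelength, nm.
#' @return Reflectance per unit area (1/mm^2), vectorized over `rho`.
#' @examples
#' m <- layered_skin(list(skin_layer("medium", Inf, 0.01, 10, g = 0.9, n = 1)))
#' diffusion_reflectance(m, rho = 5, wavelength = 550)
#' @export
diffusion_reflectance <- function(model, rho, wavelength) {
  stopifnot(inherits(model, "skin_model"))
  if (length(model$layers) != 1L || !model$layers[[1]]$semi_infinite)
    stop("invalid-parameter: diffusion oracle needs a single semi-infinite layer")
  lay <- model$layers[[1]]
  mua <- lay$mua(wavelength)
  musp <- lay$mus(wavelength) * (1 - lay$g)
  mutp <- mua + musp
  if (mutp <= 0) stop("invalid-parameter: mua + mus' must be positive")

  mueff <- sqrt(3 * mua * mutp)
  z0 <- 1 / mutp
  D <- 1 / (3 * mutp)
  n_rel <- lay$n / model$n_ambient
  if (abs(n_rel - 1) < 1e-12) {
    A <- 1
  } else {
    # Groenhuis polynomial approximation for the internal reflection
    r_d <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
    A <- (1 + r_d) / (1 - r_d)
  }
  zb <- 2 * A * D

  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  R <- (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
          (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
  attr(R, "near_field") <- rho <= 1 / mutp
  R
}

#' Effective attenuation coefficient
#'
#' `sqrt(3 * mua * (mua + mus'))`, the decay constant of the diffuse
#' fluence far from the source.
#'
#' @param mua Absorption coefficient, 1/mm.
#' @param musp Reduced scattering coefficient `mus * (1 - g)`, 1/mm.
#' @return mueff in 1/mm.
#' @export
mu_eff <- function(mua, musp) sqrt(3 * mua * (mua + musp))
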