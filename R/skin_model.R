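#' @useDynLib biliphone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.biliphone_env <- new.env(parent = emptyenv())

#' Built-in chromophore absorption table
#'
#' Returns the packaged per-wavelength absorption table used by
#' [build_default_skin()]: interior-melanosome absorption, oxygenated and
#' deoxygenated whole-blood absorption, the dermal bilirubin proxy
#' absorption per mg/dL, and a flat tissue baseline, all in 1/mm. The
#' values are documented package defaults with the qualitative shape of
#' the standard spectra (melanin power law, hemoglobin Soret/Q bands,
#' bilirubin band near 460 nm); every layer property is user-overridable
#' through [layered_skin()].
#'
#' @param path Optional path to a replacement CSV with the same columns.
#' @return Data frame with columns `wavelength_nm`, `mua_melanosome`,
#'   `mua_blood_oxy`, `mua_blood_deoxy`, `mua_bilirubin_per_mgdl`,
#'   `mua_baseline`.
#' @export
chromophore_table <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.biliphone_env$chromophores)) {
      f <- system.file("extdata", "chromophores.csv", package = "biliphone",
                       mustWork = TRUE)
      .biliphone_env$chromophores <- utils::read.csv(f)
    }
    return(.biliphone_env$chromophores)
  }
  utils::read.csv(path)
}

# linear interpolation of one chromophore column at requested wavelengths
chromophore_mua <- function(column, wavelengths, table = chromophore_table()) {
  wl <- table$wavelength_nm
  if (any(wavelengths < min(wl)) || any(wavelengths > max(wl)))
    stop("unsupported-wavelength: outside the chromophore table range (",
         min(wl), "-", max(wl), " nm)")
  stats::approx(wl, table[[column]], xout = wavelengths)$y
}

#' Construct a single tissue layer
#'
#' @param name Layer label.
#' @param thickness Thickness in mm, or `Inf` for a semi-infinite final
#'   layer.
#' @param mua Absorption coefficient: a function of wavelength (nm)
#'   returning 1/mm, or a single non-negative number (flat spectrum).
#' @param mus Scattering coefficient: same conventions as `mua`, must be
#'   positive.
#' @param g Scattering anisotropy, in (-1, 1).
#' @param n Refractive index, >= 1.
#' @return Object of class `"skin_layer"`.
#' @export
skin_layer <- function(name, thickness, mua, mus, g = 0.9, n = 1.4) {
  if (!is.function(mua)) { mua_v <- as.numeric(mua); mua <- function(wl) rep(mua_v, length(wl)) }
  if (!is.function(mus)) { mus_v <- as.numeric(mus); mus <- function(wl) rep(mus_v, length(wl)) }
  if (!(thickness > 0)) stop("invalid-parameter: thickness must be > 0 (or Inf)")
  if (g <= -1 || g >= 1) stop("invalid-parameter: g must be in (-1, 1)")
  if (n < 1) stop("invalid-parameter: refractive index must be >= 1")
  structure(list(name = name, thickness = thickness, mua = mua, mus = mus,
                 g = g, n = n, semi_infinite = is.infinite(thickness)),
            class = "skin_layer")
}

#' Assemble a layered skin model
#'
#' @param layers List of [skin_layer()] objects, top first; the last layer
#'   may be semi-infinite.
#' @param n_ambient Refractive index of the medium above the tissue.
#' @param params Optional named list of model parameters kept as metadata.
#' @return Object of class `"skin_model"`.
#' @export
layered_skin <- function(layers, n_ambient = 1.0, params = list()) {
  if (length(layers) < 1L) stop("invalid-parameter: at least one layer required")
  stopifnot(all(vapply(layers, inherits, logical(1), "skin_layer")))
  fin <- vapply(layers, function(l) is.finite(l$thickness), logical(1))
  if (any(!fin[-length(layers)]))
    stop("invalid-parameter: only the last layer may be semi-infinite")
  structure(list(layers = layers, n_ambient = n_ambient, params = params),
            class = "skin_model")
}

#' Default neonatal skin model
#'
#' Builds an epidermis / dermis / semi-infinite subcutis model. Epidermal
#' absorption mixes interior-melanosome absorption at the given fractional
#' volume with the tissue baseline; dermal absorption adds whole-blood
#' absorption at the given blood volume fraction and oxygen saturation plus
#' a bilirubin term linear in the dermal bilirubin proxy concentration.
#' Scattering follows a power-law decay in wavelength,
#' `mus'(lambda) = mus'(500) * (lambda/500)^-b`, divided by `1 - g`.
#' Layer thicknesses and scattering amplitudes are documented package
#' defaults for thin neonatal skin.
#'
#' Bilirubin absorbs in a band around 460 nm, so increasing
#' `bilirubin_mg_dl` raises dermal absorption in the blue channel while
#' leaving the red channel essentially unchanged; melanin raises epidermal
#' absorption across the whole visible range.
#'
#' @param melanosome_fraction Fractional volume of melanosomes in the
#'   epidermis, in `[0, 1]`. 0.10 models darkly pigmented skin.
#' @param bilirubin_mg_dl Dermal bilirubin proxy concentration, mg/dL.
#' @param blood_volume_fraction Dermal blood volume fraction, in `[0, 1]`.
#' @param oxygen_saturation Hemoglobin oxygen saturation, in `[0, 1]`.
#' @return A [layered_skin()] model; `model$params$pigmentation` is
#'   `"dark"` when `melanosome_fraction >= 0.06`, else `"light"`.
#' @examples
#' m <- build_default_skin(melanosome_fraction = 0.10, bilirubin_mg_dl = 10)
#' skin_mua(m, c(474, 554, 635))
#' @export
build_default_skin <- function(melanosome_fraction = 0.10,
                               bilirubin_mg_dl = 0,
                               blood_volume_fraction = 0.005,
                               oxygen_saturation = 0.75) {
  for (v in c(melanosome_fraction, blood_volume_fraction, oxygen_saturation))
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("invalid-parameter: fractions must lie in [0, 1]")
  if (bilirubin_mg_dl < 0)
    stop("invalid-parameter: bilirubin_mg_dl must be >= 0")

  tab <- chromophore_table()
  f_mel <- melanosome_fraction
  bvf <- blood_volume_fraction
  s <- oxygen_saturation
  bili <- bilirubin_mg_dl

  mua_epi <- function(wl)
    f_mel * chromophore_mua("mua_melanosome", wl, tab) +
      (1 - f_mel) * chromophore_mua("mua_baseline", wl, tab)
  mua_derm <- function(wl)
    bvf * (s * chromophore_mua("mua_blood_oxy", wl, tab) +
             (1 - s) * chromophore_mua("mua_blood_deoxy", wl, tab)) +
      bili * chromophore_mua("mua_bilirubin_per_mgdl", wl, tab) +
      chromophore_mua("mua_baseline", wl, tab)
  mua_sub <- function(wl) chromophore_mua("mua_baseline", wl, tab)

  musp_pl <- function(a, b) function(wl) a * (wl / 500)^(-b)
  g <- 0.9
  mus_from_musp <- function(musp) function(wl) musp(wl) / (1 - g)

  layers <- list(
    skin_layer("epidermis", 0.06, mua_epi,
               mus_from_musp(musp_pl(4.0, 1.3)), g = g, n = 1.4),
    skin_layer("dermis", 1.2, mua_derm,
               mus_from_musp(musp_pl(4.0, 1.3)), g = g, n = 1.4),
    skin_layer("subcutis", Inf, mua_sub,
               mus_from_musp(musp_pl(2.5, 0.7)), g = g, n = 1.4))

  layered_skin(layers, n_ambient = 1.0,
               params = list(melanosome_fraction = f_mel,
                             bilirubin_mg_dl = bili,
                             blood_volume_fraction = bvf,
                             oxygen_saturation = s,
                             pigmentation = if (f_mel >= 0.06) "dark" else "light"))
}

#' Per-layer absorption / scattering spectra
#'
#' @param model A `"skin_model"`.
#' @param wavelengths Wavelengths in nm.
#' @return Matrix (layers x wavelengths) of coefficients in 1/mm.
#' @export
skin_mua <- function(model, wavelengths) {
  stopifnot(inherits(model, "skin_model"))
  out <- do.call(rbind, lapply(model$layers, function(l) l$mua(wavelengths)))
  dimnames(out) <- list(vapply(model$layers, `[[`, "", "name"), wavelengths)
  out
}

#' @rdname skin_mua
#' @export
skin_mus <- function(model, wavelengths) {
  stopifnot(inherits(model, "skin_model"))
  out <- do.call(rbind, lapply(model$layers, function(l) l$mus(wavelengths)))
  dimnames(out) <- list(vapply(model$layers, `[[`, "", "name"), wavelengths)
  out
}

#' @export
print.skin_model <- function(x, ...) {
  cat("Layered skin model (", length(x$layers), " layers)\n", sep = "")
  for (l in x$layers)
    cat(sprintf("  %-10s %s mm  g=%.2f n=%.2f\n", l$name,
                if (is.infinite(l$thickness)) "semi-inf" else
                  sprintf("%8.3f", l$thickness), l$g, l$n))
  if (length(x$params))
    cat("  params:", paste(names(x$params),
                           vapply(x$params, format, ""), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

# Collapse the model to a single semi-infinite layer for diffusion-theory
# work: absorption is a path-weighted mix of epidermis and dermis (the
# epidermis is thin, so it carries a small fixed weight), scattering and
# optics are taken from the dominant dermal layer.
homogenize_skin <- function(model, epidermis_weight = 0.15) {
  stopifnot(inherits(model, "skin_model"))
  ls <- model$layers
  if (length(ls) == 1L) return(model)
  mua_fun <- function(wl) {
    epidermis_weight * ls[[1]]$mua(wl) +
      (1 - epidermis_weight) * ls[[2]]$mua(wl)
  }
  one <- skin_layer("homogenized", Inf, mua_fun, ls[[2]]$mus,
                    g = ls[[2]]$g, n = ls[[2]]$n)
  layered_skin(list(one), n_ambient = model$n_ambient, params = model$params)
}
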