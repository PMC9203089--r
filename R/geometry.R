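#' Adapter illumination/collection geometry
#'
#' Describes the snap-on adapter that turns the phone flash and camera into
#' a spatially offset diffuse-reflectance probe: a circular illumination
#' spot, a rectangular camera field of view (FOV) displaced laterally from
#' the spot, and the acceptance cone of the collection optics.
#'
#' Coordinates are in millimetres on the skin surface. The origin is the
#' centre of the illumination spot's surface projection; the x axis points
#' toward the FOV, which occupies
#' `x` in `[spot_radius + edge_offset, spot_radius + edge_offset + fov[2]]`
#' and `y` in `[-fov[1]/2, fov[1]/2]`.
#'
#' @param spot_radius Illumination beam radius at the skin, mm.
#' @param edge_offset Gap between the proximal beam edge and the proximal
#'   FOV edge, mm. The two configurations of interest are 1.6 and 0.
#' @param fov Field of view as `c(height, width)` in mm.
#' @param acceptance_half_angle Half angle (degrees, in air) of the cone
#'   within which exiting photons are collected.
#' @param incidence_angle Beam angle from the surface normal, degrees.
#' @param adapter_thickness Adapter stand-off, mm (metadata only).
#' @return An object of class `"adapter_geometry"`.
#' @examples
#' g <- adapter_geometry(edge_offset = 0)
#' center_offset(g)  # 7.5 mm
#' @export
adapter_geometry <- function(spot_radius = 1.5, edge_offset = 1.6,
                             fov = c(9, 12), acceptance_half_angle = 21,
                             incidence_angle = 30, adapter_thickness = 10) {
  if (!is.numeric(spot_radius) || length(spot_radius) != 1L || spot_radius <= 0)
    stop("invalid-parameter: 'spot_radius' must be a positive scalar (mm)")
  if (!is.numeric(edge_offset) || length(edge_offset) != 1L || edge_offset < 0)
    stop("invalid-parameter: 'edge_offset' must be a non-negative scalar (mm)")
  if (!is.numeric(fov) || length(fov) != 2L || any(fov <= 0))
    stop("invalid-parameter: 'fov' must be c(height, width) with both > 0")
  if (acceptance_half_angle < 0 || acceptance_half_angle >= 90)
    stop("invalid-parameter: 'acceptance_half_angle' must be in [0, 90)")
  structure(list(spot_radius = spot_radius, edge_offset = edge_offset,
                 fov = as.numeric(fov),
                 acceptance_half_angle = acceptance_half_angle,
                 incidence_angle = incidence_angle,
                 adapter_thickness = adapter_thickness),
            class = "adapter_geometry")
}

#' @export
print.adapter_geometry <- function(x, ...) {
  cat("Adapter geometry\n")
  cat(sprintf("  spot radius:     %.2f mm\n", x$spot_radius))
  cat(sprintf("  edge offset:     %.2f mm\n", x$edge_offset))
  cat(sprintf("  FOV (h x w):     %.1f x %.1f mm\n", x$fov[1], x$fov[2]))
  cat(sprintf("  centre offset:   %.2f mm\n", center_offset(x)))
  cat(sprintf("  acceptance:      %.1f deg half-angle\n",
              x$acceptance_half_angle))
  cat(sprintf("  incidence:       %.1f deg\n", x$incidence_angle))
  invisible(x)
}

#' Source-centre to FOV-centre offset
#'
#' Distance from the centre of the illumination spot to the centre of the
#' camera field of view: `spot_radius + edge_offset + fov_width / 2`.
#' For the default 12 mm wide FOV and 1.5 mm spot this gives 7.5 mm at
#' zero edge offset and 9.1 mm at a 1.6 mm edge offset.
#'
#' @param geometry An [adapter_geometry()].
#' @return Offset in mm.
#' @export
center_offset <- function(geometry) {
  stopifnot(inherits(geometry, "adapter_geometry"))
  geometry$spot_radius + geometry$edge_offset + geometry$fov[2] / 2
}

# FOV rectangle in surface coordinates: c(x0, x1, y0, y1)
fov_rect <- function(geometry) {
  x0 <- geometry$spot_radius + geometry$edge_offset
  c(x0, x0 + geometry$fov[2], -geometry$fov[1] / 2, geometry$fov[1] / 2)
}

#' Spectral sampling grid
#'
#' @param wavelengths Strictly increasing wavelengths in nm, within the
#'   400-700 nm range covered by the built-in chromophore tables.
#' @return Validated numeric vector of class `"spectral_grid"`.
#' @export
spectral_grid <- function(wavelengths = seq(400, 700, by = 10)) {
  w <- as.numeric(wavelengths)
  if (length(w) == 0L) stop("invalid-parameter: empty spectral grid")
  if (any(diff(w) <= 0))
    stop("invalid-parameter: wavelengths must be strictly increasing")
  if (min(w) < 400 || max(w) > 700)
    stop("unsupported-wavelength: grid must lie within 400-700 nm")
  structure(w, class = "spectral_grid")
}

#' RGB filter channel bank
#'
#' The triple band-pass filter passbands: blue 474 +/- 10 nm, green
#' 554 +/- 10 nm, red 635 +/- 10 nm by default.
#'
#' @param bands Data frame with columns `name`, `center`, `halfwidth` (nm).
#' @return Object of class `"channel_bank"` (ordered blue, green, red).
#' @export
channel_bank <- function(bands = data.frame(
                           name = c("blue", "green", "red"),
                           center = c(474, 554, 635),
                           halfwidth = c(10, 10, 10))) {
  stopifnot(is.data.frame(bands),
            all(c("name", "center", "halfwidth") %in% names(bands)))
  o <- order(bands$center)
  b <- bands[o, , drop = FALSE]
  lo <- b$center - b$halfwidth
  hi <- b$center + b$halfwidth
  if (any(hi[-nrow(b)] > lo[-1]))
    stop("invalid-parameter: channel bands overlap")
  rownames(b) <- NULL
  structure(b, class = c("channel_bank", "data.frame"))
}
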