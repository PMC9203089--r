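#' Arc-shaped region of interest
#'
#' An annular segment around the illumination-spot centre, the spatial
#' feature unit of the estimator: photons collected farther from the
#' source have travelled deeper, so arcs at different radii sample
#' different depth-weighted reflectance.
#'
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @param radius Mid-arc radius from the source centre, mm.
#' @param width Radial extent, mm; the inner edge `radius - width/2` must
#'   stay positive.
#' @param theta Angular centre, degrees (0 = toward the FOV centre line).
#' @param span Angular extent, degrees, in `(0, 360]`.
#' @return Object of class `"arc_roi"`.
#' @export
arc_roi <- function(channel = c("blue", "green", "red"), radius, width,
                    theta = 0, span = 90) {
  channel <- match.arg(channel)
  if (!(width > 0)) stop("invalid-parameter: width must be > 0")
  if (radius - width / 2 <= 0)
    stop("invalid-parameter: inner radius must be positive")
  if (span <= 0 || span > 360)
    stop("invalid-parameter: span must be in (0, 360]")
  structure(list(channel = channel, radius = radius, width = width,
                 theta = theta, span = span),
            class = "arc_roi")
}

#' Ordered set of arc ROIs with box bounds
#'
#' @param rois List of [arc_roi()]s.
#' @param bounds Per-parameter box constraints, a list with elements
#'   `radius`, `width`, `theta`, each `c(lower, upper)`.
#' @return Object of class `"roi_set"`.
#' @export
roi_set <- function(rois, bounds = default_roi_bounds()) {
  stopifnot(all(vapply(rois, inherits, logical(1), "arc_roi")))
  structure(list(rois = rois, bounds = bounds), class = "roi_set")
}

#' @rdname roi_set
#' @export
default_roi_bounds <- function() {
  list(radius = c(2.2, 9.5), width = c(0.4, 2.5), theta = c(-50, 50))
}

#' Default ROI composition
#'
#' Four blue, three green and two red arcs: the channel counts follow the
#' relative amount of unsaturated area per channel (blue largest, red
#' smallest). Initial radii are evenly spaced within each channel's
#' usable region, blue nearest the source where bilirubin contrast is
#' strongest; all arcs start centred on the FOV axis with a 90 degree
#' span.
#'
#' @param composition Named integer vector of arcs per channel.
#' @param span Angular span, degrees, shared by all arcs.
#' @param bounds Box bounds, see [default_roi_bounds()].
#' @return A [roi_set()].
#' @export
default_roi_set <- function(composition = c(blue = 4L, green = 3L, red = 2L),
                            span = 90, bounds = default_roi_bounds()) {
  ranges <- list(blue = c(3.0, 5.5), green = c(3.5, 7.0), red = c(4.0, 8.0))
  rois <- list()
  for (ch in names(composition)) {
    n <- composition[[ch]]
    if (n < 1L) next
    rr <- if (n == 1L) mean(ranges[[ch]]) else
      seq(ranges[[ch]][1], ranges[[ch]][2], length.out = n)
    for (r in rr)
      rois[[length(rois) + 1L]] <- arc_roi(ch, radius = r, width = 1.0,
                                           theta = 0, span = span)
  }
  roi_set(rois, bounds)
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set (", length(x$rois), " arcs)\n", sep = "")
  for (i in seq_along(x$rois)) {
    r <- x$rois[[i]]
    cat(sprintf("  %2d %-6s r=%.2f mm w=%.2f mm theta=%+.1f deg span=%.0f deg\n",
                i, r$channel, r$radius, r$width, r$theta, r$span))
  }
  invisible(x)
}

# flatten a roi_set to the free parameter vector (radius, width, theta per
# arc) and back; span and channel are fixed by configuration
roi_params <- function(rs) {
  unlist(lapply(rs$rois, function(r) c(r$radius, r$width, r$theta)))
}

roi_from_params <- function(rs, par) {
  stopifnot(length(par) == 3L * length(rs$rois))
  for (i in seq_along(rs$rois)) {
    p <- par[(3L * (i - 1L) + 1L):(3L * i)]
    rs$rois[[i]]$radius <- p[1]
    rs$rois[[i]]$width <- p[2]
    rs$rois[[i]]$theta <- p[3]
  }
  rs
}

roi_bounds_vec <- function(rs) {
  n <- length(rs$rois)
  list(lower = rep(c(rs$bounds$radius[1], rs$bounds$width[1],
                     rs$bounds$theta[1]), n),
       upper = rep(c(rs$bounds$radius[2], rs$bounds$width[2],
                     rs$bounds$theta[2]), n))
}

#' Pixel mask of an arc ROI
#'
#' A pixel belongs to the arc when its centre's radial distance from the
#' source lies in `[radius - width/2, radius + width/2]` and its angle is
#' within `span/2` of `theta` (angles wrap).
#'
#' @param roi An [arc_roi()].
#' @param shape Image dimensions `c(rows, cols)`.
#' @param mm_per_px Pixel pitch, mm.
#' @param origin mm coordinates `c(x, y)` of the outer corner of pixel
#'   `[1, 1]` relative to the source centre.
#' @return Logical matrix; errors if the arc misses the image entirely.
#' @export
arc_roi_mask <- function(roi, shape, mm_per_px, origin) {
  stopifnot(inherits(roi, "arc_roi"))
  img <- list(rgb = array(0, c(shape[1], shape[2], 1L)),
              mm_per_px = mm_per_px, origin = origin)
  co <- pixel_coords(img)
  r <- sqrt(co$x^2 + co$y^2)
  ang <- atan2(co$y, co$x) * 180 / pi
  dang <- abs(((ang - roi$theta + 180) %% 360) - 180)
  m <- r >= roi$radius - roi$width / 2 & r <= roi$radius + roi$width / 2 &
    dang <= roi$span / 2
  if (!any(m)) stop("degenerate-roi: arc does not intersect the image")
  m
}

channel_index <- function(channel) match(channel, c("red", "green", "blue"))

#' Mean reflectance features over a ROI set
#'
#' One feature per arc: the mean of the arc's channel over valid
#' (unsaturated, calibratable) pixels inside the arc mask, in the order
#' of the ROI set.
#'
#' @param image A `"calibrated_image"`.
#' @param rois A [roi_set()].
#' @return Named numeric feature vector.
#' @export
extract_features <- function(image, rois) {
  stopifnot(inherits(image, "calibrated_image"), inherits(rois, "roi_set"))
  vapply(seq_along(rois$rois), function(i) {
    roi <- rois$rois[[i]]
    m <- arc_roi_mask(roi, dim(image$rgb)[1:2], image$mm_per_px, image$origin)
    m <- m & image$mask
    if (!any(m))
      stop("masked-roi: ROI ", i, " (", roi$channel,
           ") is fully saturated or invalid")
    mean(image$rgb[, , channel_index(roi$channel)][m])
  }, 0) |> stats::setNames(paste0("roi", seq_along(rois$rois)))
}
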