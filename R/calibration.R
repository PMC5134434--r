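# Pixel-to-millimetre calibration via the aerial-photograph scale model:
# object size = image size (px) * pixel pitch (mm) * camera-object distance
# (mm) / focal length (mm). The side view is reflected by a plane mirror, so
# its distance is the fixed h3 + h4; the top-view distance h1 is recalibrated
# per image from the fruit height measured in the side view.

#' Camera geometry for the two-view capture platform
#'
#' @param focal_length_mm Lens focal length (default 8 mm).
#' @param pixel_size_mm Sensor pixel pitch in mm (default 0.0045, i.e.
#'   4.5 um).
#' @param h2_mm Camera-to-platform distance (default 450 mm).
#' @param h3_mm Camera-to-mirror distance (default 350 mm).
#' @param h4_mm Mirror-to-object distance (default 150 mm).
#' @param plane_fraction Fraction of the fruit height at which the top-view
#'   object plane sits (default 0.5: the widest section is assumed at
#'   mid-height).
#' @param h1_mm Camera-to-object-plane distance; normally left `NULL` and
#'   derived per image with [derive_h1()].
#' @return A `camera_geometry` object.
#' @export
camera_geometry <- function(focal_length_mm = 8, pixel_size_mm = 0.0045,
                            h2_mm = 450, h3_mm = 350, h4_mm = 150,
                            plane_fraction = 0.5, h1_mm = NULL) {
  if (focal_length_mm <= 0 || pixel_size_mm <= 0 ||
      h2_mm <= 0 || h3_mm <= 0 || h4_mm <= 0)
    stop("all camera distances and sizes must be positive", call. = FALSE)
  if (pixel_size_mm >= 0.1)
    stop("pixel_size_mm must be a sensor pitch in (0, 0.1) mm", call. = FALSE)
  if (focal_length_mm >= h2_mm || focal_length_mm >= h3_mm + h4_mm)
    stop("focal length must be smaller than the object distances", call. = FALSE)
  if (plane_fraction < 0 || plane_fraction > 1)
    stop("plane_fraction must be in [0, 1]", call. = FALSE)
  structure(list(focal_length_mm = focal_length_mm,
                 pixel_size_mm = pixel_size_mm,
                 h2_mm = h2_mm, h3_mm = h3_mm, h4_mm = h4_mm,
                 plane_fraction = plane_fraction, h1_mm = h1_mm),
            class = "camera_geometry")
}

#' @export
print.camera_geometry <- function(x, ...) {
  cat("Camera geometry: f =", x$focal_length_mm, "mm, pixel pitch =",
      x$pixel_size_mm * 1000, "um\n")
  cat("  h2 =", x$h2_mm, "mm, h3 =", x$h3_mm, "mm, h4 =", x$h4_mm, "mm",
      if (!is.null(x$h1_mm)) paste(", h1 =", round(x$h1_mm, 2), "mm"), "\n")
  invisible(x)
}

#' Convert a pixel extent to millimetres at a given distance
#'
#' `object size = image size x pixel size x distance / focal length`.
#'
#' @param image_size_px Extent in pixels (>= 0).
#' @param geometry A [camera_geometry()].
#' @param distance_mm Camera-to-object-plane distance in mm.
#' @return Object size in mm.
#' @export
object_size <- function(image_size_px, geometry, distance_mm) {
  if (any(image_size_px < 0)) stop("image_size_px must be >= 0", call. = FALSE)
  if (any(distance_mm <= 0)) stop("distance must be positive", call. = FALSE)
  image_size_px * geometry$pixel_size_mm * distance_mm / geometry$focal_length_mm
}

#' Millimetre-to-pixel inverse of [object_size()]
#'
#' @inheritParams object_size
#' @param size_mm Object size in mm.
#' @return Extent in pixels.
#' @export
pixels_from_size <- function(size_mm, geometry, distance_mm) {
  if (any(distance_mm <= 0)) stop("distance must be positive", call. = FALSE)
  size_mm * geometry$focal_length_mm / (geometry$pixel_size_mm * distance_mm)
}

#' Side-view pixel extent to mm
#'
#' The plane mirror places the side-view object plane at the fixed distance
#' `h3 + h4`, so this calibration never changes between images.
#'
#' @inheritParams object_size
#' @return Object size in mm.
#' @export
side_view_size <- function(image_size_px, geometry) {
  object_size(image_size_px, geometry, geometry$h3_mm + geometry$h4_mm)
}

#' Derive the top-view object-plane distance h1 from the fruit height
#'
#' The fruit's height (measured in the side view) lifts the widest section
#' of the fruit above the platform; h1 is the camera-to-platform distance h2
#' minus `plane_fraction` of that height.
#'
#' @param side_height_mm Fruit height in mm from the side view.
#' @param geometry A [camera_geometry()].
#' @param plane_fraction Fraction of the height at which the object plane
#'   sits; defaults to the geometry's setting.
#' @return h1 in mm.
#' @export
derive_h1 <- function(side_height_mm, geometry,
                      plane_fraction = geometry$plane_fraction) {
  if (side_height_mm < 0 || side_height_mm >= geometry$h2_mm)
    stop("side_height_mm must be in [0, h2)", call. = FALSE)
  if (plane_fraction < 0 || plane_fraction > 1)
    stop("plane_fraction must be in [0, 1]", call. = FALSE)
  geometry$h2_mm - plane_fraction * side_height_mm
}

#' Top-view pixel extent to mm using the derived h1
#'
#' @inheritParams object_size
#' @return Object size in mm.
#' @export
top_view_size <- function(image_size_px, geometry) {
  if (is.null(geometry$h1_mm))
    stop("h1 has not been derived; call derive_h1() first", call. = FALSE)
  object_size(image_size_px, geometry, geometry$h1_mm)
}

#' Millimetres per pixel for each view
#'
#' @param geometry A [camera_geometry()] (with `h1_mm` set for the top view).
#' @return Named numeric `c(top = ..., side = ...)`; `top` is `NA` until h1
#'   is derived.
#' @export
mm_per_px <- function(geometry) {
  s <- geometry$pixel_size_mm / geometry$focal_length_mm
  c(top = if (is.null(geometry$h1_mm)) NA_real_ else s * geometry$h1_mm,
    side = s * (geometry$h3_mm + geometry$h4_mm))
}
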