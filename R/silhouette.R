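#' @importFrom stats approx cor fft lm median qt sd t.test var coef
#' @importFrom utils read.csv write.csv
NULL

# ---- raster containers ------------------------------------------------------
#
# A raster image is a numeric H x W x 3 array with 8-bit intensities in
# [0, 255], channels ordered R, G, B; origin top-left, row = y, col = x.
# A binary mask is a logical H x W matrix, TRUE = fruit.
# Pixel coordinates are 0-based with pixel centers at integer (x, y),
# x rightwards (columns), y downwards (rows).

#' Read an 8-bit RGB image
#'
#' Reads a PNG file into the package's raster representation: an
#' `H x W x 3` numeric array of intensities in `[0, 255]`.
#'
#' @param path Path to a PNG file.
#' @return Numeric `H x W x 3` array.
#' @export
read_raster <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px * 255
}

#' Write a raster image or mask as PNG
#'
#' Masks are written as 8-bit grayscale with fruit = 255.
#'
#' @param x Raster array (`H x W x 3`, values 0-255) or logical mask matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.numeric(x), nrow(x), ncol(x))
  png::writePNG(x / 255, path)
  invisible(path)
}

.assert_raster <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an H x W x 3 RGB raster array", call. = FALSE)
}

.assert_mask <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("expected a logical H x W mask matrix", call. = FALSE)
}

# ---- view layout ------------------------------------------------------------

#' Two-view frame layout
#'
#' The camera captures the top view and the mirror-reflected side view of the
#' fruit in one frame; this object records the rectangle occupied by each
#' view. Rectangles are 0-based `c(x, y, width, height)`.
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param top,side Rectangles `c(x, y, w, h)`; defaults split the frame into
#'   left (top view) and right (side view) halves.
#' @return A `view_layout` object.
#' @export
view_layout <- function(frame_width = 1600, frame_height = 850,
                        top = c(0, 0, frame_width %/% 2, frame_height),
                        side = c(frame_width %/% 2, 0,
                                 frame_width - frame_width %/% 2, frame_height)) {
  for (r in list(top, side)) {
    if (length(r) != 4L || any(r[3:4] < 1))
      stop("layout rectangles must be c(x, y, w, h) with w, h >= 1", call. = FALSE)
  }
  structure(list(frame_width = frame_width, frame_height = frame_height,
                 top = top, side = side), class = "view_layout")
}

.crop <- function(image, rect) {
  H <- dim(image)[1]; W <- dim(image)[2]
  x0 <- rect[1]; y0 <- rect[2]; w <- rect[3]; h <- rect[4]
  if (x0 < 0 || y0 < 0 || x0 + w > W || y0 + h > H)
    stop("layout rectangle out of image bounds", call. = FALSE)
  image[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), , drop = FALSE]
}

#' Split a two-view frame into top and side sub-images
#'
#' @param image Raster array holding both views.
#' @param layout A [view_layout()].
#' @return List with elements `top` and `side`, each a raster array.
#' @export
split_views <- function(image, layout = view_layout(dim(image)[2], dim(image)[1])) {
  .assert_raster(image)
  rt <- layout$top; rs <- layout$side
  if (rt[1] < rs[1] + rs[3] && rs[1] < rt[1] + rt[3] &&
      rt[2] < rs[2] + rs[4] && rs[2] < rt[2] + rt[4])
    stop("view rectangles overlap", call. = FALSE)
  list(top = .crop(image, rt), side = .crop(image, rs))
}

# ---- thresholding -----------------------------------------------------------

#' Extract the blue channel as a grayscale image
#'
#' The fruit is segmented on the B band: the white tray has high R, G and B
#' while the fruit has a distinctly low B value.
#'
#' @param image `H x W x 3` raster array.
#' @return `H x W` numeric matrix of B intensities (0-255).
#' @export
to_gray_b <- function(image) {
  .assert_raster(image)
  image[, , 3]
}

#' Segment the top view by double global threshold
#'
#' Fruit pixels are those with B value strictly between the stem range and
#' the background threshold: intensities at or below `stem_range[2]` belong
#' to the (very dark) stem, intensities at or above `bg_thresh` to the white
#' tray.
#'
#' @param gray `H x W` matrix of intensities in `[0, 255]`.
#' @param bg_thresh Background threshold; pixels `>= bg_thresh` are excluded
#'   (default 90).
#' @param stem_range Inclusive intensity interval treated as stem and
#'   excluded (default `c(0, 20)`).
#' @return Logical mask, TRUE = fruit.
#' @export
threshold_top <- function(gray, bg_thresh = 90, stem_range = c(0, 20)) {
  if (!is.matrix(gray)) stop("gray must be a matrix", call. = FALSE)
  if (stem_range[1] > stem_range[2] || stem_range[2] >= bg_thresh)
    stop("stem_range must be an interval below bg_thresh", call. = FALSE)
  gray > stem_range[2] & gray < bg_thresh
}

#' Remove small connected components
#'
#' Deletes foreground components smaller than `min_area`, but always retains
#' the largest component so a valid fruit is never removed outright. The
#' default `min_area` is 500 px for a 1600 x 850 frame, scaled by image area
#' otherwise.
#'
#' @param mask Logical mask.
#' @param min_area Minimum component area in pixels.
#' @return Cleaned logical mask.
#' @export
remove_small_particles <- function(mask, min_area = NULL) {
  .assert_mask(mask)
  if (is.null(min_area)) min_area <- default_min_area(dim(mask))
  if (min_area < 1) stop("min_area must be >= 1", call. = FALSE)
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  keep <- union(keep, which.max(sizes))
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Default small-particle area threshold for a given mask size
#'
#' @param dim_mask `c(H, W)` of the mask.
#' @return Area threshold in pixels (>= 1).
#' @export
default_min_area <- function(dim_mask) {
  max(1, round(500 * prod(dim_mask[1:2]) / (1600 * 850)))
}

#' Fill enclosed holes in a mask
#'
#' Background regions completely enclosed by fruit (e.g. produced when dark
#' spots on the skin fall into the stem intensity range) are converted to
#' foreground.
#'
#' @param mask Logical mask.
#' @return Hole-free logical mask.
#' @export
fill_holes <- function(mask) {
  .assert_mask(mask)
  matrix(EBImage::fillHull(mask) > 0, nrow(mask), ncol(mask))
}

.channel_index <- function(ch) {
  i <- match(toupper(ch), c("R", "G", "B"))
  if (is.na(i)) stop("channel must be one of R, G, B", call. = FALSE)
  i
}

.median_mask <- function(mask, size) {
  if (!any(mask) || all(mask)) return(mask)
  r <- (size - 1L) %/% 2L
  matrix(EBImage::medianFilter(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                               r) > 0.5,
         nrow(mask), ncol(mask))
}

#' Segment the side view by three repeated global thresholds
#'
#' The mirror-reflected side view is low-contrast and carries a shadow band
#' cast by the fruit. Each pass keeps pixels of the stated channel below the
#' stated intensity *within the region surviving the previous pass*; a median
#' filter between passes erases the shadow boundary. The default B-G-B pass
#' values (120, 110, 100) remove a grey shadow that is darker than the tray
#' in B but brighter than the fruit in G.
#'
#' @param image `H x W x 3` raster array (side view).
#' @param params List of three `(channel, intensity)` pairs, e.g.
#'   `list(c("B", 120), c("G", 110), c("B", 100))`.
#' @param median_size Odd median filter window size in pixels (default 7).
#' @return Logical mask, TRUE = fruit.
#' @export
threshold_side <- function(image,
                           params = list(c("B", 120), c("G", 110), c("B", 100)),
                           median_size = 7) {
  .assert_raster(image)
  if (median_size %% 2 != 1 || median_size < 3)
    stop("median_size must be odd and >= 3", call. = FALSE)
  region <- matrix(TRUE, dim(image)[1], dim(image)[2])
  for (k in seq_along(params)) {
    p <- params[[k]]
    ch <- .channel_index(p[[1]])
    thr <- as.numeric(p[[2]])
    region <- region & (image[, , ch] < thr)
    # the median filter runs between passes (it erases the shadow boundary
    # before the next threshold), not after the last one
    if (k < length(params)) region <- .median_mask(region, median_size)
  }
  region
}

# ---- boundary tracing -------------------------------------------------------

#' Trace the outer boundary of a single-component mask
#'
#' Moore-neighbour tracing of the 8-connected outer border, started at the
#' topmost-then-leftmost boundary pixel and oriented so the shoelace signed
#' area is negative in image coordinates (the package's "clockwise"
#' convention). Coordinates are 0-based `(x, y)` pixel centers.
#'
#' @param mask Logical mask with exactly one foreground component of area
#'   >= 4.
#' @return A `boundary_trace`: integer matrix with columns `x`, `y`, one row
#'   per boundary pixel, closed implicitly (last row 8-adjacent to first).
#' @export
extract_boundary <- function(mask) {
  .assert_mask(mask)
  n_fg <- sum(mask)
  if (n_fg < 4) stop("mask must contain a component of area >= 4", call. = FALSE)
  if (max(EBImage::bwlabel(mask)) != 1)
    stop("mask must contain exactly one connected component", call. = FALSE)

  H <- nrow(mask); W <- ncol(mask)
  pm <- matrix(FALSE, H + 2L, W + 2L)
  pm[2:(H + 1L), 2:(W + 1L)] <- mask

  # 8 neighbours in clockwise scan order (row down = y down): N, NE, E, SE,
  # S, SW, W, NW as (drow, dcol)
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

  idx <- which(pm, arr.ind = TRUE)
  r0 <- min(idx[, 1])
  c0 <- min(idx[idx[, 1] == r0, 2])

  # entered the start pixel "moving east": backtrack points west (dir 7).
  # stop when the walk is about to repeat its very first move (start ->
  # second pixel), so each boundary pixel is emitted once per pass.
  cr <- r0; cc <- c0; back <- 7L
  pts <- matrix(0L, 4L * n_fg + 8L, 2L)
  np <- 0L
  r2 <- NA_integer_; c2 <- NA_integer_
  repeat {
    found <- FALSE
    d <- back
    for (s in 1:8) {
      d <- d %% 8L + 1L  # next clockwise
      nr <- cr + dr[d]; nc <- cc + dc[d]
      if (pm[nr, nc]) { found <- TRUE; break }
    }
    if (!found) { np <- np + 1L; pts[np, ] <- c(cr, cc); break }
    if (np >= 1L && cr == r0 && cc == c0 && nr == r2 && nc == c2) break
    np <- np + 1L
    pts[np, ] <- c(cr, cc)
    if (np == 1L) { r2 <- nr; c2 <- nc }
    back <- (d + 4L - 1L) %% 8L + 1L  # direction pointing back at current
    cr <- nr; cc <- nc
    if (np >= nrow(pts)) break  # safety
  }
  pts <- pts[1:np, , drop = FALSE]
  xy <- cbind(x = pts[, 2] - 2L, y = pts[, 1] - 2L)  # un-pad, 0-based
  # drop an immediate duplicate closure point if present
  if (np > 1 && all(xy[np, ] == xy[1, ])) xy <- xy[-np, , drop = FALSE]
  if (.shoelace_area(xy) > 0) {
    n <- nrow(xy)
    xy <- xy[c(1L, n:2L), , drop = FALSE]
  }
  structure(xy, class = c("boundary_trace", class(xy)))
}

# signed polygon area; negative = the package's clockwise convention
.shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Rasterize a closed boundary back into a filled mask
#'
#' Inverse of [extract_boundary()] for hole-free masks: draws the boundary
#' pixels and fills the enclosed region.
#'
#' @param boundary A `boundary_trace` (matrix of x, y).
#' @param dim_mask `c(H, W)` of the output mask.
#' @return Logical mask.
#' @export
boundary_to_mask <- function(boundary, dim_mask) {
  m <- matrix(FALSE, dim_mask[1], dim_mask[2])
  m[cbind(boundary[, 2] + 1L, boundary[, 1] + 1L)] <- TRUE
  fill_holes(m)
}

# ---- mask measurements ------------------------------------------------------

#' Measure a single-component mask
#'
#' Area, boundary perimeter, Feret-style maximum diameter (largest
#' center-to-center distance between boundary pixels) with its perpendicular
#' extent as the minimum diameter, and the bounding box.
#'
#' @param mask Logical mask with one foreground component.
#' @return List with `area_px`, `perimeter_px`, `max_diameter_px`,
#'   `min_diameter_px`, `bbox` (`c(x, y, w, h)`, 0-based), `centroid_px`.
#' @export
measure_mask <- function(mask) {
  .assert_mask(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  bnd <- extract_boundary(mask)
  x <- bnd[, 1]; y <- bnd[, 2]
  # perimeter: length of the closed 8-connected contour
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  perim <- sum(sqrt(dx^2 + dy^2))
  # Feret diameters on the convex hull of the boundary
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  dmat <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  maxd <- sqrt(dmat[ij[1], ij[2]])
  ux <- (hx[ij[2]] - hx[ij[1]]) / maxd
  uy <- (hy[ij[2]] - hy[ij[1]]) / maxd
  proj <- -uy * hx + ux * hy  # perpendicular direction
  mind <- max(proj) - min(proj)
  idx <- which(mask, arr.ind = TRUE)
  bx <- range(idx[, 2] - 1L); by <- range(idx[, 1] - 1L)
  list(area_px = sum(mask),
       perimeter_px = perim,
       max_diameter_px = maxd,
       min_diameter_px = mind,
       bbox = c(x = bx[1], y = by[1], w = diff(bx) + 1L, h = diff(by) + 1L),
       centroid_px = c(x = mean(idx[, 2] - 1), y = mean(idx[, 1] - 1)))
}
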