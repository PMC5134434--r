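# Volume by the disk method, mass from volume, commercial grade from mass.
#
# The two orthogonal silhouettes are cut into slices perpendicular to the
# fruit's major axis; each slice is revolved into an elliptic cylindrical
# disk whose two diameters are the top-view width and side-view height of
# that slice. Total volume is the sum of the disks. Mass follows from a
# linear density model, and the grade from the mass thresholds used for
# Harumanis mango.

#' Per-slice width/height profiles from the two views
#'
#' Each mask is measured along its own major axis (principal axis of the
#' pixel distribution; skipped when the mask is already axis-aligned): the
#' foreground extent perpendicular to the axis is recorded for every
#' one-pixel slice along it. The two views are registered by physical
#' position along the shared length axis (mm relative to each silhouette's
#' centroid), and the side-view height profile is linearly interpolated at
#' the top view's slice positions, so each slice pairs the width and height
#' of the same section of fruit.
#'
#' @param top_mask,side_mask Single-component logical masks.
#' @param mm_per_px_top,mm_per_px_side Scales from [mm_per_px()].
#' @return A `slice_profile_pair`: list with `n_slices`, `dx_mm` (slice
#'   thickness: one top-view pixel), `dy_mm` (top widths), `dz_mm` (side
#'   heights).
#' @export
slice_profiles <- function(top_mask, side_mask, mm_per_px_top, mm_per_px_side) {
  pt <- .axis_profile(top_mask)
  ps <- .axis_profile(side_mask)
  dy <- pt$w * mm_per_px_top
  dz_at <- approx(ps$u * mm_per_px_side, ps$w * mm_per_px_side,
                  xout = pt$u * mm_per_px_top, rule = 2)$y
  structure(list(n_slices = length(dy), dx_mm = mm_per_px_top,
                 dy_mm = dy, dz_mm = dz_at),
            class = "slice_profile_pair")
}

# extent (px) of the mask perpendicular to its major axis, one value per
# 1-px bin along the axis; u = bin center relative to the pixel centroid
.axis_profile <- function(mask) {
  .assert_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  cxx <- mean((x - cx)^2); cyy <- mean((y - cy)^2); cxy <- mean((x - cx) * (y - cy))
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  if (abs(theta) > pi / 360) {  # rotate only if off-axis by > 0.5 degrees
    u <- (x - cx) * cos(theta) + (y - cy) * sin(theta)
    v <- -(x - cx) * sin(theta) + (y - cy) * cos(theta)
  } else {
    u <- x - cx; v <- y - cy
  }
  bin <- round(u - min(u))
  w <- tapply(v, bin, function(z) max(z) - min(z) + 1)
  ord <- order(as.integer(names(w)))
  list(u = as.integer(names(w))[ord] + min(u), w = as.numeric(w[ord]))
}

#' Sub-pixel maximum extent of a silhouette perpendicular to its axis
#'
#' The integer column extents of a binary mask quantize the fruit height to
#' a whole pixel; because the top-view scale is recalibrated from this
#' height, that quantization would dominate the volume error budget. This
#' estimator fits a quadratic to the extent profile over its plateau
#' (within 6 px of the maximum) and returns the vertex value, which is
#' accurate to a fraction of a pixel for smooth convex silhouettes. Falls
#' back to the integer maximum when the fit is degenerate.
#'
#' @param mask Single-component logical mask.
#' @return Maximum perpendicular extent in pixels (sub-pixel).
#' @export
mask_extent_px <- function(mask) {
  p <- .axis_profile(mask)
  e_max <- max(p$w)
  sel <- p$w >= e_max - 6
  if (sum(sel) >= 5) {
    u <- p$u[sel]; e <- p$w[sel]
    fit <- stats::lm(e ~ u + I(u^2))
    cf <- coef(fit)
    if (is.finite(cf[3]) && cf[3] < 0) {
      u0 <- -cf[2] / (2 * cf[3])
      if (u0 >= min(u) && u0 <= max(u)) {
        e0 <- cf[1] + cf[2] * u0 + cf[3] * u0^2
        if (is.finite(e0) && abs(e0 - e_max) <= 2) return(unname(e0))
      }
    }
  }
  e_max
}

#' Disk-method volume
#'
#' `V = sum_i pi * (dy_i / 2) * (dz_i / 2) * dx`, in mm^3, reported in mL.
#'
#' @param profiles A `slice_profile_pair`.
#' @return Volume in mL.
#' @export
disk_volume <- function(profiles) {
  sum(pi * (profiles$dy_mm / 2) * (profiles$dz_mm / 2) * profiles$dx_mm) / 1000
}

#' Mass from volume by the linear density model
#'
#' Default coefficients: `mass = 0.9973 * volume + 6.778` (g, mL).
#'
#' @param volume_ml Volume in mL (>= 0).
#' @param slope,intercept Model coefficients (g/mL, g).
#' @return Mass in g.
#' @export
estimate_mass <- function(volume_ml, slope = 0.9973, intercept = 6.778) {
  if (any(volume_ml < 0)) stop("volume must be >= 0", call. = FALSE)
  slope * volume_ml + intercept
}

#' Fit the mass-volume regression
#'
#' Ordinary least squares of mass on volume.
#'
#' @param volumes Volumes in mL (>= 3 values, non-constant).
#' @param masses Masses in g.
#' @return A `mass_model`: list with `slope`, `intercept`, `r_squared`.
#' @export
fit_mass_model <- function(volumes, masses) {
  if (length(volumes) < 3 || length(volumes) != length(masses))
    stop("need >= 3 volume/mass pairs of equal length", call. = FALSE)
  if (sd(volumes) == 0) stop("volumes are constant", call. = FALSE)
  fit <- lm(masses ~ volumes)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((masses - mean(masses))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot),
            class = "mass_model")
}

#' @export
print.mass_model <- function(x, ...) {
  cat(sprintf("mass = %.4f * volume + %.3f  (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Assign a commercial grade
#'
#' Misshapen fruit are rejected regardless of mass; regular fruit are graded
#' A (>= 400 g), B (350-400 g) or C (< 350 g). The half-open intervals close
#' the gaps the market standard leaves at 350 and 400 g.
#'
#' @param mass_g Mass in g (>= 0); may be `NA` for misshapen fruit.
#' @param shape_class `"regular"` or `"misshapen"` (recycled).
#' @return Character vector of grades in `A`, `B`, `C`, `Rejected`.
#' @export
assign_grade <- function(mass_g, shape_class = "regular") {
  n <- max(length(mass_g), length(shape_class))
  mass_g <- rep_len(mass_g, n)
  shape_class <- rep_len(as.character(shape_class), n)
  if (any(!is.na(mass_g) & mass_g < 0)) stop("mass must be >= 0", call. = FALSE)
  out <- character(n)
  mis <- shape_class == "misshapen"
  out[mis] <- "Rejected"
  m <- mass_g[!mis]
  out[!mis] <- ifelse(m >= 400, "A", ifelse(m >= 350, "B", "C"))
  out
}
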