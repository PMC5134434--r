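# Synthetic two-view fruit scenes with known ground truth.
#
# A fruit is modelled as a solid with elliptical cross-sections along its
# length axis. The axial radius profile is a tapered ovoid,
# p(t) = sqrt(1 - t^2) * (1 + taper * t) on t in [-1, 1] (normalised to a
# maximum of 1), and misshapen fruit add angular surface lobes to the
# cross-section. Silhouettes are projected through the same pinhole scale
# model the calibration inverts, so pixel measurements can be validated
# against millimetre ground truth; the true volume comes from fine slice
# integration of the generative solid.

#' Specify a synthetic fruit
#'
#' @param length_mm Fruit length along the major axis.
#' @param max_width_mm,max_height_mm Width (top view) and height (side view)
#'   of the base ovoid at its widest section.
#' @param taper Asymmetry exponent of the axial profile (default 0.12; 0 =
#'   symmetric ovoid).
#' @param lobes List of surface deformations, each
#'   `c(angle = <rad>, amplitude = <mm>, width = <rad>, center = <t>,
#'   extent = <t>)`: a Gaussian bump (amplitude > 0) or dent (amplitude < 0)
#'   at angular position `angle` (measured from the top-view width axis),
#'   angular sd `width`, centred axially at `center` in `[-1, 1]` with axial
#'   sd `extent` (defaults 0 and 0.15). Deformations are damped by the axial
#'   profile so the solid stays closed at the tips.
#' @param density `c(slope, intercept)` of the linear mass-volume model used
#'   for the true mass (defaults to the package's mass model coefficients).
#' @param id Optional fruit identifier.
#' @param misshapen_threshold_mm Lobe amplitude above which the fruit is
#'   labelled misshapen (default 2 mm).
#' @return A `fruit_spec`; field `is_misshapen` is derived from the lobes.
#' @export
fruit_spec <- function(length_mm, max_width_mm, max_height_mm,
                       taper = 0.12, lobes = list(),
                       density = c(slope = 0.9973, intercept = 6.778),
                       id = NULL, misshapen_threshold_mm = 2) {
  if (length_mm <= 0 || max_width_mm <= 0 || max_height_mm <= 0)
    stop("fruit dimensions must be positive", call. = FALSE)
  if (abs(taper) >= 1) stop("taper must be in (-1, 1)", call. = FALSE)
  lobes <- lapply(lobes, function(l) {
    l <- unlist(l)
    if (!all(c("angle", "amplitude", "width") %in% names(l)))
      stop("each lobe needs angle, amplitude, width", call. = FALSE)
    if (!"center" %in% names(l)) l[["center"]] <- 0
    if (!"extent" %in% names(l)) l[["extent"]] <- 0.15
    l
  })
  amp <- if (length(lobes)) max(abs(vapply(lobes, `[[`, 0, "amplitude"))) else 0
  structure(list(length_mm = length_mm, max_width_mm = max_width_mm,
                 max_height_mm = max_height_mm, taper = taper, lobes = lobes,
                 density = density, id = id,
                 is_misshapen = amp > misshapen_threshold_mm),
            class = "fruit_spec")
}

# normalised axial profile pn(t) in [0, 1]
.axial_profile <- function(spec, t) {
  p <- sqrt(pmax(0, 1 - t^2)) * (1 + spec$taper * t)
  pmax_val <- stats::optimize(function(u) sqrt(1 - u^2) * (1 + spec$taper * u),
                              c(-1, 1), maximum = TRUE)$objective
  p / pmax_val
}

# polar radius of the solid's surface, r(t, theta) in mm, as a
# length(t) x length(theta) matrix; theta measured from the +y (top-view
# width) axis, so y = r cos(theta), z = r sin(theta)
.solid_radius <- function(spec, t, theta) {
  b <- spec$max_width_mm / 2; c_ <- spec$max_height_mm / 2
  ell <- 1 / sqrt((cos(theta) / b)^2 + (sin(theta) / c_)^2)
  pn <- .axial_profile(spec, t)
  R <- pn %o% ell
  for (l in spec$lobes) {
    dth <- abs(((theta - l[["angle"]] + pi) %% (2 * pi)) - pi)
    gth <- exp(-dth^2 / (2 * l[["width"]]^2))
    gt <- pn * exp(-(t - l[["center"]])^2 / (2 * l[["extent"]]^2))
    R <- R + l[["amplitude"]] * (gt %o% gth)
  }
  if (min(R[t > -1 & t < 1, ]) <= 0)
    stop("lobe amplitude makes the surface radius negative", call. = FALSE)
  R
}

# axial summary of the solid: per-slice silhouette extents (mm, relative to
# the axis) and cross-sectional area, plus total volume by slice integration
.solid_summary <- function(spec, n_t = 10001, n_theta = 720) {
  t <- seq(-1, 1, length.out = n_t)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  R <- .solid_radius(spec, t, theta)
  ct <- cos(theta); st <- sin(theta)
  Y <- R * rep(ct, each = n_t)
  Z <- R * rep(st, each = n_t)
  area <- rowSums(R^2) * (2 * pi / n_theta) / 2
  dt <- t[2] - t[1]
  vol_mm3 <- (spec$length_mm / 2) *
    sum((area[-1] + area[-n_t]) / 2) * dt
  list(t = t,
       y_lo = .row_min(Y), y_hi = .row_max(Y),
       z_lo = .row_min(Z), z_hi = .row_max(Z),
       area = area, volume_ml = vol_mm3 / 1000)
}

.row_min <- function(M) do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))
.row_max <- function(M) do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))

#' Generate a fruit's ground-truth scene
#'
#' Builds the solid, integrates its true volume over 10,000 axial slices,
#' and projects the two silhouettes into frame-sized masks through the
#' camera geometry (top view at the object plane h1 implied by the fruit's
#' own height, side view at h3 + h4), each view centred in its layout
#' rectangle.
#'
#' @param spec A [fruit_spec()].
#' @param geometry A [camera_geometry()].
#' @param layout A [view_layout()].
#' @param n_slices Axial integration grid for the true volume (default
#'   10001 points, i.e. 10,000 slices).
#' @param n_theta Angular grid for the cross-section (default 720).
#' @return A `scene_truth`: list with `top_mask`, `side_mask` (frame-sized
#'   logical), `true_volume_ml`, `true_mass_g`, `true_height_mm`,
#'   `true_length_mm`, `true_width_mm`, `spec`, `geometry`, `layout`,
#'   `centers` (px).
#' @export
generate_fruit <- function(spec, geometry = camera_geometry(),
                           layout = view_layout(),
                           n_slices = 10001, n_theta = 720) {
  ss <- .solid_summary(spec, n_t = n_slices, n_theta = n_theta)
  L <- spec$length_mm
  true_volume_ml <- ss$volume_ml
  true_mass_g <- spec$density[["slope"]] * true_volume_ml +
    spec$density[["intercept"]]
  true_height_mm <- max(ss$z_hi) - min(ss$z_lo)
  true_width_mm <- max(ss$y_hi) - min(ss$y_lo)
  geometry$h1_mm <- derive_h1(true_height_mm, geometry)
  sc <- mm_per_px(geometry)

  H <- layout$frame_height; W <- layout$frame_width
  centers <- list(
    top = c(x = layout$top[1] + (layout$top[3] - 1) / 2,
            y = layout$top[2] + (layout$top[4] - 1) / 2),
    side = c(x = layout$side[1] + (layout$side[3] - 1) / 2,
             y = layout$side[2] + (layout$side[4] - 1) / 2))

  top_mask <- .render_view(matrix(FALSE, H, W), centers$top, L, sc[["top"]],
                           ss$t, ss$y_lo, ss$y_hi)
  side_mask <- .render_view(matrix(FALSE, H, W), centers$side, L, sc[["side"]],
                            ss$t, ss$z_lo, ss$z_hi)

  structure(list(top_mask = top_mask, side_mask = side_mask,
                 true_volume_ml = true_volume_ml, true_mass_g = true_mass_g,
                 true_height_mm = true_height_mm,
                 true_width_mm = true_width_mm, true_length_mm = L,
                 spec = spec, geometry = geometry, layout = layout,
                 centers = centers),
            class = "scene_truth")
}

# mark pixels whose center falls inside the silhouette; lo/hi give the
# perpendicular extents (mm) of the silhouette per axial grid point
.render_view <- function(mask, center, L, mmpp, t_grid, lo, hi) {
  W <- ncol(mask); H <- nrow(mask)
  x_mm <- ((0:(W - 1)) - center[["x"]]) * mmpp
  t <- x_mm / (L / 2)
  inside <- which(abs(t) <= 1)
  if (!length(inside)) return(mask)
  lo_j <- approx(t_grid, lo, xout = t[inside])$y
  hi_j <- approx(t_grid, hi, xout = t[inside])$y
  y_mm <- ((0:(H - 1)) - center[["y"]]) * mmpp
  for (k in seq_along(inside)) {
    if (hi_j[k] > lo_j[k])
      mask[y_mm >= lo_j[k] & y_mm <= hi_j[k], inside[k]] <- TRUE
  }
  mask
}

#' Render a two-view scene image
#'
#' Paints the fruit (dark green, B channel inside the top-view fruit
#' threshold band) on a white tray, with optional acquisition artefacts: a
#' very dark stem at the fruit tip (B below the stem threshold), small dark
#' specks (dirt on the tray, dark spots punching holes in the fruit), and a
#' grey shadow band adjoining the side-view fruit (survives the B threshold
#' but is removed by the G pass).
#'
#' @param truth A `scene_truth` from [generate_fruit()].
#' @param noise List with `stem` (logical), `specks` (count), `shadow`
#'   (logical), `rgb_sd` (per-channel Gaussian intensity noise, default 2).
#' @param seed Integer seed for the speck placement and pixel noise.
#' @return List with `image` (raster array) and `labels` (logical masks
#'   `stem`, `speck`, `shadow`).
#' @export
render_scene <- function(truth,
                         noise = list(stem = TRUE, specks = 0, shadow = TRUE),
                         seed = 1) {
  withr::with_seed(seed, .render_scene_impl(truth, noise))
}

.render_scene_impl <- function(truth, noise) {
  H <- truth$layout$frame_height; W <- truth$layout$frame_width
  col_tray <- c(242, 241, 236)
  col_fruit <- c(70, 100, 55)
  col_stem <- c(25, 22, 15)
  col_shadow <- c(112, 118, 105)
  col_dirt <- c(75, 92, 60)
  col_spot <- c(14, 13, 10)
  rgb_sd <- noise$rgb_sd %||% 2

  ch <- lapply(col_tray, function(v) matrix(v, H, W))
  paint <- function(idx, colr) {
    for (k in 1:3) ch[[k]][idx] <<- colr[k]
  }
  fruit <- truth$top_mask | truth$side_mask
  paint(which(fruit), col_fruit)

  labels <- list(stem = matrix(FALSE, H, W),
                 speck = matrix(FALSE, H, W),
                 shadow = matrix(FALSE, H, W))

  # shadow band adjoining the bottom edge of the side-view fruit
  if (isTRUE(noise$shadow) && any(truth$side_mask)) {
    idx <- which(truth$side_mask, arr.ind = TRUE)
    r_bot <- max(idx[, 1])
    cols <- range(idx[, 2])
    rows <- r_bot + seq_len(min(40, H - r_bot))
    if (length(rows)) {
      sh <- matrix(FALSE, H, W)
      sh[rows, max(1, cols[1] - 10):min(W, cols[2] + 10)] <- TRUE
      sh <- sh & !fruit
      paint(which(sh), col_shadow)
      labels$shadow <- sh
    }
  }

  # stem at the +x tip of the top-view fruit
  if (isTRUE(noise$stem) && any(truth$top_mask)) {
    idx <- which(truth$top_mask, arr.ind = TRUE)
    c_tip <- max(idx[, 2])
    r_tip <- round(mean(idx[idx[, 2] == c_tip, 1]))
    st <- matrix(FALSE, H, W)
    st[max(1, r_tip - 2):min(H, r_tip + 2),
       max(1, c_tip - 4):min(W, c_tip + 22)] <- TRUE
    paint(which(st), col_stem)
    labels$stem <- st
  }

  # specks: half dirt on the tray (top view), half dark spots on the fruit
  n_sp <- noise$specks %||% 0
  if (n_sp > 0) {
    interior <- truth$top_mask &
      matrix(EBImage::erode(truth$top_mask,
                            EBImage::makeBrush(9, "box")) > 0, H, W)
    tray_top <- !fruit
    tray_top[, (truth$layout$top[1] + truth$layout$top[3] + 1):W] <- FALSE
    pool_in <- which(interior); pool_out <- which(tray_top)
    for (i in seq_len(n_sp)) {
      on_fruit <- i %% 2 == 0
      pool <- if (on_fruit) pool_in else pool_out
      if (!length(pool)) next
      p <- sample(pool, 1)
      r0 <- (p - 1) %% H + 1; c0 <- (p - 1) %/% H + 1
      rows <- max(1, r0 - 2):min(H, r0 + 2)
      cols <- max(1, c0 - 2):min(W, c0 + 2)
      hit <- outer(rows - r0, cols - c0, function(a, b) a^2 + b^2 <= 4)
      idx <- as.vector(outer(rows, (cols - 1) * H, "+"))[hit]
      paint(idx, if (on_fruit) col_spot else col_dirt)
      labels$speck[idx] <- TRUE
    }
  }

  img <- array(c(ch[[1]], ch[[2]], ch[[3]]), c(H, W, 3))
  if (rgb_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, rgb_sd)
    img[img > 255] <- 255
    img[img < 0] <- 0
    dim(img) <- c(H, W, 3)
  }
  list(image = img, labels = labels)
}

#' Generate a labelled synthetic dataset
#'
#' Draws fruit specifications from the default population (lengths around
#' 111 mm so true masses span the three commercial grades; misshapen fruit
#' carry 1-3 surface lobes of 3-8 mm amplitude, which raises S1-S3 and
#' lowers roundness relative to regular fruit) and computes each fruit's
#' ground truth.
#'
#' @param n_regular,n_misshapen Cohort sizes (the reference training design
#'   is 159 regular / 21 misshapen).
#' @param effect_profile Optional list overriding population parameters:
#'   `length_mean`, `length_sd`, `width_ratio`, `height_ratio`, `taper_range`,
#'   `mis_amp_range`, `mis_lobes`, `mis_width_range`.
#' @param seed Integer seed.
#' @param geometry,layout Scene geometry.
#' @return List with `specs` (list of `fruit_spec`) and `truth` (data frame:
#'   id, class, length_mm, width_mm, height_mm, true_volume_ml, true_mass_g,
#'   grade).
#' @export
generate_dataset <- function(n_regular = 159, n_misshapen = 21,
                             effect_profile = list(), seed = 1,
                             geometry = camera_geometry(),
                             layout = view_layout()) {
  ep <- utils::modifyList(list(length_mean = 130, length_sd = 9,
                               length_range = c(108, 150),
                               width_ratio = c(0.60, 0.03),
                               height_ratio = c(0.88, 0.03),
                               taper_range = c(0.05, 0.2),
                               mis_amp_range = c(6, 12),
                               mis_lobes = 1:3,
                               mis_width_range = c(0.4, 0.9),
                               mis_center_range = c(-0.6, 0.6),
                               mis_extent_range = c(0.12, 0.25)),
                          effect_profile)
  specs <- withr::with_seed(seed, {
    n <- n_regular + n_misshapen
    cls <- rep(c("regular", "misshapen"), c(n_regular, n_misshapen))
    lapply(seq_len(n), function(i) {
      L <- min(max(stats::rnorm(1, ep$length_mean, ep$length_sd),
                   ep$length_range[1]), ep$length_range[2])
      Wd <- L * stats::rnorm(1, ep$width_ratio[1], ep$width_ratio[2])
      Ht <- Wd * stats::rnorm(1, ep$height_ratio[1], ep$height_ratio[2])
      lobes <- list()
      if (cls[i] == "misshapen") {
        k <- sample(ep$mis_lobes, 1)
        # concavities (dents); the first is angled near the top-view
        # silhouette plane and kept away from the tips, emulating an
        # expert-labelled cohort whose deformation is clearly visible in the
        # view the classifier sees; further dents fall anywhere
        lobes <- lapply(seq_len(k), function(j) {
          first <- j == 1
          c(angle = if (first)
              (sample(c(0, pi), 1) + stats::rnorm(1, 0, 0.25)) %% (2 * pi)
            else stats::runif(1, 0, 2 * pi),
            amplitude = -stats::runif(1, ep$mis_amp_range[1], ep$mis_amp_range[2]),
            width = stats::runif(1, ep$mis_width_range[1], ep$mis_width_range[2]),
            center = stats::runif(1, if (first) -0.5 else ep$mis_center_range[1],
                                  if (first) 0.5 else ep$mis_center_range[2]),
            extent = stats::runif(1, ep$mis_extent_range[1], ep$mis_extent_range[2]))
        })
      }
      fruit_spec(L, Wd, Ht,
                 taper = stats::runif(1, ep$taper_range[1], ep$taper_range[2]),
                 lobes = lobes, id = sprintf("fruit_%03d", i))
    })
  })
  if (length(specs) == 0) {
    return(list(specs = specs,
                truth = data.frame(id = character(0), class = character(0),
                                   length_mm = numeric(0), width_mm = numeric(0),
                                   height_mm = numeric(0),
                                   true_volume_ml = numeric(0),
                                   true_mass_g = numeric(0),
                                   grade = character(0))))
  }
  rows <- lapply(specs, function(sp) {
    ss <- .solid_summary(sp, n_t = 2001, n_theta = 360)
    v <- ss$volume_ml
    m <- sp$density[["slope"]] * v + sp$density[["intercept"]]
    cls <- if (sp$is_misshapen) "misshapen" else "regular"
    data.frame(id = sp$id, class = cls,
               length_mm = sp$length_mm,
               width_mm = max(ss$y_hi) - min(ss$y_lo),
               height_mm = max(ss$z_hi) - min(ss$z_lo),
               true_volume_ml = v, true_mass_g = m,
               grade = assign_grade(m, cls))
  })
  list(specs = specs, truth = do.call(rbind, rows))
}

#' Shape features of a cohort of synthetic fruit
#'
#' Renders each fruit's ground-truth top mask and extracts the six shape
#' features; used to train and evaluate the shape classifier on synthetic
#' data.
#'
#' @param dataset Output of [generate_dataset()].
#' @param geometry,layout Scene geometry (defaults to those in the specs'
#'   generation).
#' @return Data frame: id, aspect_ratio, area_ratio, roundness, S1, S2, S3,
#'   label.
#' @export
dataset_features <- function(dataset, geometry = camera_geometry(),
                             layout = view_layout()) {
  rows <- lapply(seq_along(dataset$specs), function(i) {
    tr <- generate_fruit(dataset$specs[[i]], geometry, layout,
                         n_slices = 2001, n_theta = 360)
    f <- shape_features(tr$top_mask)
    cbind(data.frame(id = dataset$truth$id[i]), as.data.frame(t(f)),
          data.frame(label = dataset$truth$class[i]))
  })
  do.call(rbind, rows)
}
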