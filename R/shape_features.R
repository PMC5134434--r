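# Shape description of a closed fruit boundary.
#
# Two families of features are computed: size-shape parameters (aspect
# ratio, area ratio, roundness) from the mask measures, and
# Fourier-descriptor features from the centroid-distance signature of the
# boundary. The signature is resampled to 512 points and rescaled to a
# maximum of 100 before the DFT, which makes the S features scale-invariant;
# S_p sums the first 10 harmonic magnitudes weighted by m^p, so a bumpy,
# misshapen outline (more high-harmonic energy) scores higher than a smooth
# regular one.

#' Area-weighted centroid of a closed boundary
#'
#' Green's-theorem centroid of the polygon through the boundary pixel
#' centers.
#'
#' @param boundary A `boundary_trace` or two-column matrix of `(x, y)`.
#' @return Named numeric `c(x, y)`.
#' @export
boundary_centroid <- function(boundary) {
  x <- boundary[, 1]; y <- boundary[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < sqrt(.Machine$double.eps))
    stop("degenerate (zero-area) boundary", call. = FALSE)
  c(x = sum((x + xn) * cross) / (6 * a),
    y = sum((y + yn) * cross) / (6 * a))
}

#' Centroid-distance signature of a boundary
#'
#' `R(k)`: the Euclidean distance from the centroid to each boundary point,
#' in boundary (clockwise) order.
#'
#' @param boundary A `boundary_trace`.
#' @param centroid Optional centroid `c(x, y)`; computed with
#'   [boundary_centroid()] when missing.
#' @return A `distance_signature`: list with `values` (numeric vector) and
#'   `centroid`.
#' @export
distance_signature <- function(boundary, centroid = NULL) {
  if (is.null(centroid)) centroid <- boundary_centroid(boundary)
  structure(list(values = sqrt((boundary[, 1] - centroid[1])^2 +
                                 (boundary[, 2] - centroid[2])^2),
                 centroid = centroid),
            class = "distance_signature")
}

.sig_values <- function(sig) {
  if (inherits(sig, "distance_signature") || is.list(sig)) sig$values else sig
}

#' Resample and rescale a distance signature
#'
#' Linear-interpolation resampling of the (periodic) signature to `n`
#' equally spaced arc-index points, then rescaling so the maximum equals
#' `scale_to`. 512 points normalised to 100 puts every fruit's signature on
#' a common scale for comparison.
#'
#' @param sig A `distance_signature` or numeric vector.
#' @param n Number of output samples (default 512).
#' @param scale_to Value of the maximum after rescaling (default 100).
#' @return A `normalized_signature`: list with `values` (length `n`) and
#'   `scale` (the factor applied).
#' @export
normalize_signature <- function(sig, n = 512, scale_to = 100) {
  v <- .sig_values(sig)
  if (length(v) < 1) stop("empty signature", call. = FALSE)
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  N <- length(v)
  res <- if (N == n) v else {
    # periodic resample: sample positions k*N/n on the closed curve
    approx(x = 0:N, y = c(v, v[1]), xout = (0:(n - 1)) * N / n)$y
  }
  mx <- max(res)
  scale <- if (mx > 0) scale_to / mx else 1
  structure(list(values = res * scale, scale = scale),
            class = "normalized_signature")
}

#' Fourier magnitude spectrum of a signature
#'
#' `|F(m)| = (1/N) * sqrt[(sum_k R(k) cos(2 pi m k / N))^2 +
#' (sum_k R(k) sin(2 pi m k / N))^2]`, for `m = 0..m_max`.
#'
#' @param sig A `normalized_signature`, `distance_signature` or numeric
#'   vector.
#' @param m_max Highest harmonic to return (default `floor(N/2)`).
#' @return A `fourier_spectrum`: numeric vector of magnitudes named
#'   `"0".."m_max"`.
#' @export
fourier_magnitudes <- function(sig, m_max = NULL) {
  v <- .sig_values(sig)
  N <- length(v)
  if (is.null(m_max)) m_max <- N %/% 2
  if (m_max >= N) stop("m_max must be < length of the signature", call. = FALSE)
  mag <- Mod(fft(v)) / N
  structure(mag[1:(m_max + 1)], names = 0:m_max,
            class = "fourier_spectrum")
}

#' Harmonic-sum shape features S1, S2, S3
#'
#' `S_p = sum_{m=1}^{h_max} |F(m)| * m^p` over the first `h_max` harmonics.
#' Weighting by m emphasises high-frequency boundary irregularity: S1
#' relates to the derivative of the boundary signature, S2 to its curvature.
#'
#' @param spec A `fourier_spectrum` (must cover harmonics up to `h_max`).
#' @param h_max Highest harmonic summed (default 10).
#' @return Named numeric `c(S1, S2, S3)`.
#' @export
s_features <- function(spec, h_max = 10) {
  if (length(spec) < h_max + 1)
    stop("spectrum does not cover m <= h_max", call. = FALSE)
  m <- 1:h_max
  f <- as.numeric(spec[m + 1])
  c(S1 = sum(f * m), S2 = sum(f * m^2), S3 = sum(f * m^3))
}

#' Size-shape parameters
#'
#' Aspect ratio, area ratio, and roundness from the mask measures. Roundness
#' is `4 * area / (pi * maxD^2)`, normalised so a circle scores 1.
#'
#' @param measures List with `area`, `max_diameter`, `min_diameter` (any
#'   consistent units), e.g. from [measure_mask()] (fields `area_px`,
#'   `max_diameter_px`, `min_diameter_px` are also recognised).
#' @return Named numeric `c(aspect_ratio, area_ratio, roundness)`.
#' @export
size_shape <- function(measures) {
  area <- measures$area %||% measures$area_px
  maxd <- measures$max_diameter %||% measures$max_diameter_px
  mind <- measures$min_diameter %||% measures$min_diameter_px
  if (is.null(area) || is.null(maxd) || is.null(mind))
    stop("measures must provide area, max_diameter, min_diameter", call. = FALSE)
  if (mind <= 0 || maxd <= 0 || area <= 0)
    stop("area and diameters must be positive", call. = FALSE)
  aspect <- maxd / mind
  c(aspect_ratio = aspect,
    area_ratio = area / aspect,
    roundness = 4 * area / (pi * maxd^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full shape feature vector of a fruit mask
#'
#' Convenience wrapper: measures the mask, traces the boundary, builds the
#' 512-point normalised distance signature and returns the six shape
#' features used for classification. Size-shape parameters are computed on
#' the pixel scale unless `mm_per_px` is given.
#'
#' @param mask Single-component logical mask (top view).
#' @param mm_per_px Optional scale to express area and diameters in mm.
#' @param n_points Signature length (default 512).
#' @param h_max Harmonics summed in the S features (default 10).
#' @return Named numeric vector `aspect_ratio, area_ratio, roundness, S1,
#'   S2, S3`.
#' @export
shape_features <- function(mask, mm_per_px = NULL, n_points = 512, h_max = 10) {
  meas <- measure_mask(mask)
  if (!is.null(mm_per_px)) {
    meas$area_px <- meas$area_px * mm_per_px^2
    meas$max_diameter_px <- meas$max_diameter_px * mm_per_px
    meas$min_diameter_px <- meas$min_diameter_px * mm_per_px
  }
  ss <- size_shape(meas)
  bnd <- extract_boundary(mask)
  sig <- normalize_signature(distance_signature(bnd), n = n_points)
  s <- s_features(fourier_magnitudes(sig, m_max = h_max), h_max = h_max)
  c(ss, s)
}
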