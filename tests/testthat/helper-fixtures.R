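# fixtures are built in code: digital shapes, small scenes, oracles

disc_mask <- function(r, pad = 10) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  row <- matrix(rep(1:n, n), n)
  col <- t(row)
  (col - c0)^2 + (row - c0)^2 <= r^2
}

ellipse_mask <- function(a, b, pad = 10) {
  # semi-axes a (x) and b (y) in pixels
  n_r <- 2 * (b + pad) + 1
  n_c <- 2 * (a + pad) + 1
  r0 <- b + pad + 1; c0 <- a + pad + 1
  row <- matrix(rep(1:n_r, n_c), n_r)
  col <- matrix(rep(1:n_c, each = n_r), n_r)
  ((col - c0) / a)^2 + ((row - r0) / b)^2 <= 1
}

rect_mask <- function(h, w, pad = 5) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + (1:h), pad + (1:w)] <- TRUE
  m
}

# brute-force O(N^2) DFT magnitude oracle (the formula, term by term)
dft_oracle <- function(v, m_max) {
  N <- length(v)
  vapply(0:m_max, function(m) {
    k <- 0:(N - 1)
    sqrt(sum(v * cos(2 * pi * m * k / N))^2 +
           sum(v * sin(2 * pi * m * k / N))^2) / N
  }, numeric(1))
}

# polygon centroid by fan triangulation from the first vertex
centroid_oracle <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  cx <- 0; cy <- 0; A <- 0
  for (i in 2:(n - 1)) {
    ax <- x[i] - x[1]; ay <- y[i] - y[1]
    bx <- x[i + 1] - x[1]; by <- y[i + 1] - y[1]
    a2 <- (ax * by - ay * bx) / 2
    gx <- (x[1] + x[i] + x[i + 1]) / 3
    gy <- (y[1] + y[i] + y[i + 1]) / 3
    cx <- cx + a2 * gx; cy <- cy + a2 * gy; A <- A + a2
  }
  c(cx / A, cy / A)
}

# a small scene: modest fruit in a half-size frame for fast pipeline tests
small_layout <- function() view_layout(800, 480)

small_fruit <- function(length_mm = 90, width_mm = 54, height_mm = 48,
                        taper = 0.1, lobes = list(), id = "t1") {
  fruit_spec(length_mm, width_mm, height_mm, taper = taper, lobes = lobes,
             id = id)
}

small_scene <- function(spec = small_fruit(), noise = list(stem = FALSE,
                                                           specks = 0,
                                                           shadow = FALSE,
                                                           rgb_sd = 0),
                        seed = 1) {
  tr <- generate_fruit(spec, layout = small_layout(),
                       n_slices = 2001, n_theta = 360)
  list(truth = tr, render = render_scene(tr, noise, seed = seed))
}

small_config <- function(...) {
  run_config(layout = small_layout(), ...)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# coarser optics: ~0.42 mm/px top view, so a 150 mm fruit fits a 400 px
# half-frame; used where the full size range must fit the small layout
coarse_geometry <- function() {
  camera_geometry(focal_length_mm = 5, h2_mm = 500, h3_mm = 400, h4_mm = 200)
}
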