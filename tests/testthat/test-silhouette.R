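test_that("split_views crops the layout rectangles and rejects bad ones", {
  img <- array(runif(40 * 60 * 3, 0, 255), c(40, 60, 3))
  lay <- view_layout(60, 40)
  v <- split_views(img, lay)
  expect_equal(dim(v$top), c(40, 30, 3))
  expect_equal(dim(v$side), c(40, 30, 3))
  expect_identical(v$top[3, 4, ], img[3, 4, ])
  expect_identical(v$side[3, 4, ], img[3, 34, ])

  expect_error(split_views(img, view_layout(60, 40,
                                            top = c(0, 0, 60, 40),
                                            side = c(30, 0, 30, 40))),
               "overlap")
  expect_error(split_views(img, view_layout(60, 40,
                                            top = c(0, 0, 61, 40),
                                            side = c(61, 0, 2, 40))),
               "bounds")
  expect_error(view_layout(60, 40, top = c(0, 0, 0, 40)), "w, h >= 1")
})

test_that("to_gray_b extracts the blue channel", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(10, 20, 200)
  expect_equal(to_gray_b(img)[1, 1], 200)
  white <- array(255, c(3, 3, 3))
  expect_true(all(to_gray_b(white) == 255))
  expect_error(to_gray_b(matrix(0, 2, 2)), "RGB")
})

test_that("threshold_top keeps the fruit band and excludes stem and tray", {
  g <- matrix(c(10, 50, 150), 1, 3)
  expect_equal(as.vector(threshold_top(g)), c(FALSE, TRUE, FALSE))
  expect_false(any(threshold_top(matrix(255, 4, 4))))
  # boundary values are excluded on both sides
  g2 <- matrix(c(20, 21, 89, 90), 2, 2)
  expect_equal(as.vector(threshold_top(g2)), c(FALSE, TRUE, TRUE, FALSE))
  expect_error(threshold_top(g, bg_thresh = 15, stem_range = c(0, 20)),
               "below bg_thresh")
})

test_that("remove_small_particles drops specks but never the largest blob", {
  m <- matrix(FALSE, 120, 120)
  m[20:89, 20:89] <- TRUE            # 4900-px blob
  m[5:6, 5:9] <- TRUE                # 10-px speck
  m[110:111, 10:14] <- TRUE
  m[100:101, 100:104] <- TRUE
  out <- remove_small_particles(m, min_area = 100)
  expect_equal(sum(out), 70 * 70)
  expect_true(all(out[20:89, 20:89]))

  empty <- matrix(FALSE, 10, 10)
  expect_identical(remove_small_particles(empty, 10), empty)

  # a lone blob below min_area is retained (one object per view)
  lone <- matrix(FALSE, 20, 20); lone[5:7, 5:7] <- TRUE
  expect_identical(remove_small_particles(lone, min_area = 100), lone)

  # idempotence
  expect_identical(remove_small_particles(out, 100), out)
})

test_that("fill_holes fills enclosed background and is idempotent", {
  ann <- disc_mask(20) & !disc_mask(8, pad = 22)
  expect_identical(fill_holes(ann), disc_mask(20))
  blob <- disc_mask(10)
  expect_identical(fill_holes(blob), blob)
  expect_identical(fill_holes(fill_holes(ann)), fill_holes(ann))
})

test_that("three-pass side threshold removes the shadow band", {
  sc <- small_scene(noise = list(stem = FALSE, specks = 0, shadow = TRUE,
                                 rgb_sd = 0))
  v <- split_views(sc$render$image, small_layout())
  mask <- threshold_side(v$side)
  truth <- sc$truth$side_mask[, 401:800]
  shadow <- sc$render$labels$shadow[, 401:800]
  expect_true(any(shadow))
  expect_false(any(mask & shadow))
  recall <- sum(mask & truth) / sum(truth)
  expect_gte(recall, 0.98)
  # single-pass B threshold would have kept the shadow
  single <- v$side[, , 3] < 120
  expect_true(any(single & shadow))
  expect_error(threshold_side(v$side, median_size = 4), "odd")
  expect_false(any(threshold_side(array(250, c(20, 20, 3)))))
})

test_that("without a shadow the extra passes change nothing", {
  sc <- small_scene(noise = list(stem = FALSE, specks = 0, shadow = FALSE,
                                 rgb_sd = 0))
  v <- split_views(sc$render$image, small_layout())
  three <- threshold_side(v$side)
  one <- threshold_side(v$side, params = list(c("B", 120)))
  expect_identical(three, one)
})

test_that("extract_boundary traces a closed clockwise 8-connected contour", {
  m <- matrix(FALSE, 7, 7); m[3:5, 3:5] <- TRUE
  b <- extract_boundary(m)
  expect_equal(nrow(b), 8)
  expect_equal(b[1, ], c(x = 2, y = 2))  # topmost-then-leftmost start

  mc <- disc_mask(50)
  bc <- extract_boundary(mc)
  steps <- cbind(diff(c(bc[, 1], bc[1, 1])), diff(c(bc[, 2], bc[1, 2])))
  expect_true(all(abs(steps) <= 1))
  expect_true(all(rowSums(abs(steps)) > 0))
  expect_false(anyDuplicated(paste(bc[, 1], bc[, 2])) > 0)

  perim <- sum(sqrt(rowSums(steps^2)))
  expect_gte(perim, 2 * pi * 50)
  expect_lte(perim, 2 * pi * 50 * sqrt(2) * 1.1)

  # clockwise convention: negative shoelace signed area
  x <- bc[, 1]; y <- bc[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  expect_lt(sum(x * yn - xn * y) / 2, 0)

  expect_error(extract_boundary(matrix(FALSE, 5, 5)), "area >= 4")
  two <- matrix(FALSE, 20, 20); two[2:5, 2:5] <- TRUE; two[10:13, 10:13] <- TRUE
  expect_error(extract_boundary(two), "exactly one")
})

test_that("boundary round-trips through rasterization for hole-free masks", {
  for (m in list(disc_mask(30), ellipse_mask(40, 22), rect_mask(15, 33))) {
    b <- extract_boundary(m)
    expect_identical(boundary_to_mask(b, dim(m)), m)
  }
  sc <- small_scene()
  b <- extract_boundary(sc$truth$top_mask)
  expect_identical(boundary_to_mask(b, dim(sc$truth$top_mask)),
                   sc$truth$top_mask)
})

test_that("measure_mask reports area, Feret diameters and bbox", {
  r <- rect_mask(10, 20)
  mr <- measure_mask(r)
  expect_equal(mr$area_px, 200)
  expect_equal(unname(mr$bbox[c("w", "h")]), c(20, 10))

  md <- measure_mask(disc_mask(50))
  expect_lt(abs(md$area_px / (pi * 50^2) - 1), 0.01)
  expect_equal(md$max_diameter_px, 100, tolerance = 0.02)

  me <- measure_mask(ellipse_mask(100, 50))
  expect_equal(me$max_diameter_px / me$min_diameter_px, 2, tolerance = 0.02)

  expect_error(measure_mask(matrix(FALSE, 5, 5)), "empty")
})

test_that("segmentation operations do not modify their inputs", {
  m <- disc_mask(15)
  m[3, 3] <- TRUE
  snapshot <- m
  invisible(remove_small_particles(m, 10))
  invisible(fill_holes(m))
  expect_identical(m, snapshot)
})
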