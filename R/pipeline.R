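# End-to-end grading runs: split -> segment both views -> calibrate ->
# shape features -> classify -> (regular only) disk volume -> mass -> grade.

#' Run configuration
#'
#' @param geometry A [camera_geometry()].
#' @param layout A [view_layout()].
#' @param bg_thresh,stem_range Top-view threshold parameters.
#' @param side_params Side-view threshold passes (list of
#'   `(channel, intensity)`).
#' @param median_size Side-view median filter size (odd).
#' @param min_area Small-particle threshold; `NULL` = scaled default.
#' @param model A `discriminant_model`, a path to a model JSON, or
#'   `"builtin"` for the shipped coefficients.
#' @param classify If `FALSE`, every fruit is graded as regular (shape
#'   classification disabled).
#' @param feature_units `"px"` (default) or `"mm"`: scale on which size-shape
#'   features are computed. The builtin model presumes the original
#'   acquisition scale.
#' @param mass_slope,mass_intercept Mass-model coefficients.
#' @param grade_a,grade_b Grade thresholds in g (A: `>= grade_a`,
#'   B: `[grade_b, grade_a)`, C below).
#' @param seed Seed recorded in the config (used by `simulate` runs).
#' @return A `run_config`.
#' @export
run_config <- function(geometry = camera_geometry(), layout = view_layout(),
                       bg_thresh = 90, stem_range = c(0, 20),
                       side_params = list(c("B", 120), c("G", 110), c("B", 100)),
                       median_size = 7, min_area = NULL,
                       model = "builtin", classify = TRUE,
                       feature_units = c("px", "mm"),
                       mass_slope = 0.9973, mass_intercept = 6.778,
                       grade_a = 400, grade_b = 350, seed = 1) {
  feature_units <- match.arg(feature_units)
  if (is.character(model) && model != "builtin") model <- read_model_json(model)
  structure(list(geometry = geometry, layout = layout,
                 bg_thresh = bg_thresh, stem_range = stem_range,
                 side_params = side_params, median_size = median_size,
                 min_area = min_area, model = model, classify = classify,
                 feature_units = feature_units,
                 mass_slope = mass_slope, mass_intercept = mass_intercept,
                 grade_a = grade_a, grade_b = grade_b, seed = seed),
            class = "run_config")
}

.config_model <- function(config) {
  if (identical(config$model, "builtin")) default_shape_model() else config$model
}

#' Write / read a run configuration as YAML
#'
#' The configuration round-trips unchanged (the model is stored as
#' `"builtin"` or an inline coefficient table).
#'
#' @param config A `run_config`.
#' @param path YAML path.
#' @return `path` / a `run_config`.
#' @export
write_config_yaml <- function(config, path) {
  obj <- list(
    geometry = config$geometry[c("focal_length_mm", "pixel_size_mm", "h2_mm",
                                 "h3_mm", "h4_mm", "plane_fraction")],
    layout = list(frame_width = config$layout$frame_width,
                  frame_height = config$layout$frame_height,
                  top = as.integer(config$layout$top),
                  side = as.integer(config$layout$side)),
    bg_thresh = config$bg_thresh, stem_range = config$stem_range,
    side_params = lapply(config$side_params,
                         function(p) list(channel = as.character(p[[1]]),
                                          intensity = as.numeric(p[[2]]))),
    median_size = config$median_size, min_area = config$min_area,
    model = if (identical(config$model, "builtin")) "builtin" else
      list(classes = config$model$classes,
           features = config$model$features,
           coefficients = apply(config$model$coefficients, 2, as.list),
           constants = as.list(config$model$constants)),
    classify = config$classify, feature_units = config$feature_units,
    mass_slope = config$mass_slope, mass_intercept = config$mass_intercept,
    grade_a = config$grade_a, grade_b = config$grade_b, seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  o <- yaml::read_yaml(path)
  model <- o$model
  if (!identical(model, "builtin")) {
    coefs <- sapply(model$coefficients, function(cl) unlist(cl))
    rownames(coefs) <- model$features
    model <- discriminant_model(unlist(model$classes), coefs,
                                unlist(model$constants))
  }
  run_config(
    geometry = do.call(camera_geometry, o$geometry),
    layout = view_layout(o$layout$frame_width, o$layout$frame_height,
                         top = unlist(o$layout$top),
                         side = unlist(o$layout$side)),
    bg_thresh = o$bg_thresh, stem_range = unlist(o$stem_range),
    side_params = lapply(o$side_params,
                         function(p) c(p$channel, p$intensity)),
    median_size = o$median_size, min_area = o$min_area,
    model = model, classify = o$classify, feature_units = o$feature_units,
    mass_slope = o$mass_slope, mass_intercept = o$mass_intercept,
    grade_a = o$grade_a, grade_b = o$grade_b, seed = o$seed)
}

#' Segment the top view of a frame
#'
#' B-band conversion, stem/background double threshold, small-particle
#' removal, hole filling.
#'
#' @param image Top-view raster array.
#' @param config A `run_config`.
#' @return Logical fruit mask.
#' @export
segment_top <- function(image, config = run_config()) {
  m <- threshold_top(to_gray_b(image), config$bg_thresh, config$stem_range)
  m <- remove_small_particles(m, config$min_area)
  fill_holes(m)
}

#' Segment the side view of a frame
#'
#' Three-pass B/G/B thresholding with inter-pass median filtering, then
#' small-particle removal and hole filling.
#'
#' @inheritParams segment_top
#' @return Logical fruit mask.
#' @export
segment_side <- function(image, config = run_config()) {
  m <- threshold_side(image, config$side_params, config$median_size)
  m <- remove_small_particles(m, config$min_area)
  fill_holes(m)
}

#' Process one two-view frame
#'
#' @param image Raster array (or path to a PNG).
#' @param config A `run_config`.
#' @param id Identifier recorded in the result.
#' @return One-row data frame: id, shape_class, length_mm, width_mm,
#'   height_mm, volume_ml, mass_g, grade.
#' @export
process_frame <- function(image, config = run_config(), id = "fruit") {
  if (is.character(image)) image <- read_raster(image)
  views <- split_views(image, config$layout)
  top <- segment_top(views$top, config)
  side <- segment_side(views$side, config)
  if (!any(top) || !any(side)) stop("no fruit found in one of the views",
                                    call. = FALSE)

  geom <- config$geometry
  height_px <- mask_extent_px(side)
  height_mm <- side_view_size(height_px, geom)
  geom$h1_mm <- derive_h1(height_mm, geom)
  sc <- mm_per_px(geom)

  meas <- measure_mask(top)
  length_mm <- meas$max_diameter_px * sc["top"]
  width_mm <- meas$min_diameter_px * sc["top"]

  feats <- shape_features(top, mm_per_px = if (config$feature_units == "mm")
    sc[["top"]] else NULL)
  cls <- if (isTRUE(config$classify))
    classify_shape(feats, .config_model(config)) else "regular"

  if (cls == "regular") {
    prof <- slice_profiles(top, side, sc[["top"]], sc[["side"]])
    vol <- disk_volume(prof)
    mass <- estimate_mass(vol, config$mass_slope, config$mass_intercept)
    grade <- if (mass >= config$grade_a) "A" else
      if (mass >= config$grade_b) "B" else "C"
  } else {
    vol <- NA_real_; mass <- NA_real_; grade <- "Rejected"
  }
  data.frame(id = id, shape_class = cls,
             length_mm = unname(length_mm), width_mm = unname(width_mm),
             height_mm = unname(height_mm),
             volume_ml = unname(vol), mass_g = unname(mass), grade = grade,
             error = NA_character_)
}

#' Grade a batch of frames
#'
#' Processes each frame independently; per-item failures are recorded as
#' error rows and the run continues, so every input yields exactly one
#' report row.
#'
#' @param images Character vector of PNG paths, or a list of raster arrays
#'   (optionally named).
#' @param config A `run_config`.
#' @return A `grade_report` data frame (one row per input) with columns as
#'   in [process_frame()] plus `error`.
#' @export
grade_batch <- function(images, config = run_config()) {
  ids <- names(images)
  if (is.null(ids)) {
    ids <- if (is.character(images)) basename(images) else
      sprintf("fruit_%03d", seq_along(images))
  }
  rows <- lapply(seq_along(images), function(i) {
    tryCatch(process_frame(images[[i]], config, id = ids[i]),
             error = function(e)
               data.frame(id = ids[i], shape_class = NA_character_,
                          length_mm = NA_real_, width_mm = NA_real_,
                          height_mm = NA_real_, volume_ml = NA_real_,
                          mass_g = NA_real_, grade = NA_character_,
                          error = conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("grade_report", class(out))
  out
}

#' @export
print.grade_report <- function(x, ...) {
  ok <- is.na(x$error)
  cat("Grade report:", nrow(x), "items,", sum(!ok), "errors\n")
  if (any(ok)) print(table(grade = x$grade[ok]))
  NextMethod()
}

#' Write a grade report as CSV and JSON
#'
#' @param report A `grade_report`.
#' @param csv,json Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) round(v, 2))
  if (!is.null(csv)) write.csv(df, csv, row.names = FALSE)
  if (!is.null(json)) {
    ok <- is.na(df$error)
    summary <- list(n = nrow(df), errors = sum(!ok),
                    grades = as.list(table(df$grade[ok])))
    jsonlite::write_json(list(summary = summary, results = df), json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(report)
}

#' Train a shape model from a labelled feature table
#'
#' Runs stepwise Wilks' Lambda selection, then fits Fisher classification
#' functions on the selected features. Falls back to all features if the
#' selection is empty.
#'
#' @param features Data frame with feature columns and a `label` column, or
#'   a path to such a CSV (header
#'   `id,aspect_ratio,area_ratio,roundness,S1,S2,S3,label`).
#' @param f_enter,f_remove Stepwise thresholds.
#' @return List with `model` (a `discriminant_model`), `selected`, `trace`.
#' @export
train_shape_model <- function(features, f_enter = 3.84, f_remove = 2.71) {
  if (is.character(features)) features <- read.csv(features)
  if (!"label" %in% names(features))
    stop("features must have a 'label' column", call. = FALSE)
  y <- as.character(features$label)
  if (length(unique(y)) < 2)
    stop("training data must contain >= 2 classes", call. = FALSE)
  if (any(table(y) < 2))
    stop("need >= 2 samples per class", call. = FALSE)
  X <- features[, setdiff(names(features), c("id", "label")), drop = FALSE]
  sel <- stepwise_select(X, y, f_enter, f_remove)
  use <- if (length(sel$selected)) sel$selected else colnames(X)
  model <- fit_classification_functions(X[, use, drop = FALSE], y)
  list(model = model, selected = sel$selected, trace = sel$trace)
}
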