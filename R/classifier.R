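# Fisher linear classification functions for regular vs misshapen fruit.
#
# Each class c gets a linear score constant_c + sum(coef_c * features);
# the argmax assigns the class. The shipped default model carries the
# published coefficients for Harumanis mango on the S1, S2, S3 and
# area-ratio features, so fruit can be classified without any training
# data. Retraining computes classification functions from the pooled
# within-class covariance, optionally after stepwise Wilks' Lambda feature
# selection.

#' Construct a linear discriminant (classification-function) model
#'
#' @param classes Character vector of class labels; the first class wins
#'   ties.
#' @param coefficients Numeric matrix, one column per class (named), one row
#'   per feature (named).
#' @param constants Named numeric vector of per-class constants.
#' @return A `discriminant_model`.
#' @export
discriminant_model <- function(classes, coefficients, constants) {
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  coefficients <- as.matrix(coefficients)
  if (is.null(rownames(coefficients)) || is.null(colnames(coefficients)))
    stop("coefficients must have feature rownames and class colnames",
         call. = FALSE)
  if (!setequal(colnames(coefficients), classes) ||
      !setequal(names(constants), classes))
    stop("coefficient columns and constants must match classes", call. = FALSE)
  structure(list(classes = classes,
                 features = rownames(coefficients),
                 coefficients = coefficients[, classes, drop = FALSE],
                 constants = constants[classes]),
            class = "discriminant_model")
}

#' The built-in shape model for Harumanis mango
#'
#' Classification-function coefficients on S1, S2, S3 and area ratio:
#' regular = -198.85 + 24.96 S1 - 8.95 S2 + 0.78 S3 + 0.34 AR;
#' misshapen = -228.38 + 22.05 S1 - 6.97 S2 + 0.59 S3 + 0.37 AR. These
#' presume features on the original acquisition scale (see the package
#' vignette on feature units).
#'
#' @return A `discriminant_model` with classes `regular`, `misshapen`.
#' @export
default_shape_model <- function() {
  coefs <- cbind(regular = c(S1 = 24.96, S2 = -8.95, S3 = 0.78,
                             area_ratio = 0.34),
                 misshapen = c(S1 = 22.05, S2 = -6.97, S3 = 0.59,
                               area_ratio = 0.37))
  discriminant_model(classes = c("regular", "misshapen"),
                     coefficients = coefs,
                     constants = c(regular = -198.85, misshapen = -228.38))
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("Fisher linear classification functions (", length(x$classes),
      " classes)\n", sep = "")
  tab <- rbind(x$coefficients, `(constant)` = x$constants)
  print(round(tab, 4))
  invisible(x)
}

.feature_row <- function(features, wanted) {
  if (is.data.frame(features)) features <- unlist(features[1, , drop = TRUE])
  miss <- setdiff(wanted, names(features))
  if (length(miss))
    stop("missing features: ", paste(miss, collapse = ", "), call. = FALSE)
  as.numeric(features[wanted])
}

#' Per-class discriminant scores
#'
#' @param features Named numeric vector (or 1-row data frame) providing
#'   every model feature.
#' @param model A `discriminant_model` (default: [default_shape_model()]).
#' @return Named numeric vector of scores, one per class.
#' @export
discriminant_scores <- function(features, model = default_shape_model()) {
  v <- .feature_row(features, model$features)
  drop(v %*% model$coefficients) + model$constants
}

#' Classify a feature vector
#'
#' Assigns the class with the highest discriminant score; exact ties go to
#' the first listed class.
#'
#' @inheritParams discriminant_scores
#' @return A class label (character).
#' @export
classify_shape <- function(features, model = default_shape_model()) {
  s <- discriminant_scores(features, model)
  model$classes[which.max(s[model$classes])]
}

#' Predict classes for a feature table
#'
#' @param object A `discriminant_model`.
#' @param newdata Data frame with the model's feature columns.
#' @param type `"class"` (default) or `"scores"`.
#' @param ... Unused.
#' @return Character vector of labels, or a score matrix.
#' @export
predict.discriminant_model <- function(object, newdata, type = c("class", "scores"),
                                       ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  S <- X %*% object$coefficients +
    matrix(object$constants, nrow(X), length(object$classes), byrow = TRUE)
  colnames(S) <- object$classes
  if (type == "scores") return(S)
  object$classes[max.col(S[, object$classes, drop = FALSE], ties.method = "first")]
}

#' Fit Fisher classification functions
#'
#' Coefficients `W^-1 mu_k` and constants `-mu_k' W^-1 mu_k / 2 + log
#' prior_k`, with `W` the pooled within-class covariance. Equal priors by
#' default.
#'
#' @param x Numeric matrix or data frame of features (named columns).
#' @param y Class labels (character/factor), >= 2 samples per class.
#' @param prior Named numeric priors (default equal).
#' @return A `discriminant_model`; class order follows the order of first
#'   appearance in `y`.
#' @export
fit_classification_functions <- function(x, y, prior = NULL) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(y) < 2)) stop("need >= 2 samples per class", call. = FALSE)
  if (is.null(prior)) prior <- rep(1 / length(classes), length(classes))
  if (is.null(names(prior))) names(prior) <- classes

  n <- nrow(X); g <- length(classes)
  mus <- vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                numeric(ncol(X)))
  if (is.null(dim(mus)))
    mus <- matrix(mus, 1, g, dimnames = list(colnames(X), classes))
  W <- matrix(0, ncol(X), ncol(X))
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    Xi <- sweep(Xi, 2, mus[, cl])
    W <- W + crossprod(Xi)
  }
  W <- W / (n - g)
  Winv <- tryCatch(solve(W), error = function(e)
    stop("pooled within-class covariance is singular", call. = FALSE))
  coefs <- Winv %*% mus
  consts <- -0.5 * colSums(mus * coefs) + log(prior[classes])
  rownames(coefs) <- colnames(X); colnames(coefs) <- classes
  discriminant_model(classes, coefs, consts)
}

#' Wilks' Lambda of a feature subset
#'
#' `Lambda = det(W) / det(T)` with `W` the within-group and `T` the total
#' scatter matrix of the subset; values near 0 indicate well-separated
#' groups.
#'
#' @param x Feature matrix / data frame.
#' @param y Class labels.
#' @param features Column names (or indices) of the subset; defaults to all.
#' @return Lambda in (0, 1].
#' @export
wilks_lambda <- function(x, y, features = colnames(as.data.frame(x))) {
  X <- as.matrix(as.data.frame(x)[, features, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.character(y)
  Tm <- crossprod(sweep(X, 2, colMeans(X)))
  W <- matrix(0, ncol(X), ncol(X))
  for (cl in unique(y)) {
    Xi <- X[y == cl, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    W <- W + crossprod(Xi)
  }
  dT <- det(Tm)
  if (!is.finite(dT) || dT <= 0)
    stop("total scatter matrix is singular", call. = FALSE)
  det(W) / dT
}

#' Stepwise Wilks' Lambda feature selection
#'
#' At each step the candidate that minimises the overall Wilks' Lambda is
#' entered if its partial F exceeds `f_enter`; in-model features whose
#' partial F falls below `f_remove` are removed. Iterates until no change.
#'
#' @param x Feature matrix / data frame (>= 2 columns).
#' @param y Class labels.
#' @param f_enter F-to-enter threshold (default 3.84).
#' @param f_remove F-to-remove threshold (default 2.71).
#' @param max_steps Safety cap on enter/remove steps.
#' @return List with `selected` (character vector, possibly empty) and
#'   `trace` (data frame: step, action, feature, lambda, F).
#' @export
stepwise_select <- function(x, y, f_enter = 3.84, f_remove = 2.71,
                            max_steps = 100) {
  X <- as.data.frame(x)
  if (ncol(X) < 2) stop("need >= 2 candidate features", call. = FALSE)
  y <- as.character(y)
  n <- nrow(X); g <- length(unique(y))
  selected <- character(0)
  trace <- data.frame(step = integer(0), action = character(0),
                      feature = character(0), lambda = numeric(0),
                      F = numeric(0))
  lam_cur <- 1
  step <- 0
  seen <- character(0)
  repeat {
    changed <- FALSE
    # enter: candidate minimising Lambda
    cands <- setdiff(colnames(X), selected)
    if (length(cands)) {
      lam_new <- vapply(cands, function(f)
        tryCatch(wilks_lambda(X, y, c(selected, f)), error = function(e) NA_real_),
        numeric(1))
      ok <- which(is.finite(lam_new))
      if (length(ok)) {
        best <- ok[which.min(lam_new[ok])]
        p <- length(selected)
        Fent <- (n - g - p) / (g - 1) * (lam_cur / lam_new[best] - 1)
        if (is.finite(Fent) && Fent >= f_enter) {
          selected <- c(selected, cands[best])
          lam_cur <- lam_new[best]
          step <- step + 1
          trace <- rbind(trace, data.frame(step = step, action = "enter",
                                           feature = cands[best],
                                           lambda = lam_cur, F = Fent))
          changed <- TRUE
        }
      }
    }
    # remove: in-model feature with smallest partial F
    if (length(selected) > 1) {
      p <- length(selected)
      Frem <- vapply(selected, function(f) {
        lam_wo <- wilks_lambda(X, y, setdiff(selected, f))
        (n - g - p + 1) / (g - 1) * (lam_wo / lam_cur - 1)
      }, numeric(1))
      worst <- which.min(Frem)
      if (Frem[worst] < f_remove) {
        drop_f <- selected[worst]
        selected <- setdiff(selected, drop_f)
        lam_cur <- if (length(selected)) wilks_lambda(X, y, selected) else 1
        step <- step + 1
        trace <- rbind(trace, data.frame(step = step, action = "remove",
                                         feature = drop_f,
                                         lambda = lam_cur, F = Frem[worst]))
        changed <- TRUE
      }
    }
    state <- paste(sort(selected), collapse = ",")
    if (!changed || step >= max_steps || state %in% seen) break
    seen <- c(seen, state)
  }
  list(selected = selected, trace = trace)
}

#' Confusion matrix with per-class and overall accuracy
#'
#' @param y_true Actual labels.
#' @param y_pred Predicted labels (same length).
#' @return A `confusion_report`: list with `counts` (actual x predicted
#'   matrix), `per_class_pct`, `overall_pct`, `n`.
#' @export
confusion_report <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("label vectors must have equal length", call. = FALSE)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  levs <- union(unique(y_true), unique(y_pred))
  counts <- table(factor(y_true, levs), factor(y_pred, levs))
  counts <- matrix(counts, length(levs), length(levs),
                   dimnames = list(actual = levs, predicted = levs))
  rs <- rowSums(counts)
  per_class <- ifelse(rs > 0, 100 * diag(counts) / rs, NA_real_)
  names(per_class) <- levs
  structure(list(counts = counts,
                 per_class_pct = per_class,
                 overall_pct = 100 * sum(diag(counts)) / sum(counts),
                 n = sum(counts)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("Confusion matrix (n = ", x$n, "):\n", sep = "")
  tab <- cbind(x$counts, Total = rowSums(x$counts),
               Percentage = sprintf("%.1f%%", x$per_class_pct))
  print(tab, quote = FALSE)
  cat(sprintf("Overall: %.1f%%\n", x$overall_pct))
  invisible(x)
}

#' Serialize a discriminant model to JSON
#'
#' @param model A `discriminant_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(classes = model$classes,
              features = model$features,
              coefficients = as.data.frame(model$coefficients),
              constants = as.list(model$constants))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a discriminant model from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return A `discriminant_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- as.matrix(obj$coefficients)
  rownames(coefs) <- obj$features
  discriminant_model(obj$classes, coefs, unlist(obj$constants))
}
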