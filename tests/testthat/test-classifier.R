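# published cohort mean feature vectors for regular and misshapen fruit:
# the reference points for the shipped classification functions
means_regular <- c(S1 = 20.49, S2 = 62.47, S3 = 311.29, area_ratio = 593.79)
means_misshapen <- c(S1 = 25.72, S2 = 94.25, S3 = 510.31, area_ratio = 653.66)

test_that("discriminant scores reproduce the published classification functions", {
  m <- default_shape_model()
  zero <- c(S1 = 0, S2 = 0, S3 = 0, area_ratio = 0)
  expect_equal(unname(discriminant_scores(zero, m)),
               c(-198.85, -228.38))

  # hand evaluation of the two linear functions at the cohort means
  s_reg <- discriminant_scores(means_regular, m)
  expect_equal(unname(s_reg["regular"]), 198.17, tolerance = 0.01)
  expect_equal(unname(s_reg["misshapen"]), 191.36, tolerance = 0.01)
  expect_gt(s_reg["regular"], s_reg["misshapen"])

  s_mis <- discriminant_scores(means_misshapen, m)
  expect_gt(s_mis["misshapen"], s_mis["regular"])

  expect_error(discriminant_scores(c(S1 = 1), m), "missing features")
})

test_that("classify_shape takes the argmax with a deterministic tie-break", {
  m <- default_shape_model()
  expect_equal(classify_shape(means_regular, m), "regular")
  expect_equal(classify_shape(means_misshapen, m), "misshapen")

  # exactly equal scores -> first listed class
  tie <- discriminant_model(c("regular", "misshapen"),
                            cbind(regular = c(f = 1), misshapen = c(f = 1)),
                            c(regular = 0, misshapen = 0))
  expect_equal(classify_shape(c(f = 3), tie), "regular")
})

test_that("fitted classification functions separate what is separable", {
  withr::with_seed(31, {
    n <- 100
    X <- rbind(matrix(rnorm(2 * n), n), matrix(rnorm(2 * n, 10), n))
    colnames(X) <- c("u", "v")
    y <- rep(c("a", "b"), each = n)
    m <- fit_classification_functions(X, y)
    expect_equal(mean(predict(m, as.data.frame(X)) == y), 1)

    # identical class distributions: chance-level accuracy
    X0 <- matrix(rnorm(4 * n), 2 * n)
    colnames(X0) <- c("u", "v")
    m0 <- fit_classification_functions(X0, y)
    acc0 <- mean(predict(m0, as.data.frame(X0)) == y)
    expect_lt(abs(acc0 - 0.5), 0.1)
  })
})

test_that("refitting on data at the published effect sizes recovers the labels", {
  withr::with_seed(77, {
    sd_reg <- c(2.03, 9.75, 68.01, 56.79)
    sd_mis <- c(5.094, 26.21, 190.27, 69.18)
    gen <- function(n, mu, sd) {
      X <- sapply(seq_along(mu), function(j) rnorm(n, mu[j], sd[j]))
      colnames(X) <- names(means_regular)
      X
    }
    X <- rbind(gen(159, means_regular, sd_reg), gen(21, means_misshapen, sd_mis))
    y <- rep(c("regular", "misshapen"), c(159, 21))
    m <- fit_classification_functions(X, y)
    expect_gte(mean(predict(m, as.data.frame(X)) == y), 0.90)
  })
})

test_that("fitted model agrees with an independent LDA implementation", {
  withr::with_seed(9, {
    n <- 80
    X <- data.frame(u = c(rnorm(n, 0), rnorm(n, 1.5)),
                    v = c(rnorm(n, 1), rnorm(n, 0)))
    y <- rep(c("a", "b"), each = n)
    mine <- predict(fit_classification_functions(X, y), X)
    ref <- as.character(predict(MASS::lda(X, grouping = y,
                                          prior = c(0.5, 0.5)))$class)
    expect_equal(mine, ref)
  })
})

test_that("duplicating every row leaves the decision boundary unchanged", {
  withr::with_seed(13, {
    X <- data.frame(u = rnorm(40), v = rnorm(40, 1))
    y <- rep(c("a", "b"), each = 20)
    m1 <- fit_classification_functions(X, y)
    m2 <- fit_classification_functions(rbind(X, X), c(y, y))
    grid <- expand.grid(u = seq(-3, 3, length.out = 11),
                        v = seq(-2, 4, length.out = 11))
    expect_equal(predict(m1, grid), predict(m2, grid))
  })
})

test_that("scores are affine: compensated feature scaling preserves classes", {
  m <- default_shape_model()
  scale <- c(S1 = 10, S2 = 0.5, S3 = 2, area_ratio = 100)
  m2 <- discriminant_model(m$classes, m$coefficients / scale, m$constants)
  withr::with_seed(3, {
    for (i in 1:20) {
      f <- c(S1 = runif(1, 10, 30), S2 = runif(1, 40, 120),
             S3 = runif(1, 200, 700), area_ratio = runif(1, 400, 800))
      expect_equal(classify_shape(f, m), classify_shape(f * scale, m2))
    }
  })
})

test_that("wilks_lambda matches the scatter-determinant ratio", {
  withr::with_seed(21, {
    n <- 60
    X <- data.frame(u = rnorm(n), v = rnorm(n), w = rnorm(n))
    y <- rep(c("a", "b"), each = n / 2)
    # direct oracle from the definition
    oracle <- function(X, y) {
      M <- as.matrix(X)
      Tm <- crossprod(sweep(M, 2, colMeans(M)))
      W <- Reduce(`+`, lapply(unique(y), function(cl) {
        Mi <- M[y == cl, , drop = FALSE]
        crossprod(sweep(Mi, 2, colMeans(Mi)))
      }))
      det(W) / det(Tm)
    }
    expect_equal(wilks_lambda(X, y), oracle(X, y), tolerance = 1e-9)
    expect_equal(wilks_lambda(X, y, c("u", "w")), oracle(X[c("u", "w")], y),
                 tolerance = 1e-9)

    # identical group means: Lambda near 1
    expect_gt(wilks_lambda(X, y), 0.9)
    # near-perfect 1-D separation: Lambda near 0
    Xs <- data.frame(u = c(rnorm(30, 0, 0.1), rnorm(30, 50, 0.1)), v = rnorm(60))
    expect_lt(wilks_lambda(Xs, y, "u"), 0.01)
  })
})

test_that("stepwise selection finds signal, skips noise, and logs a trace", {
  withr::with_seed(101, {
    n <- 100
    y <- rep(c("a", "b"), each = n / 2)
    hits_first <- 0
    for (r in 1:20) {
      X <- data.frame(inf = rnorm(n) + ifelse(y == "a", 0, 2),
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
      res <- stepwise_select(X, y)
      expect_true("inf" %in% res$selected)
      enters <- res$trace[res$trace$action == "enter", ]
      hits_first <- hits_first + (enters$feature[1] == "inf")
      # Lambda is non-increasing across enter steps
      expect_true(all(diff(enters$lambda) <= 1e-12))
      expect_true(all(res$trace$lambda > 0 & res$trace$lambda <= 1))
    }
    expect_equal(hits_first, 20)

    # all-noise features: usually nothing is selected at these thresholds
    none <- 0
    for (r in 1:100) {
      Xn <- data.frame(n1 = rnorm(n), n2 = rnorm(n),
                       n3 = rnorm(n), n4 = rnorm(n))
      none <- none + (length(stepwise_select(Xn, y)$selected) == 0)
    }
    expect_gte(none, 70)
  })
})

test_that("confusion_report reproduces the published matrix arithmetic", {
  # training set: 19/2 misshapen, 1/158 regular
  y_true <- rep(c("misshapen", "regular"), c(21, 159))
  y_pred <- c(rep("misshapen", 19), rep("regular", 2),
              rep("misshapen", 1), rep("regular", 158))
  cr <- confusion_report(y_true, y_pred)
  expect_equal(round(cr$overall_pct, 1), 98.3)
  expect_equal(round(unname(cr$per_class_pct["misshapen"]), 1), 90.5)
  expect_equal(round(unname(cr$per_class_pct["regular"]), 1), 99.4)

  # grading validation set counts
  g_true <- rep(c("A", "B", "C"), c(42, 42, 42))
  g_pred <- c(rep("A", 40), rep("B", 2),
              rep("A", 1), rep("B", 39), rep("C", 2),
              rep("B", 2), rep("C", 40))
  gr <- confusion_report(g_true, g_pred)
  expect_equal(round(gr$overall_pct, 1), 94.4)

  perfect <- confusion_report(c("x", "y"), c("x", "y"))
  expect_equal(perfect$overall_pct, 100)
  expect_true(all(perfect$per_class_pct == 100))
  expect_error(confusion_report("a", c("a", "b")), "equal length")
})

test_that("models survive a JSON round trip", {
  m <- default_shape_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$classes, m$classes)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$constants, m$constants)
  expect_equal(classify_shape(means_misshapen, m2), "misshapen")
})
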