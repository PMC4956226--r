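# Classifier harnesses: tuning contracts, fits, attribution, prediction.

test_that("tuning contracts hold (grids, grouped folds, determinism)", {
  d <- make_planted_features(8, 6, n_noise = 4, seed = 3)
  cols <- planted_feature_cols(d)

  # patient-grouped folds never split a patient
  foldid <- patient_folds(d$patient_id, 5, seed = 2)
  expect_true(all(tapply(foldid, d$patient_id, function(v) {
    length(unique(v))
  }) == 1))

  sp1 <- tune_model(model_spec("L1LR"), d,
    seed = 4, features = cols,
    grid = list(lambda = c(0.001, 0.01, 0.1))
  )
  sp2 <- tune_model(model_spec("L1LR"), d,
    seed = 4, features = cols,
    grid = list(lambda = c(0.001, 0.01, 0.1))
  )
  expect_identical(sp1$hyper, sp2$hyper) # same seed, same choice
  expect_true(sp1$hyper$lambda %in% c(0.001, 0.01, 0.1))

  single <- dplyr::filter(d, label == 1)
  expect_error(tune_model(model_spec("L1LR"), single, features = cols),
    class = "shockable_error"
  )
})

test_that("L1LR: heavy regularization zeroes every coefficient", {
  d <- make_planted_features(6, 6, n_noise = 4, seed = 5)
  cols <- planted_feature_cols(d)
  m <- fit_model(model_spec("L1LR", lambda = 50), d, features = cols)
  expect_true(all(abs(m$fit$w) == 0))
  # balanced classes push the intercept to (numerically) zero; an exact
  # zero-score tie is broken to +1 by convention
  expect_lt(abs(m$fit$w0), 1e-6)
  m$fit$w0 <- 0
  pr <- predict(m, d)
  expect_true(all(pr$pred == 1))

  # planted signal: informative feature dominates the attribution
  m2 <- fit_model(model_spec("L1LR", lambda = 0.02), d, features = cols)
  att <- setNames(m2$attribution, cols)
  expect_equal(names(which.max(att)), "inf1")
})

test_that("RF defaults to p = floor(sqrt(K)) and BAG(B=1) equals its tree", {
  d <- make_separated_features(6, 4, n_feat = 30, seed = 6)
  cols <- sprintf("f%02d", 1:30)
  m <- fit_model(model_spec("RF", n_trees = 20), d, features = cols)
  expect_equal(m$hyper$p, 5) # floor(sqrt(30))

  m1 <- fit_model(model_spec("BAG", n_trees = 1), d,
    seed = 9,
    features = cols
  )
  tree_pred <- shockable:::.cart_predict(
    m1$fit$trees[[1]], as.matrix(d[cols])
  )
  expect_equal(predict(m1, d)$pred, as.numeric(tree_pred))
})

test_that("BST attribution is nonnegative and flags the planted feature", {
  d <- make_planted_features(8, 6, n_noise = 6, effect = 2, seed = 7)
  cols <- planted_feature_cols(d)
  m <- fit_model(model_spec("BST", depth = 1, M = 25), d, features = cols)
  expect_true(all(m$attribution >= 0))
  att <- setNames(m$attribution, cols)
  expect_true(names(which.max(att)) %in% c("inf1", "inf2"))
})

test_that("SVM solves the dual: agreement with an independent QP solver", {
  skip_if_not_installed("quadprog")
  set.seed(3)
  n <- 25
  X <- rbind(
    matrix(rnorm(n * 2, 1.2), n, 2),
    matrix(rnorm(n * 2, -1.2), n, 2)
  )
  y <- rep(c(1, -1), each = n)
  gam <- 0.5
  C <- 2
  K <- exp(-gam * as.matrix(dist(X))^2)
  Q <- (y %*% t(y)) * K + diag(1e-8, 2 * n)
  qp <- quadprog::solve.QP(
    Q, rep(1, 2 * n),
    cbind(y, diag(2 * n), -diag(2 * n)),
    c(0, rep(0, 2 * n), rep(-C, 2 * n)),
    meq = 1
  )
  a_qp <- pmin(pmax(qp$solution, 0), C)
  sv <- shockable:::.svm_fit(X, y, C, gam, 1e-6, 200000)
  expect_lt(max(abs(a_qp - sv$alpha)), 1e-4)
  f_qp <- as.vector(K %*% (a_qp * y))
  free <- a_qp > 1e-6 & a_qp < C - 1e-6
  b_qp <- mean(y[free] - f_qp[free])
  dec <- shockable:::.svm_decision(X, y, sv$alpha, sv$b, gam, X)
  expect_lt(max(abs(f_qp + b_qp - dec)), 1e-4)
})

test_that("tuned SVM separates a separable two-feature fixture", {
  d <- make_separated_features(5, 4, n_feat = 2, gap = 5, seed = 8)
  sp <- tune_model(model_spec("SVM"), d,
    seed = 11, features = c("f01", "f02"),
    grid = list(C = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1))
  )
  m <- fit_model(sp, d, features = c("f01", "f02"))
  pr <- predict(m, d)
  expect_equal(mean(pr$pred == d$label), 1) # zero training error
})

test_that("prediction is total, order-equivariant and validates input", {
  d <- make_separated_features(5, 4, n_feat = 4, seed = 12)
  cols <- sprintf("f%02d", 1:4)
  m <- fit_model(model_spec("BST", depth = 1, M = 10), d, features = cols)
  pr <- predict(m, d)
  expect_true(all(pr$pred %in% c(-1, 1)))
  expect_equal(mean(pr$pred == d$label), 1) # separable fixture learned

  perm <- sample(nrow(d))
  expect_equal(predict(m, d[perm, ])$pred, pr$pred[perm])

  expect_error(predict(m, d[, c("f01", "label")]))
  d2 <- d
  d2$f01[1] <- NA
  expect_error(predict(m, d2), class = "shockable_error")
  expect_error(
    fit_model(model_spec("BST"), d2, features = cols),
    class = "shockable_error"
  )
})

test_that("all five algorithms clear the sanity ceiling on separated data", {
  d <- make_separated_features(12, 6, n_feat = 6, gap = 6, seed = 13)
  cols <- sprintf("f%02d", 1:6)
  sp <- patient_split(d, 0.8, seed = 14)
  for (alg in c("L1LR", "BAG", "RF", "BST", "SVM")) {
    m <- fit_model(model_spec(alg, n_trees = 60, M = 30), sp$train,
      seed = 15, features = cols
    )
    mm <- classification_metrics(
      sp$test$label,
      predict(m, sp$test)$pred
    )
    expect_gte(mm$se, 99)
    expect_gte(mm$sp, 99)
  }
})

test_that("models round-trip through the serialized container", {
  d <- make_separated_features(4, 4, n_feat = 3, seed = 16)
  cols <- sprintf("f%02d", 1:3)
  m <- fit_model(model_spec("L1LR", lambda = 0.01), d, features = cols)
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(m2$hyper, m$hyper)
  expect_equal(predict(m2, d), predict(m, d))
})

test_that("seed determinism: identical fits and predictions", {
  d <- make_planted_features(6, 5, n_noise = 5, seed = 17)
  cols <- planted_feature_cols(d)
  for (alg in c("RF", "BST", "SVM")) {
    m1 <- fit_model(model_spec(alg, n_trees = 15, M = 10), d,
      seed = 21, features = cols
    )
    m2 <- fit_model(model_spec(alg, n_trees = 15, M = 10), d,
      seed = 21, features = cols
    )
    expect_equal(predict(m1, d)$score, predict(m2, d)$score)
    expect_equal(m1$attribution, m2$attribution)
  }
})
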