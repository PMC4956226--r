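#' Classifier specifications
#'
#' The five classifier families used for shock/no-shock decisions:
#' `L1LR` (L1-regularized logistic regression, via glmnet), `BAG` (bagged
#' classification trees), `RF` (random forest: bagged trees with random
#' feature subsampling, `p = floor(sqrt(K))` by default), `BST`
#' (exponential-loss boosting of shallow trees with weighted vote
#' `sign(sum alpha_m f_m(x))`) and `SVM` (C-SVC with Gaussian kernel).
#' Hyperparameters not supplied are filled by [tune_model()] from the
#' documented grids, or by algorithm defaults at fit time.
#'
#' @param algorithm one of `"L1LR"`, `"BAG"`, `"RF"`, `"BST"`, `"SVM"`.
#' @param ... hyperparameters: `lambda` (L1LR); `n_trees`, `max_depth`,
#'   `min_node` (BAG/RF), `p` (RF feature subsample); `depth`, `M` (BST);
#'   `C`, `gamma` (SVM).
#' @return a `shock_spec` object.
#' @export
model_spec <- function(algorithm = c("L1LR", "BAG", "RF", "BST", "SVM"),
                       ...) {
  algorithm <- match.arg(algorithm)
  hyper <- list(...)
  bad <- vapply(hyper, function(v) is.numeric(v) && any(v <= 0), logical(1))
  if (any(bad)) {
    abort("hyperparameters must be positive", class = "shockable_error")
  }
  structure(list(algorithm = algorithm, hyper = hyper),
    class = "shock_spec"
  )
}

# documented tuning grids (package conventions, set a priori)
default_grid <- function(algorithm) {
  switch(algorithm,
    L1LR = list(lambda = 10^seq(-4, 1, length.out = 20)),
    SVM = list(
      C = 10^seq(-2, 3, length.out = 6),
      gamma = 10^seq(-3, 1, length.out = 5)
    ),
    BST = list(depth = c(1, 2, 3), M = c(100, 300, 500)),
    BAG = list(max_depth = c(2, 4, 8)),
    RF = list(max_depth = c(2, 4, 8))
  )
}

default_hyper <- function(algorithm, K) {
  switch(algorithm,
    L1LR = list(lambda = 0.01),
    SVM = list(C = 1, gamma = 1 / K),
    BST = list(depth = 2, M = 100),
    BAG = list(n_trees = 300, max_depth = 8, min_node = 5),
    RF = list(
      n_trees = 300, max_depth = 8, min_node = 5,
      p = floor(sqrt(K))
    )
  )
}

prep_xy <- function(data, features) {
  miss <- setdiff(features, names(data))
  if (length(miss)) {
    abort(paste("missing feature columns:", paste(miss, collapse = ", ")),
      class = "shockable_error"
    )
  }
  X <- as.matrix(data[features])
  if (!all(is.finite(X))) {
    abort("non-finite feature values", class = "shockable_error")
  }
  y <- data$label
  if (!all(y %in% c(-1, 1))) {
    abort("labels must be +1/-1", class = "shockable_error")
  }
  list(X = X, y = y)
}

#' Patient-grouped cross-validation folds
#'
#' Assigns whole patients to folds so no patient ever straddles a training
#' and a validation fold.
#'
#' @param patient_ids character vector (one per row).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id per row.
#' @export
patient_folds <- function(patient_ids, k = 10, seed = 1) {
  pats <- unique(patient_ids)
  k <- min(k, length(pats))
  set.seed(seed)
  shuffled <- sample(pats)
  fold_of <- setNames(rep_len(seq_len(k), length(pats)), shuffled)
  as.integer(fold_of[patient_ids])
}

#' Select hyperparameters for a classifier
#'
#' `L1LR`, `SVM` and `BST` are tuned by patient-grouped 10-fold
#' cross-validation, minimizing the balanced error rate of the pooled
#' out-of-fold predictions over the documented grid; `BAG` and `RF` tree
#' complexity is chosen by out-of-bag misclassification (BER). Ties go to
#' the first (most regularized) grid point. Deterministic given `seed`.
#'
#' @param spec a [model_spec()].
#' @param train training feature tibble with `patient_id`, `label` and the
#'   feature columns.
#' @param seed RNG seed.
#' @param features feature columns to use.
#' @param folds number of CV folds.
#' @param grid optional named list overriding the default grid.
#' @return the spec with `hyper` completed and a `tuning` element holding
#'   the grid results.
#' @export
tune_model <- function(spec, train, seed = 1,
                       features = intersect(feature_names(), names(train)),
                       folds = 10, grid = NULL) {
  stopifnot(inherits(spec, "shock_spec"))
  if (length(unique(train$label)) < 2) {
    abort("training data must contain both classes",
      class = "shockable_error"
    )
  }
  d <- prep_xy(train, features)
  grid <- grid %||% default_grid(spec$algorithm)
  algo <- spec$algorithm

  if (algo %in% c("BAG", "RF")) {
    res <- purrr::map_dfr(grid$max_depth, function(md) {
      set.seed(seed)
      hy <- utils::modifyList(
        default_hyper(algo, ncol(d$X)),
        c(spec$hyper, list(max_depth = md))
      )
      oob <- ensemble_oob(d$X, d$y, algo, hy)
      tibble(max_depth = md, ber = oob)
    })
    best <- res$max_depth[which.min(res$ber)]
    spec$hyper <- utils::modifyList(
      default_hyper(algo, ncol(d$X)),
      c(spec$hyper, list(max_depth = best))
    )
    spec$tuning <- res
    return(spec)
  }

  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  foldid <- patient_folds(train$patient_id, folds, seed)
  res <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    hy <- utils::modifyList(
      default_hyper(algo, ncol(d$X)),
      c(spec$hyper, as.list(combos[i, , drop = FALSE]))
    )
    pred <- rep(NA_real_, nrow(d$X))
    for (f in sort(unique(foldid))) {
      tr <- foldid != f
      if (length(unique(d$y[tr])) < 2) next
      set.seed(seed + f)
      fit <- fit_engine(algo, d$X[tr, , drop = FALSE], d$y[tr], hy)
      pred[!tr] <- sign_pos(
        predict_engine(fit, d$X[!tr, , drop = FALSE])
      )
    }
    ok <- !is.na(pred)
    m <- metric_values(d$y[ok], pred[ok])
    bind_cols(as_tibble(combos[i, , drop = FALSE]), tibble(ber = m["ber"]))
  })
  best <- as.list(combos[which.min(res$ber), , drop = FALSE])
  spec$hyper <- utils::modifyList(
    default_hyper(algo, ncol(d$X)),
    c(spec$hyper, best)
  )
  spec$tuning <- res
  spec
}

sign_pos <- function(score) ifelse(score >= 0, 1, -1) # ties to +1

#' Fit a classifier
#'
#' Fits the specified algorithm and returns a `shock_model` carrying the
#' decision function, the per-feature attribution vector (`|w_k|` for
#' L1LR, accumulated impurity improvement for the tree ensembles, mean
#' absolute decision-function gradient for the SVM) and the training
#' metadata. Deterministic given `seed`.
#'
#' @inheritParams tune_model
#' @return a `shock_model`.
#' @export
fit_model <- function(spec, train, seed = 1,
                      features = intersect(feature_names(), names(train))) {
  stopifnot(inherits(spec, "shock_spec"))
  d <- prep_xy(train, features)
  hy <- utils::modifyList(
    default_hyper(spec$algorithm, ncol(d$X)),
    spec$hyper
  )
  set.seed(seed)
  fit <- fit_engine(spec$algorithm, d$X, d$y, hy)
  structure(
    list(
      algorithm = spec$algorithm, hyper = hy, features = features,
      fit = fit, attribution = attribution_engine(fit, d),
      seed = seed, n_train = nrow(d$X)
    ),
    class = "shock_model"
  )
}

#' @rdname fit_model
#' @param object a `shock_model`.
#' @param newdata feature tibble (or matrix with named columns).
#' @param ... unused.
#' @return tibble with decision `score` and `pred` (+1/-1; ties to +1).
#' @export
predict.shock_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  if (!all(is.finite(X))) {
    abort("non-finite feature values", class = "shockable_error")
  }
  score <- predict_engine(object$fit, X)
  tibble(score = as.numeric(score), pred = sign_pos(score))
}

# ---- algorithm engines --------------------------------------------------

fit_engine <- function(algorithm, X, y, hy) {
  switch(algorithm,
    L1LR = fit_l1lr(X, y, hy),
    BAG = fit_bagged(X, y, hy, mtry = ncol(X)),
    RF = fit_bagged(X, y, hy, mtry = hy$p),
    BST = fit_boost(X, y, hy),
    SVM = fit_svm(X, y, hy)
  )
}

fit_l1lr <- function(X, y, hy) {
  one <- ncol(X) == 1
  if (one) X <- cbind(X, `.dummy` = 0) # glmnet needs >= 2 columns
  lambda_path <- sort(unique(c(10^seq(-4, 1, length.out = 20), hy$lambda)),
    decreasing = TRUE
  )
  fit <- glmnet::glmnet(X, (y + 1) / 2,
    family = "binomial", alpha = 1,
    lambda = lambda_path, standardize = FALSE
  )
  co <- as.numeric(stats::coef(fit, s = hy$lambda, exact = FALSE))
  w <- co[-1]
  if (one) w <- w[1]
  list(type = "L1LR", w0 = co[1], w = w)
}

fit_bagged <- function(X, y, hy, mtry) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- vector("list", hy$n_trees)
  inbag <- vector("list", hy$n_trees)
  for (b in seq_len(hy$n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- .cart_fit(
      X[idx, , drop = FALSE], as.integer(y[idx]),
      w[idx] * n / n, hy$max_depth, hy$min_node, mtry
    )
    inbag[[b]] <- idx
  }
  list(type = "BAG", trees = trees, inbag = inbag, n = n)
}

# out-of-bag BER for bagged/random-forest ensembles (tuning criterion)
ensemble_oob <- function(X, y, algorithm, hy) {
  mtry <- if (algorithm == "RF") hy$p else ncol(X)
  fit <- fit_bagged(X, y, hy, mtry)
  n <- nrow(X)
  votes <- numeric(n)
  nvotes <- integer(n)
  for (b in seq_along(fit$trees)) {
    oob <- setdiff(seq_len(n), unique(fit$inbag[[b]]))
    if (!length(oob)) next
    p <- .cart_predict(fit$trees[[b]], X[oob, , drop = FALSE])
    votes[oob] <- votes[oob] + p
    nvotes[oob] <- nvotes[oob] + 1L
  }
  ok <- nvotes > 0
  m <- metric_values(y[ok], sign_pos(votes[ok]))
  unname(m["ber"])
}

fit_boost <- function(X, y, hy) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(hy$M)) {
    tr <- .cart_fit(X, as.integer(y), w, hy$depth, 1L, ncol(X))
    pred <- .cart_predict(tr, X)
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    if (err < 1e-10) {
      trees[[length(trees) + 1]] <- tr
      alphas <- c(alphas, 10) # perfect weak learner dominates the vote
      break
    }
    a <- 0.5 * log((1 - err) / err)
    trees[[length(trees) + 1]] <- tr
    alphas <- c(alphas, a)
    w <- w * exp(-a * y * pred)
    w <- w / sum(w)
  }
  list(type = "BST", trees = trees, alphas = alphas)
}

fit_svm <- function(X, y, hy) {
  sv <- .svm_fit(X, as.numeric(y), hy$C, hy$gamma,
    eps = 1e-3,
    max_iter = max(200000L, 100L * nrow(X))
  )
  list(
    type = "SVM", X = X, y = as.numeric(y), alpha = sv$alpha, b = sv$b,
    gamma = hy$gamma
  )
}

predict_engine <- function(fit, X) {
  switch(fit$type,
    L1LR = drop(fit$w0 + X %*% fit$w),
    BAG = {
      s <- numeric(nrow(X))
      for (tr in fit$trees) s <- s + .cart_predict(tr, X)
      s / length(fit$trees)
    },
    BST = {
      s <- numeric(nrow(X))
      for (i in seq_along(fit$trees)) {
        s <- s + fit$alphas[i] * .cart_predict(fit$trees[[i]], X)
      }
      s
    },
    SVM = .svm_decision(fit$X, fit$y, fit$alpha, fit$b, fit$gamma, X)
  )
}

attribution_engine <- function(fit, d) {
  K <- ncol(d$X)
  out <- switch(fit$type,
    L1LR = abs(fit$w),
    BAG = {
      imp <- numeric(K)
      for (tr in fit$trees) imp <- imp + tr$importance
      imp
    },
    BST = {
      imp <- numeric(K)
      for (i in seq_along(fit$trees)) {
        imp <- imp + fit$alphas[i] * fit$trees[[i]]$importance
      }
      imp
    },
    SVM = svm_gradient_attribution(fit, d$X)
  )
  if (sum(out) > 0) out <- out / sum(out) * K
  unname(out)
}

# mean |d f / d x_k| of the RBF decision function over the training points
svm_gradient_attribution <- function(fit, X) {
  act <- fit$alpha > 0
  if (!any(act)) return(numeric(ncol(X)))
  Xs <- fit$X[act, , drop = FALSE]
  ay <- fit$alpha[act] * fit$y[act]
  n <- nrow(X)
  grad <- matrix(0, n, ncol(X))
  for (j in seq_len(nrow(Xs))) {
    diff <- sweep(X, 2, Xs[j, ])
    kern <- exp(-fit$gamma * rowSums(diff^2))
    grad <- grad + (-2 * fit$gamma * ay[j]) * diff * kern
  }
  colMeans(abs(grad))
}

#' Save and load fitted models
#'
#' Serialized container with the algorithm, hyperparameters, seed and
#' feature names alongside the decision function.
#'
#' @param model a `shock_model`.
#' @param path file path.
#' @return `load_model()` returns the `shock_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "shock_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "shock_model"))
  m
}

#' @export
print.shock_model <- function(x, ...) {
  cat(
    "<shock_model>", x$algorithm, "| features:", length(x$features),
    "| n_train:", x$n_train, "\n"
  )
  hp <- x$hyper[vapply(x$hyper, is.numeric, logical(1))]
  cat(
    "hyper:",
    paste(names(hp), signif(unlist(hp), 3), sep = "=", collapse = ", "),
    "\n"
  )
  invisible(x)
}
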