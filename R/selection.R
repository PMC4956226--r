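#' Bootstrap-embedded recursive feature elimination
#'
#' For each of `B` patient-wise bootstrap resamples of the training set
#' (patients drawn with replacement; out-of-bag patients kept aside), the
#' ranking model -- boosting importance for `BSTsel`, `|w_k|` of the
#' L1-regularized logistic regression for `L1LRsel` -- is fitted on the
#' in-bag segments, the least important feature is eliminated, and the
#' model is refitted, down to a single feature. At every subset size the
#' BER on the out-of-bag patients' segments is recorded. Resamples whose
#' in-bag or out-of-bag part misses a class are redrawn (counted in
#' `n_redraws`). Hyperparameters are reused across resamples (globally
#' tuned or supplied), not retuned per resample.
#'
#' @param train feature tibble with `patient_id`, `label`, feature columns.
#' @param method `"BSTsel"` or `"L1LRsel"`.
#' @param B number of bootstrap resamples (study default 500).
#' @param seed RNG seed.
#' @param features feature columns to start from.
#' @param hyper hyperparameters for the ranking model (defaults:
#'   `depth = 2`, `M = 100` for BSTsel; `lambda = 0.01` for L1LRsel).
#' @return a `shock_rfe`: per-resample BER curves (`curves`), elimination
#'   orders (`elim`, earliest eliminated first), and bookkeeping.
#' @export
rfe_bootstrap <- function(train, method = c("BSTsel", "L1LRsel"), B = 500,
                          seed = 1,
                          features = intersect(
                            feature_names(), names(train)
                          ),
                          hyper = list()) {
  method <- match.arg(method)
  if (length(unique(train$label)) < 2) {
    abort("training data must contain both classes",
      class = "shockable_error"
    )
  }
  pats <- unique(train$patient_id)
  if (length(pats) < 2) {
    abort("need at least 2 training patients", class = "shockable_error")
  }
  hy <- utils::modifyList(
    if (method == "BSTsel") list(depth = 2, M = 100) else list(lambda = 0.01),
    hyper
  )
  d <- prep_xy(train, features)
  by_pat <- split(seq_len(nrow(train)), train$patient_id)
  K <- length(features)
  set.seed(seed)
  curves <- vector("list", B)
  elim <- vector("list", B)
  n_redraws <- 0L
  for (b in seq_len(B)) {
    tries <- 0L
    repeat {
      draw <- sample(pats, length(pats), replace = TRUE)
      inbag <- unlist(by_pat[draw], use.names = FALSE)
      oob <- unlist(by_pat[setdiff(pats, unique(draw))], use.names = FALSE)
      ok <- length(oob) > 0 &&
        length(unique(d$y[inbag])) == 2 &&
        length(unique(d$y[oob])) == 2
      if (ok) break
      n_redraws <- n_redraws + 1L
      tries <- tries + 1L
      if (tries > 500L) {
        abort(
          "could not draw a two-class bootstrap resample (too few patients per class)",
          class = "shockable_error"
        )
      }
    }
    active <- seq_len(K)
    order_out <- integer(0)
    bers <- numeric(K)
    for (k in K:1) {
      fit <- rank_fit(
        method, d$X[inbag, active, drop = FALSE],
        d$y[inbag], hy
      )
      pred <- sign_pos(
        predict_engine(fit, d$X[oob, active, drop = FALSE])
      )
      bers[k] <- unname(metric_values(d$y[oob], pred)["ber"])
      att <- rank_attribution(fit)
      drop_i <- which.min(att)
      order_out <- c(order_out, active[drop_i])
      active <- active[-drop_i]
    }
    curves[[b]] <- tibble(resample = b, k = seq_len(K), ber = bers)
    elim[[b]] <- features[order_out] # eliminated first -> last
  }
  structure(
    list(
      method = method, B = B, seed = seed, features = features,
      curves = bind_rows(curves), elim = elim, n_redraws = n_redraws,
      hyper = hy
    ),
    class = "shock_rfe"
  )
}

rank_fit <- function(method, X, y, hy) {
  if (method == "BSTsel") {
    fit_boost(X, y, list(depth = hy$depth, M = hy$M))
  } else {
    fit_l1lr(X, y, list(lambda = hy$lambda))
  }
}

rank_attribution <- function(fit) {
  if (fit$type == "BST") {
    imp <- numeric(length(fit$trees[[1]]$importance))
    for (i in seq_along(fit$trees)) {
      imp <- imp + fit$alphas[i] * fit$trees[[i]]$importance
    }
    imp
  } else {
    abs(fit$w)
  }
}

#' Choose the subset size by the one-standard-error rule
#'
#' Over the bootstrap BER curves, let `k_min` be the size with the lowest
#' mean BER and `band` the spread of the B out-of-bag BER values at
#' `k_min` (their SD by default, matching bootstrap error bars; the
#' SD/sqrt(B) variant sits behind `band`). The chosen size `K_s` is the
#' smallest `k` whose mean BER is within `band` of the minimum. The final
#' subset is the `K_s` features most often selected (i.e. surviving to
#' size `K_s`) across resamples; ties break by mean elimination step, then
#' name.
#'
#' @param rfe a `shock_rfe`.
#' @param band `"sd"` (default) or `"se"` (SD divided by sqrt(B)).
#' @return a `shock_selection`: `curve` (per-k mean/SD/SE), `k_min`,
#'   `threshold`, `K_s`, `counts` (per-feature selection counts) and
#'   `subset` (ordered, length `K_s`).
#' @export
one_se_subset <- function(rfe, band = c("sd", "se")) {
  band <- match.arg(band)
  stopifnot(inherits(rfe, "shock_rfe"))
  curve <- rfe$curves |>
    group_by(.data$k) |>
    summarise(
      mean_ber = mean(.data$ber, na.rm = TRUE),
      sd_ber = sd(.data$ber, na.rm = TRUE),
      se_ber = sd(.data$ber, na.rm = TRUE) / sqrt(sum(!is.na(.data$ber))),
      .groups = "drop"
    )
  k_min <- curve$k[which.min(curve$mean_ber)]
  bandw <- if (band == "sd") {
    curve$sd_ber[curve$k == k_min]
  } else {
    curve$se_ber[curve$k == k_min]
  }
  threshold <- min(curve$mean_ber) + bandw
  K_s <- min(curve$k[curve$mean_ber <= threshold])
  K <- length(rfe$features)
  # survival to size K_s = among the last K_s eliminated
  counts <- setNames(integer(K), rfe$features)
  steps <- setNames(numeric(K), rfe$features)
  for (ord in rfe$elim) {
    surv <- tail(ord, K_s)
    counts[surv] <- counts[surv] + 1L
    steps[ord] <- steps[ord] + seq_len(K)
  }
  counts_tbl <- tibble(
    feature = rfe$features,
    count = as.integer(counts[rfe$features]),
    mean_step = steps[rfe$features] / length(rfe$elim)
  ) |>
    arrange(
      desc(.data$count), desc(.data$mean_step), .data$feature
    )
  structure(
    list(
      method = rfe$method, curve = curve, k_min = k_min, band = band,
      band_value = bandw, threshold = threshold, K_s = K_s,
      counts = counts_tbl, subset = counts_tbl$feature[seq_len(K_s)],
      B = rfe$B
    ),
    class = "shock_selection"
  )
}

#' @export
print.shock_selection <- function(x, ...) {
  cat(
    "<shock_selection>", x$method, "| K_s =", x$K_s,
    sprintf(
      "(min BER %.2f at k = %d, threshold %.2f)\n",
      min(x$curve$mean_ber), x$k_min, x$threshold
    )
  )
  cat("subset:", paste(x$subset, collapse = ", "), "\n")
  invisible(x)
}

#' Compare a feature subset against the full feature set
#'
#' Refits the classifier on the subset columns and on all features (same
#' seed), and runs the paired patient-wise bootstrap comparison of the BER
#' on the shared test resamples. The reported `delta` is BER(all) -
#' BER(subset): negative values mean the subset *increased* the error.
#'
#' @param train,test feature tibbles.
#' @param subset character vector of selected feature names.
#' @param spec a [model_spec()] (tuned hyperparameters reused for both
#'   fits).
#' @param B bootstrap resamples for the comparison.
#' @param seed RNG seed.
#' @param features the full feature set to compare against.
#' @return list: `metrics_subset`, `metrics_all` (test-set metric rows),
#'   `comparison` (`shock_comparison` on the BER), `cost_subset`,
#'   `cost_all` (relative feature-computation costs).
#' @export
evaluate_subset <- function(train, test, subset, spec, B = 500, seed = 1,
                            features = intersect(
                              feature_names(), names(train)
                            )) {
  if (!length(subset)) abort("empty subset", class = "shockable_error")
  if (!all(subset %in% features)) {
    abort("subset must be drawn from the feature set",
      class = "shockable_error"
    )
  }
  m_all <- fit_model(spec, train, seed = seed, features = features)
  m_sub <- fit_model(spec, train, seed = seed, features = subset)
  pred_all <- bind_cols(
    test[c("patient_id", "label")],
    predict(m_all, test)
  )
  pred_sub <- bind_cols(
    test[c("patient_id", "label")],
    predict(m_sub, test)
  )
  cmp <- paired_compare(pred_all, pred_sub, B = B, seed = seed,
    metric = "ber"
  )
  list(
    metrics_subset = classification_metrics(pred_sub$label, pred_sub$pred),
    metrics_all = classification_metrics(pred_all$label, pred_all$pred),
    comparison = cmp,
    cost_subset = feature_cost(subset, strict = FALSE),
    cost_all = feature_cost(features, strict = FALSE),
    model_subset = m_sub, model_all = m_all
  )
}
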