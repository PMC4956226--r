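#' Single-feature maximum-likelihood threshold classifier
#'
#' Estimates the class-conditional densities of one feature (Gaussian
#' kernel, Silverman bandwidth per class) on a common 2000-point grid
#' between the pooled 0.1st and 99.9th percentiles, and places the decision
#' threshold where the two densities cross, f(x|Sh) = f(x|NSh). With
#' several crossings, the one maximizing training Se + Sp is kept. The
#' polarity records which side of the threshold is called shockable, chosen
#' so that Se and Sp are at least 50% when achievable.
#'
#' @param sh feature values of the shockable class (training).
#' @param nsh feature values of the non-shockable class (training).
#' @return a `shock_threshold` object: `threshold`, `polarity` (+1: values
#'   above the threshold are shockable), and training `se`, `sp`, `ber`
#'   (percent).
#' @examples
#' thr <- ml_threshold(rnorm(200, 1), rnorm(200, -1))
#' @export
ml_threshold <- function(sh, nsh) {
  if (!length(sh) || !length(nsh)) {
    abort("both classes need observations", class = "shockable_error")
  }
  pooled <- c(sh, nsh)
  if (length(unique(pooled)) == 1) {
    abort("identical constant samples: densities never cross",
      class = "shockable_nocrossing"
    )
  }
  lo <- quantile(pooled, 0.001, names = FALSE)
  hi <- quantile(pooled, 0.999, names = FALSE)
  if (lo == hi) {
    lo <- min(pooled)
    hi <- max(pooled)
  }
  ngrid <- 2000L
  dsh <- kde_on_grid(sh, lo, hi, ngrid)
  dnsh <- kde_on_grid(nsh, lo, hi, ngrid)
  dd <- dsh$y - dnsh$y
  flip <- which(dd[-1] * dd[-ngrid] < 0 | dd[-ngrid] == 0)
  if (!length(flip)) {
    abort("class-conditional densities do not cross on the grid",
      class = "shockable_nocrossing"
    )
  }
  cand <- (dsh$x[flip] + dsh$x[flip + 1]) / 2
  best <- NULL
  for (thr in cand) {
    for (pol in c(1, -1)) {
      se <- mean(pol * (sh - thr) > 0) * 100
      sp <- mean(pol * (nsh - thr) <= 0) * 100
      if (is.null(best) || se + sp > best$se + best$sp) {
        best <- list(threshold = thr, polarity = pol, se = se, sp = sp)
      }
    }
  }
  structure(
    list(
      threshold = best$threshold, polarity = best$polarity,
      se = best$se, sp = best$sp, ber = 100 - (best$se + best$sp) / 2
    ),
    class = "shock_threshold"
  )
}

kde_on_grid <- function(v, lo, hi, n) {
  bw <- stats::bw.nrd0(v)
  if (!is.finite(bw) || bw <= 0) bw <- max((hi - lo) / 1000, 1e-9)
  stats::density(v, bw = bw, from = lo, to = hi, n = n)
}

#' @rdname ml_threshold
#' @param object a `shock_threshold`.
#' @param newdata numeric feature values to classify.
#' @param ... unused.
#' @return `predict()`: labels +1/-1 (threshold itself goes to -1 for
#'   polarity +1: only values strictly beyond the threshold are shockable).
#' @export
predict.shock_threshold <- function(object, newdata, ...) {
  ifelse(object$polarity * (newdata - object$threshold) > 0, 1, -1)
}

#' Single-feature performance table
#'
#' Fits [ml_threshold()] per feature on the training rows and reports
#' held-out Se/Sp/BER on the test rows, ranked by BER -- the layout used to
#' compare individual features across datasets.
#'
#' @param train,test feature tibbles with `label` and feature columns.
#' @param features feature columns to assess.
#' @return tibble: `feature`, `se`, `sp`, `ber` (percent, held-out),
#'   `threshold`, `polarity`.
#' @export
single_feature_performance <- function(train, test,
                                       features = intersect(
                                         feature_names(), names(train)
                                       )) {
  purrr::map_dfr(features, function(f) {
    thr <- tryCatch(
      ml_threshold(
        train[[f]][train$label == 1],
        train[[f]][train$label == -1]
      ),
      shockable_nocrossing = function(e) NULL
    )
    if (is.null(thr)) {
      return(tibble(
        feature = f, se = NA_real_, sp = NA_real_, ber = NA_real_,
        threshold = NA_real_, polarity = NA_real_
      ))
    }
    pred <- predict(thr, test[[f]])
    m <- metric_values(test$label, pred)
    tibble(
      feature = f, se = m[["se"]], sp = m[["sp"]], ber = m[["ber"]],
      threshold = thr$threshold, polarity = thr$polarity
    )
  }) |>
    arrange(.data$ber)
}
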