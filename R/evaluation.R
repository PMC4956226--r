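#' Sensitivity, specificity and balanced error rate
#'
#' Se is the fraction of shockable (+1) segments predicted shockable, Sp
#' the fraction of non-shockable (-1) predicted non-shockable, and
#' `BER = 100 - (Se + Sp) / 2` (all in percent). When a class is absent its
#' metric -- and therefore the BER -- is undefined and returned as `NA`
#' with a warning.
#'
#' @param truth true labels (+1/-1).
#' @param estimate predicted labels (+1/-1).
#' @return one-row tibble with `se`, `sp`, `ber` in percent.
#' @examples
#' classification_metrics(c(1, 1, -1, -1), c(1, -1, -1, -1))
#' @export
classification_metrics <- function(truth, estimate) {
  m <- metric_values(truth, estimate, warn_missing = TRUE)
  tibble(se = m[["se"]], sp = m[["sp"]], ber = m[["ber"]])
}

metric_values <- function(truth, estimate, warn_missing = FALSE) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate lengths differ", class = "shockable_error")
  }
  pos <- truth == 1
  neg <- truth == -1
  se <- if (any(pos)) mean(estimate[pos] == 1) * 100 else NA_real_
  sp <- if (any(neg)) mean(estimate[neg] == -1) * 100 else NA_real_
  if (warn_missing && (is.na(se) || is.na(sp))) {
    warn("a class is absent; its metric and the BER are undefined")
  }
  c(se = se, sp = sp, ber = 100 - (se + sp) / 2)
}

#' Split a segment dataset by patient
#'
#' Patients (not segments) are allocated at random to the training and
#' test sides, so all segments of a patient land on one side.
#'
#' @param data tibble with a `patient_id` column.
#' @param prop fraction of patients allocated to training (default 0.8).
#' @param seed RNG seed.
#' @return list with `train` and `test` tibbles.
#' @export
patient_split <- function(data, prop = 0.8, seed = 1) {
  if (!nrow(data)) abort("empty dataset", class = "shockable_error")
  pats <- unique(data$patient_id)
  if ("label" %in% names(data)) {
    per_class <- data |>
      distinct(.data$patient_id, .data$label) |>
      count(.data$label)
    if (any(per_class$n < 2)) {
      warn("fewer than 2 patients in a class; the split may be degenerate")
    }
  }
  set.seed(seed)
  n_train <- max(1L, min(round(prop * length(pats)), length(pats) - 1L))
  tr <- sample(pats, n_train)
  list(
    train = filter(data, .data$patient_id %in% tr),
    test = filter(data, !.data$patient_id %in% tr)
  )
}

# B patient resamples (with replacement) drawn from one master seed, so
# paired comparisons can share draws by construction
bootstrap_resamples <- function(patients, B, seed) {
  set.seed(seed)
  n <- length(patients)
  lapply(seq_len(B), function(b) patients[sample.int(n, n, replace = TRUE)])
}

#' Patient-wise bootstrap distribution of the performance metrics
#'
#' Each of the `B` resamples draws N patients with replacement from the N
#' evaluated patients (so on average `1 - (1 - 1/N)^N`, about 2/3, of the
#' patients appear); a duplicated patient contributes its segments as many
#' times as drawn. Resamples missing a class yield undefined metrics,
#' recorded as `NA` and excluded from the summaries (with a note in the
#' result).
#'
#' @param predictions tibble with `patient_id`, `label` (+1/-1) and `pred`
#'   (+1/-1) -- e.g. test-set predictions of a fitted model.
#' @param B number of bootstrap resamples (study default 500).
#' @param seed RNG seed (one master seed; paired analyses reuse it to share
#'   patient draws).
#' @return a `shock_boot` object: per-resample metrics, resample patient
#'   lists, and mean/SD/percentile-CI summaries.
#' @export
bootstrap_metrics <- function(predictions, B = 500, seed = 1) {
  req <- c("patient_id", "label", "pred")
  if (!all(req %in% names(predictions))) {
    abort("predictions need patient_id, label, pred",
      class = "shockable_error"
    )
  }
  pats <- unique(predictions$patient_id)
  if (length(pats) < 2) {
    warn("fewer than 2 test patients; the bootstrap is degenerate")
  }
  resamples <- bootstrap_resamples(pats, B, seed)
  by_pat <- split(predictions, predictions$patient_id)
  per <- purrr::map_dfr(seq_len(B), function(b) {
    d <- bind_rows(by_pat[resamples[[b]]])
    m <- metric_values(d$label, d$pred)
    tibble(resample = b, se = m[["se"]], sp = m[["sp"]], ber = m[["ber"]])
  })
  n_missing <- sum(is.na(per$ber))
  structure(
    list(
      metrics = per, resamples = resamples, B = B, seed = seed,
      n_missing = n_missing,
      summary = summarise_boot(per)
    ),
    class = "shock_boot"
  )
}

summarise_boot <- function(per) {
  per |>
    tidyr::pivot_longer(c("se", "sp", "ber"),
      names_to = "metric",
      values_to = "value"
    ) |>
    group_by(.data$metric) |>
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      ci_lo = quantile(.data$value, 0.025, na.rm = TRUE, names = FALSE),
      ci_hi = quantile(.data$value, 0.975, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
}

#' Paired bootstrap comparison of two prediction sets
#'
#' Both models are evaluated on identical patient resamples (shared draws
#' from the same master seed); the per-resample metric difference
#' `delta = metric_a - metric_b` is summarized by its percentile 95% CI,
#' and the difference is declared significant exactly when the CI excludes
#' zero.
#'
#' @param pred_a,pred_b prediction tibbles (`patient_id`, `label`, `pred`)
#'   over the same test patients.
#' @param B number of resamples.
#' @param seed master seed (shared by both sides).
#' @param metric which metric to compare: `"ber"`, `"se"` or `"sp"`.
#' @return a `shock_comparison`: per-resample deltas, 95% percentile CI,
#'   and `significant`.
#' @export
paired_compare <- function(pred_a, pred_b, B = 500, seed = 1,
                           metric = c("ber", "se", "sp")) {
  metric <- match.arg(metric)
  pa <- sort(unique(pred_a$patient_id))
  pb <- sort(unique(pred_b$patient_id))
  if (!identical(pa, pb)) {
    abort("both prediction sets must cover the same patients",
      class = "shockable_error"
    )
  }
  ba <- bootstrap_metrics(pred_a, B, seed)
  bb <- bootstrap_metrics(pred_b, B, seed)
  delta <- ba$metrics[[metric]] - bb$metrics[[metric]]
  ci <- quantile(delta, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(
    list(
      metric = metric, delta = delta, ci = ci,
      significant = !(ci[1] <= 0 && ci[2] >= 0),
      mean = mean(delta, na.rm = TRUE),
      boot_a = ba, boot_b = bb, B = B, seed = seed
    ),
    class = "shock_comparison"
  )
}

#' @export
print.shock_boot <- function(x, ...) {
  cat("<shock_boot> B =", x$B, "resamples\n")
  print(x$summary)
  if (x$n_missing > 0) {
    cat(x$n_missing, "resample(s) had a missing class (excluded)\n")
  }
  invisible(x)
}

#' @export
print.shock_comparison <- function(x, ...) {
  cat(
    sprintf(
      "<shock_comparison> delta %s: mean %.2f, 95%% CI [%.2f, %.2f] -> %s\n",
      x$metric, x$mean, x$ci[1], x$ci[2],
      if (x$significant) "significant" else "not significant"
    )
  )
  invisible(x)
}

#' Write bootstrap results to disk
#'
#' Per-resample metric table as CSV plus a JSON summary (mean, SD, CI).
#'
#' @param boot a `shock_boot`.
#' @param stem output path stem (writes `<stem>.csv` and `<stem>.json`).
#' @export
write_bootstrap_results <- function(boot, stem) {
  readr::write_csv(boot$metrics, paste0(stem, ".csv"))
  jsonlite::write_json(
    list(B = boot$B, seed = boot$seed, summary = boot$summary),
    paste0(stem, ".json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}
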