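# Metrics, patient split, patient-wise bootstrap, paired comparison.

test_that("Se/Sp/BER arithmetic is exact", {
  m <- classification_metrics(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_equal(unlist(m), c(se = 100, sp = 100, ber = 0))

  m2 <- classification_metrics(c(1, 1, -1, -1), c(1, 1, 1, 1))
  expect_equal(unlist(m2), c(se = 100, sp = 0, ber = 50))

  expect_warning(
    m3 <- classification_metrics(c(1, 1), c(1, -1)),
    "absent"
  )
  expect_true(is.na(m3$sp) && is.na(m3$ber))
  expect_error(classification_metrics(c(1, -1), c(1)),
    class = "shockable_error"
  )
})

test_that("patient split is by whole patients, 80/20, seed-stable", {
  d <- make_planted_features(5, 4, n_noise = 2, seed = 41) # 10 patients
  sp <- patient_split(d, 0.8, seed = 42)
  expect_equal(length(unique(sp$train$patient_id)), 8)
  expect_equal(length(unique(sp$test$patient_id)), 2)
  expect_length(
    intersect(sp$train$patient_id, sp$test$patient_id), 0
  )
  sp2 <- patient_split(d, 0.8, seed = 42)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)
  expect_error(patient_split(d[0, ]), class = "shockable_error")
})

test_that("bootstrap draws patients with replacement and keeps identities", {
  pred <- make_predictions(60, 55, 90, 80, n_patients = 10)
  bt <- bootstrap_metrics(pred, B = 50, seed = 43)
  expect_equal(nrow(bt$metrics), 50)
  # BER identity exact on every resample
  expect_equal(bt$metrics$ber,
    100 - (bt$metrics$se + bt$metrics$sp) / 2,
    tolerance = 1e-12
  )
  expect_true(all(lengths(bt$resamples) == 10))

  # single-patient set: all resamples identical, SD zero
  one <- dplyr::filter(pred, patient_id == "p01")
  expect_warning(bt1 <- bootstrap_metrics(one, B = 20, seed = 44), "fewer")
  expect_equal(sd(bt1$metrics$ber), 0)
})

test_that("bootstrap mean tracks the whole-test-set estimate", {
  set.seed(45)
  # 50 patients, segment-level predictions with per-patient error rates
  rows <- purrr::map_dfr(seq_len(50), function(p) {
    n <- sample(6:14, 1)
    lab <- sample(c(1, -1), n, replace = TRUE)
    err <- stats::rbinom(n, 1, runif(1, 0, 0.25))
    tibble::tibble(
      patient_id = sprintf("p%02d", p), label = lab,
      pred = ifelse(err == 1, -lab, lab)
    )
  })
  full_se <- classification_metrics(rows$label, rows$pred)$se
  bt <- bootstrap_metrics(rows, B = 400, seed = 46)
  mc_se <- sd(bt$metrics$se, na.rm = TRUE) / sqrt(sum(!is.na(bt$metrics$se)))
  expect_lt(
    abs(mean(bt$metrics$se, na.rm = TRUE) - full_se),
    3 * mc_se + 0.5
  )
})

test_that("resamples missing a class are recorded NA and excluded", {
  pred <- dplyr::bind_rows(
    tibble::tibble(patient_id = "a", label = 1, pred = 1),
    tibble::tibble(
      patient_id = c("b", "c", "d"), label = -1,
      pred = c(-1, -1, 1)
    )
  )
  bt <- bootstrap_metrics(pred, B = 200, seed = 47)
  expect_gt(bt$n_missing, 0) # some draws exclude patient "a"
  expect_true(all(is.finite(bt$summary$mean)))
})

test_that("paired comparison: self-delta is zero, antisymmetry exact", {
  pred <- make_predictions(40, 36, 60, 51, n_patients = 8)
  cmp <- paired_compare(pred, pred, B = 60, seed = 48)
  expect_true(all(cmp$delta == 0))
  expect_equal(cmp$ci, c(0, 0))
  expect_false(cmp$significant)

  predb <- pred
  predb$pred[predb$label == 1][1:6] <- -1 # degrade model b
  ab <- paired_compare(pred, predb, B = 60, seed = 48)
  ba <- paired_compare(predb, pred, B = 60, seed = 48)
  expect_equal(ab$delta, -ba$delta)

  predc <- pred
  predc$patient_id <- rev(predc$patient_id)
  expect_error(
    paired_compare(pred, dplyr::filter(predc, patient_id != "p01"),
      B = 10, seed = 1
    ),
    class = "shockable_error"
  )
})

test_that("a planted performance gap is declared significant", {
  set.seed(49)
  lab <- rep(c(1, -1), each = 200)
  pats <- rep_len(sprintf("p%02d", 1:20), 400)
  good <- tibble::tibble(
    patient_id = pats, label = lab,
    pred = ifelse(stats::rbinom(400, 1, 0.02) == 1, -lab, lab)
  )
  bad <- tibble::tibble(
    patient_id = pats, label = lab,
    pred = ifelse(stats::rbinom(400, 1, 0.30) == 1, -lab, lab)
  )
  cmp <- paired_compare(good, bad, B = 200, seed = 50)
  expect_true(cmp$significant)
  expect_lt(cmp$ci[2], 0) # BER(good) - BER(bad) < 0 throughout
})

test_that("bootstrap results serialize to CSV + JSON", {
  pred <- make_predictions(30, 28, 30, 27, n_patients = 6)
  bt <- bootstrap_metrics(pred, B = 25, seed = 51)
  stem <- file.path(withr::local_tempdir(), "boot")
  write_bootstrap_results(bt, stem)
  expect_true(file.exists(paste0(stem, ".csv")))
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$B, 25)
})
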