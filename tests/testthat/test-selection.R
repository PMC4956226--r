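# Bootstrap RFE, one-standard-error rule, subset evaluation.

fake_rfe <- function(mean_ber, sd_at = 0.15, B = 2, features = NULL) {
  K <- length(mean_ber)
  if (is.null(features)) features <- sprintf("f%d", seq_len(K))
  d <- sd_at / sqrt(2) # two symmetric resamples -> sample SD = sd_at
  curves <- dplyr::bind_rows(
    tibble::tibble(resample = 1, k = seq_len(K), ber = mean_ber - d),
    tibble::tibble(resample = 2, k = seq_len(K), ber = mean_ber + d)
  )
  structure(
    list(
      method = "BSTsel", B = 2, seed = 1, features = features,
      curves = curves, elim = list(features, features), n_redraws = 0
    ),
    class = "shock_rfe"
  )
}

test_that("one-SE rule: worked example and degenerate curve", {
  sel <- one_se_subset(fake_rfe(c(5, 3, 2, 1.9, 1.95)))
  expect_equal(sel$k_min, 4)
  expect_equal(sel$band_value, 0.15, tolerance = 1e-12)
  expect_equal(sel$threshold, 2.05, tolerance = 1e-12)
  expect_equal(sel$K_s, 3) # smallest k with mean BER <= 2.05
  expect_length(sel$subset, 3)
  expect_lte(sel$K_s, sel$k_min)

  # strictly decreasing curve with zero spread: only the minimum qualifies
  sel2 <- one_se_subset(fake_rfe(c(10, 8, 6, 4, 2), sd_at = 0))
  expect_equal(sel2$K_s, 5)
})

test_that("RFE: path lengths, determinism, planted-signal survival", {
  d <- make_planted_features(8, 6, n_noise = 2, effect = 2.5, seed = 61)
  cols <- planted_feature_cols(d) # inf1, inf2 + 2 noise
  rfe <- rfe_bootstrap(d, "L1LRsel",
    B = 40, seed = 62, features = cols,
    hyper = list(lambda = 0.05)
  )
  # one feature eliminated per step, every resample
  expect_true(all(lengths(rfe$elim) == length(cols)))
  expect_equal(nrow(rfe$curves), 40 * length(cols))

  rfe2 <- rfe_bootstrap(d, "L1LRsel",
    B = 40, seed = 62, features = cols,
    hyper = list(lambda = 0.05)
  )
  expect_identical(rfe$curves, rfe2$curves)
  expect_identical(rfe$elim, rfe2$elim)

  # the separating features survive to the end in nearly every resample
  last <- vapply(rfe$elim, function(e) tail(e, 1), character(1))
  expect_gte(mean(last %in% c("inf1", "inf2")), 0.95)
})

test_that("a perfectly separating feature out-scores noise at B = 200", {
  # one feature separates the classes completely, two are pure noise
  set.seed(63)
  n_pat <- 12
  d <- purrr::map_dfr(seq_len(n_pat), function(p) {
    lab <- if (p <= n_pat / 2) 1 else -1
    tibble::tibble(
      patient_id = sprintf("p%02d", p), label = lab,
      A = lab * 2 + runif(6, -0.5, 0.5), # disjoint class supports
      B = rnorm(6), C = rnorm(6)
    )
  })
  rfe <- rfe_bootstrap(d, "L1LRsel",
    B = 200, seed = 64, features = c("A", "B", "C"),
    hyper = list(lambda = 0.05)
  )
  sel <- one_se_subset(rfe)
  counts <- setNames(sel$counts$count, sel$counts$feature)
  expect_gt(counts[["A"]], max(counts[c("B", "C")]))
  expect_true(all(sel$counts$count <= 200))
  expect_lte(sel$K_s, sel$k_min) # holds by construction, asserted per run

  # A survives to k = 1 in at least 95% of resamples
  last <- vapply(rfe$elim, function(e) tail(e, 1), character(1))
  expect_gte(mean(last == "A"), 0.95)
})

test_that("both ranking methods recover a planted subset", {
  d <- make_planted_features(12, 6, n_noise = 8, effect = 2, seed = 65)
  cols <- planted_feature_cols(d)
  for (meth in c("BSTsel", "L1LRsel")) {
    rfe <- rfe_bootstrap(d, meth,
      B = 25, seed = 66, features = cols,
      hyper = if (meth == "BSTsel") {
        list(depth = 1, M = 20)
      } else {
        list(lambda = 0.05)
      }
    )
    sel <- one_se_subset(rfe)
    expect_true(all(c("inf1", "inf2") %in%
      sel$counts$feature[seq_len(max(sel$K_s, 2))]),
    label = meth
    )
  }
})

test_that("subset evaluation: identity, noise-only harm, economy", {
  d <- make_planted_features(10, 6, n_noise = 4, effect = 2, seed = 67)
  cols <- planted_feature_cols(d)
  sp <- patient_split(d, 0.8, seed = 68)
  spec <- model_spec("L1LR", lambda = 0.02)

  # subset == all features -> identical models, delta identically zero
  ev <- evaluate_subset(sp$train, sp$test, cols, spec,
    B = 40, seed = 69,
    features = cols
  )
  expect_true(all(ev$comparison$delta == 0, na.rm = TRUE)) # NA = resample
  # with a missing class, recorded and excluded by contract
  expect_equal(ev$comparison$ci, c(0, 0))
  expect_false(ev$comparison$significant)

  # pure-noise subset -> significant BER increase (delta = all - subset < 0)
  ev2 <- evaluate_subset(
    sp$train, sp$test, c("nz01", "nz02"), spec,
    B = 60, seed = 69, features = cols
  )
  expect_true(ev2$comparison$significant)
  expect_lt(ev2$comparison$ci[2], 0)

  # informative subset: no significant decline, and cheaper to compute
  ev3 <- evaluate_subset(
    sp$train, sp$test, c("inf1", "inf2"), spec,
    B = 60, seed = 69, features = cols
  )
  expect_false(ev3$comparison$significant)
  expect_lt(ev3$cost_subset, ev3$cost_all)

  expect_error(
    evaluate_subset(sp$train, sp$test, character(0), spec),
    class = "shockable_error"
  )
})

test_that("selection tidiers expose the curve and counts", {
  sel <- one_se_subset(fake_rfe(c(5, 3, 2, 1.9, 1.95)))
  expect_s3_class(tidy(sel), "tbl_df")
  g <- glance(sel)
  expect_equal(g$K_s, 3)
  p <- autoplot(sel)
  expect_s3_class(p, "ggplot")
})
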