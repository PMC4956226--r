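# Synthetic ECG generator: spectral targets, rates, reproducibility,
# patient structure.

test_that("VF generator hits its spectral and amplitude targets", {
  v <- gen_vf(8, 400, 3.5, seed = 71)
  sp <- Mod(fft(v * (0.54 - 0.46 * cos(2 * pi * (seq_along(v) - 1) /
    (length(v) - 1)))))
  f <- (seq_along(v) - 1) * 250 / length(v)
  peak <- f[which.max(sp[f <= 125])]
  expect_gte(peak, 3.2)
  expect_lte(peak, 3.8)

  p2p <- vapply(
    1:100,
    function(s) {
      x <- gen_vf(8, 400, 3.5, seed = s)
      max(x) - min(x)
    },
    numeric(1)
  )
  expect_true(all(p2p >= 300 & p2p <= 500))

  expect_identical(gen_vf(4, 400, 4, seed = 5), gen_vf(4, 400, 4, seed = 5))
  expect_error(gen_vf(4, 400, 8, seed = 1), class = "shockable_error")
  # no isoelectric baseline: never 250 ms below 5% of max (amplitude
  # waxing/waning between beats of the detuned components is expected)
  for (s in c(71, 72, 73)) {
    x <- abs(gen_vf(8, 400, 3.5, seed = s))
    runlen <- rle(x < 0.05 * max(x))
    expect_lt(max(c(0, runlen$lengths[runlen$values])), 62)
  }
})

test_that("organized generator realizes the requested rate", {
  x <- ecg_preprocess(gen_organized(8, 15, 150, TRUE, 800, seed = 73), 250)
  expect_equal(length(detect_peaks(x, 250)), 2) # 15 bpm over 8 s

  x160 <- ecg_preprocess(gen_organized(8, 160, 70, FALSE, 900, seed = 74),
    250
  )
  expect_equal(peak_rate(x160, 250), 160, tolerance = 5 / 160)

  expect_identical(
    gen_organized(4, 80, 80, seed = 9),
    gen_organized(4, 80, 80, seed = 9)
  )
  expect_error(gen_organized(4, 5, seed = 1), class = "shockable_error")
})

test_that("corpus generation is reproducible and honors prevalences", {
  c1 <- gen_corpus("public_like", 4, 1, seed = 75, record_s = 32)
  c2 <- gen_corpus("public_like", 4, 1, seed = 75, record_s = 32)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$annotations, c2$annotations)

  # all-VF profile: every retained segment is shockable
  pvf <- rhythm_profile("public_like",
    prevalence = c(
      VF = 1, VT = 0, NSR = 0, SVT = 0, PEA = 0, PR = 0,
      AS = 0, NOISE = 0
    )
  )
  cv <- preprocess_records(gen_corpus(pvf, 6, 1, seed = 76, record_s = 32))
  segs <- label_segments(segment_records(cv, 4))
  kept <- dplyr::filter(segs, retained)
  expect_gt(nrow(kept), 0)
  expect_true(all(kept$label == 1))

  expect_error(rhythm_profile("public_like", prevalence = c(VF = 0.5)),
    class = "shockable_error"
  )
})

test_that("noise epochs are excluded at the configured rate", {
  pn <- rhythm_profile("public_like",
    prevalence = c(
      VF = 0.4, VT = 0, NSR = 0.4, SVT = 0, PEA = 0, PR = 0,
      AS = 0, NOISE = 0.2
    ),
    separability = 1
  )
  cn <- preprocess_records(gen_corpus(pn, 16, 1, seed = 77, record_s = 64))
  segs <- label_segments(segment_records(cn, 4))
  frac_noise <- mean(segs$reason == "noise", na.rm = FALSE)
  frac_noise <- sum(!is.na(segs$reason) & segs$reason == "noise") /
    nrow(segs)
  # binomial tolerance around 0.2 (n approx 240 windows)
  expect_gt(frac_noise, 0.12)
  expect_lt(frac_noise, 0.28)
})

test_that("patients cluster: between-patient spread exceeds within", {
  corpus <- preprocess_records(
    gen_corpus("public_like", 12, 2, seed = 78, record_s = 64)
  )
  segs <- dplyr::filter(
    label_segments(segment_records(corpus, 4)),
    retained, source_rhythm == "VF"
  )
  feats <- extract_features(segs, features = c("TCI", "M"))
  for (cn in c("TCI", "M")) {
    v <- feats[[cn]]
    g <- feats$patient_id
    gm <- tapply(v, g, mean)
    ng <- tapply(v, g, length)
    msb <- sum(ng * (gm[unique(g)] - mean(v))^2) / (length(gm) - 1)
    msw <- sum((v - gm[g])^2) / (length(v) - length(gm))
    expect_gt(msb, msw) # persistent per-patient morphology
  }
})

test_that("the separability dial is monotone in pipeline error", {
  ber_at <- function(knob, seed) {
    pf <- rhythm_profile("ohca_like", separability = knob)
    corpus <- preprocess_records(
      gen_corpus(pf, 16, 1, seed = seed, record_s = 64)
    )
    segs <- label_segments(segment_records(corpus, 4))
    feats <- extract_features(dplyr::filter(segs, retained))
    sp <- patient_split(feats, 0.8, seed = seed + 1)
    if (length(unique(sp$train$label)) < 2 ||
      length(unique(sp$test$label)) < 2) {
      return(NA_real_)
    }
    std <- standardize_features(sp$train, sp$test)
    m <- fit_model(model_spec("L1LR", lambda = 0.01), std$train, seed = 3)
    classification_metrics(
      std$other$label,
      predict(m, std$other)$pred
    )$ber
  }
  knobs <- c(0.9, 0.75, 0.5) # the responsive range of the dial
  bers <- vapply(knobs, function(k) {
    mean(vapply(1:10, function(s) ber_at(k, 80 + s), numeric(1)),
      na.rm = TRUE
    )
  }, numeric(1))
  # decreasing separability must not decrease mean error (at most one
  # flat/inverted adjacent pair tolerated), and the extremes must order
  expect_lte(sum(diff(bers) < 0), 1)
  expect_gt(bers[3], bers[1])
})

test_that("corpora round-trip through the CSV and WFDB writers", {
  rec <- gen_corpus("public_like", 2, 1, seed = 79, record_s = 32)[1, ]
  dir <- withr::local_tempdir()

  csv <- file.path(dir, "rec1.csv")
  write_record_csv(rec, csv)
  back <- read_record_csv(csv, rec$patient_id, rec$record_id)
  expect_equal(back$samples[[1]], rec$samples[[1]], tolerance = 1e-6)
  expect_equal(back$annotations[[1]]$rhythm, rec$annotations[[1]]$rhythm)

  write_record_wfdb(rec, dir, "w1")
  wb <- read_record_wfdb(dir, "w1")
  expect_equal(wb$fs, 250)
  # 16-bit quantisation at 200 adu/mV -> 5 uV resolution
  expect_lt(max(abs(wb$samples[[1]] - rec$samples[[1]])), 5)
  expect_equal(wb$annotations[[1]]$start_s, rec$annotations[[1]]$start_s)
  expect_equal(wb$patient_id, rec$patient_id)
})
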