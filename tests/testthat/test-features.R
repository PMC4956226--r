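# Feature library: oracle equivalence, invariances, orderings, transforms.

test_that("all 30 features match their brute-force oracles on the fixtures", {
  segs <- fixture_segments()
  expect_length(segs, 20)
  for (nm in names(segs)) {
    x <- segs[[nm]]
    imp <- c(
      compute_temporal(x), compute_spectral(x), compute_li(x),
      compute_complexity(x)
    )
    ora <- oracle_features(x)[names(imp)]
    expect_true(all(abs(imp - ora) < 1e-9),
      label = paste0(
        nm, ": max |diff| = ",
        format(max(abs(imp - ora)))
      )
    )
    expect_true(all(is.finite(imp)), label = nm)
  }
})

test_that("features are deterministic and reject degenerate input", {
  x <- fixture_segments()$vf_45
  expect_identical(compute_temporal(x), compute_temporal(x))
  expect_identical(compute_li(x), compute_li(x))
  expect_error(compute_li(rep(0, 1000)), class = "shockable_degenerate")
  expect_error(compute_complexity(rep(3, 1000)),
    class = "shockable_degenerate"
  )
})

test_that("scale-relative features are invariant to amplitude scaling", {
  scale_free <- c(
    "TCSC", "MAV", "Count1", "Count2", "Count3", "x1", "x2", "bCP",
    "PSR", "HILB", "SamEn", "CM", "CVbin", "abin", "Frqbin", "Kurt",
    "TCI", "Expmod", "vFleak", "M", "A1", "A2", "A3", "x3", "x4", "x5",
    "bWT", "bW", "Li"
  )
  for (nm in c("vf_45", "nsr_70", "noise_1")) {
    x <- fixture_segments()[[nm]]
    f1 <- c(
      compute_temporal(x), compute_spectral(x), compute_li(x),
      compute_complexity(x)
    )
    f10 <- c(
      compute_temporal(10 * x), compute_spectral(10 * x),
      compute_li(10 * x), compute_complexity(10 * x)
    )
    expect_equal(f10[scale_free], f1[scale_free], tolerance = 1e-9)
  }
})

test_that("frequency-carrying features order sinusoid pairs correctly", {
  t8 <- seq(0, 8 - 1 / 250, by = 1 / 250)
  s5 <- sin(2 * pi * 5 * t8)
  s1 <- sin(2 * pi * 1 * t8)
  f5 <- compute_temporal(s5)
  f1 <- compute_temporal(s1)
  # counts: 5 Hz leaks into the narrow analysis band, 1 Hz stays in the
  # stop-band floor
  expect_gt(f5[["Count1"]], f1[["Count1"]])
  expect_gt(f5[["Count2"]], f1[["Count2"]])
  expect_gt(f5[["Count3"]], f1[["Count3"]])
  # rate measures move with frequency
  expect_lt(f5[["TCI"]], f1[["TCI"]])
  expect_gt(f5[["Expmod"]], f1[["Expmod"]])
  expect_gt(
    compute_complexity(s5)[["Frqbin"]],
    compute_complexity(s1)[["Frqbin"]]
  )
  # TCSC is duty-cycle based, hence dilation-invariant on pure sinusoids
  expect_equal(f5[["TCSC"]], f1[["TCSC"]], tolerance = 0.01)
})

test_that("spectral features separate narrowband, harmonic and flat spectra", {
  t8 <- seq(0, 8 - 1 / 250, by = 1 / 250)
  s5 <- sin(2 * pi * 5 * t8)
  sq5 <- sign(sin(2 * pi * 5 * t8) + 1e-12)
  set.seed(99)
  wn <- rnorm(length(t8))
  fs5 <- compute_spectral(s5)
  fsq <- compute_spectral(sq5)
  fwn <- compute_spectral(wn)
  expect_lt(fs5[["vFleak"]], 0.1) # near-perfect null at the mean period
  expect_gt(fsq[["vFleak"]], fs5[["vFleak"]]) # odd harmonics leak
  expect_gt(fsq[["A3"]], fs5[["A3"]]) # harmonic band power
  expect_gt(fwn[["M"]], fs5[["M"]]) # flat spectrum moves the moment up
})

test_that("complexity features order periodic vs stochastic signals", {
  t8 <- seq(0, 8 - 1 / 250, by = 1 / 250)
  s5 <- sin(2 * pi * 5 * t8)
  set.seed(7)
  wn <- rnorm(length(t8)) * sd(s5) / 1 # equal SD scale-free anyway
  cs <- compute_complexity(s5)
  cw <- compute_complexity(wn)
  expect_lt(cs[["SamEn"]], cw[["SamEn"]])
  expect_lt(cs[["PSR"]], cw[["PSR"]])

  # constant-plus-step: the binarized signal parses at the LZ76 floor
  # 0 | 0^k 1 | 1^m -- three words, independent of the run lengths
  step <- c(rep(0, 500), rep(1, 500)) + seq(0, 1e-3, length.out = 1000)
  expect_equal(
    compute_complexity(step)[["CM"]],
    oracle_lz(as.integer(step > mean(step))) * log2(1000) / 1000
  )
  expect_equal(oracle_lz(as.integer(step > mean(step))), 3)
})

test_that("TCI reads 500 ms on a 2 Hz unipolar pulse train", {
  t8 <- seq(0, 8 - 1 / 250, by = 1 / 250)
  pulses <- as.numeric((t8 %% 0.5) < 0.06) # 2 pulses per second
  tci <- compute_temporal(pulses)[["TCI"]]
  expect_equal(tci, 500, tolerance = 0.05)
})

test_that("transform_features normalizes counts and preserves order", {
  raw <- c(Count1 = 800, Count2 = 500, Count3 = 200, Kurt = 4, TCSC = 0.4)
  tr <- transform_features(raw, duration = 4, fs = 250)
  expect_equal(tr[["Count2"]], 0.5) # 500 / 1000
  expect_equal(tr[["Count1"]], 0.8)
  expect_equal(tr[["Count3"]], log1p(0.2))
  expect_equal(tr[["Kurt"]], log1p(4))
  expect_identical(tr[["TCSC"]], raw[["TCSC"]]) # untouched, bit-identical

  # monotone map: order preserved for any pair
  a <- transform_features(c(Kurt = 2), duration = 4)
  b <- transform_features(c(Kurt = 7), duration = 4)
  expect_lt(a[["Kurt"]], b[["Kurt"]])
})

test_that("fraction-type features live in [0, 1] after normalization", {
  segs <- fixture_segments()
  frac <- c("TCSC", "MAV", "Count1", "Count2", "Count3", "PSR", "HILB",
    "abin", "x2")
  for (nm in c("vf_45", "nsr_70", "pea_vf", "noise_2")) {
    x <- segs[[nm]]
    v <- c(compute_temporal(x), compute_complexity(x))
    v <- transform_features(v, window_samples = length(x))
    expect_true(all(v[frac] >= 0 & v[frac] <= 1), label = nm)
  }
})

test_that("standardization follows the training-set population convention", {
  tr <- tibble::tibble(TCI = c(1, 2, 3), TCSC = c(5, 5, 5))
  te <- tibble::tibble(TCI = c(2, 10), TCSC = c(5, 7))
  expect_warning(
    std <- standardize_features(tr, te, cols = c("TCI", "TCSC")),
    "constant"
  )
  expect_equal(std$train$TCI, c(-1, 0, 1) * sqrt(3 / 2)) # population SD
  expect_equal(std$other$TCI[1], 0) # equals the training mean
  expect_equal(std$train$TCSC, c(0, 0, 0)) # zero-SD column -> zeros
  expect_error(standardize_features(tr[0, ]), class = "shockable_error")

  # training columns end up mean 0 / SD 1 within 1e-9
  d <- make_planted_features(4, 4, n_noise = 3, seed = 2)
  cols <- planted_feature_cols(d)
  std2 <- standardize_features(d, cols = cols)
  for (cn in cols) {
    expect_lt(abs(mean(std2$train[[cn]])), 1e-9)
    n <- nrow(std2$train)
    expect_lt(abs(sqrt(sum(std2$train[[cn]]^2) / n) - 1), 1e-9)
  }
})

test_that("feature subsets cost less than the full library", {
  expect_lt(feature_cost(c("bCP", "vFleak", "SamEn")), feature_cost())
  expect_lt(feature_cost("TCI"), feature_cost(c("TCI", "HILB")))
  expect_error(feature_cost("nope"))
})

test_that("feature tables round-trip through the delimited writer", {
  segs <- fixture_segments()
  tab <- extract_features(
    tibble::tibble(
      patient_id = c("a", "b"), record_id = c("a", "b"),
      segment_id = c("s1", "s2"), duration = 4, label = c(1, -1),
      samples = segs[c("vf_45", "nsr_70")]
    )
  )
  expect_true(all(feature_names() %in% names(tab)))
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, p)
  back <- read_feature_table(p)
  expect_equal(as.data.frame(back[feature_names()]),
    as.data.frame(tab[feature_names()]),
    tolerance = 1e-12
  )
})
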