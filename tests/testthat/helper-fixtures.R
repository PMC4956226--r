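# Fixtures built in code (fixed seeds) and cached for the session.

.fix_cache <- new.env(parent = emptyenv())

fix_cached <- function(key, builder) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- builder()
  .fix_cache[[key]]
}

# 20 stored 4-s segments covering the rhythm/waveform space: VF at several
# frequencies/amplitudes, organized rhythms narrow/wide/slow/fast,
# borderline contaminated epochs, artifact noise, and deterministic
# waveforms (sinusoids, square, pulse train). All preprocessed to the
# 1-30 Hz analysis band.
fixture_segments <- function() {
  fix_cached("segments", function() {
    t4 <- seq(0, 4 - 1 / 250, by = 1 / 250)
    raw <- list(
      vf_45 = gen_vf(4, 800, 4.5, seed = 101),
      vf_25 = gen_vf(4, 300, 2.5, seed = 102),
      vf_65 = gen_vf(4, 1200, 6.5, seed = 103),
      vf_low = gen_vf(4, 180, 3.0, seed = 104),
      vf_am = gen_vf(4, 500, 5.5, seed = 105),
      vf_qrs = gen_vf(4, 400, 3.5, seed = 106) +
        gen_organized(4, 55, 110, TRUE, 300, seed = 107, noise_uv = 0),
      nsr_70 = gen_organized(4, 70, 80, FALSE, 1000, seed = 108),
      nsr_55 = gen_organized(4, 55, 70, FALSE, 1400, seed = 109),
      svt_180 = gen_organized(4, 180, 70, FALSE, 900, seed = 110),
      vt_190 = gen_organized(4, 190, 150, TRUE, 1100, seed = 111),
      pea_25 = gen_organized(4, 25, 150, TRUE, 600, seed = 112),
      pea_15 = gen_organized(4, 15, 160, TRUE, 500, seed = 113),
      pea_vf = gen_organized(4, 40, 130, TRUE, 500, seed = 114) +
        gen_vf(4, 250, 3.0, seed = 115),
      wide_110 = gen_organized(4, 110, 130, TRUE, 800, seed = 116),
      noise_1 = gen_noise(4, 150, seed = 117),
      noise_2 = gen_noise(4, 300, seed = 118),
      sin_5 = 700 * sin(2 * pi * 5 * t4),
      sin_25 = 700 * sin(2 * pi * 2.5 * t4 + 0.7),
      square_5 = 500 * sign(sin(2 * pi * 5 * t4) + 1e-12),
      pulses_2 = 800 * as.numeric((t4 %% 0.5) < 0.06)
    )
    lapply(raw, ecg_preprocess, fs = 250)
  })
}

# feature-level planted dataset: 2 informative + n_noise pure-noise
# features, patient-structured (random patient effects), for selection and
# classifier tests
make_planted_features <- function(n_patients_per_class = 30,
                                  segs_per_patient = 8, n_noise = 28,
                                  effect = 1.4, seed = 1) {
  set.seed(seed)
  rows <- list()
  pid <- 0
  for (lab in c(1, -1)) {
    for (p in seq_len(n_patients_per_class)) {
      pid <- pid + 1
      re_inf <- rnorm(2, sd = 0.4)
      re_nz <- rnorm(n_noise, sd = 0.3)
      for (s in seq_len(segs_per_patient)) {
        v1 <- lab * effect + re_inf[1] + rnorm(1, sd = 0.7)
        v2 <- lab * 0.8 * effect + re_inf[2] + rnorm(1, sd = 0.7)
        nz <- re_nz + rnorm(n_noise)
        rows[[length(rows) + 1]] <- c(
          pid = pid, label = lab, inf1 = v1, inf2 = v2,
          setNames(nz, sprintf("nz%02d", seq_len(n_noise)))
        )
      }
    }
  }
  d <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  d$patient_id <- sprintf("p%03d", d$pid)
  d$pid <- NULL
  d
}

planted_feature_cols <- function(d) setdiff(names(d), c("patient_id", "label"))

# widely separated two-class feature cloud (sanity-ceiling fixture)
make_separated_features <- function(n_patients_per_class = 10,
                                    segs_per_patient = 6, n_feat = 6,
                                    gap = 6, seed = 1) {
  set.seed(seed)
  rows <- list()
  pid <- 0
  for (lab in c(1, -1)) {
    for (p in seq_len(n_patients_per_class)) {
      pid <- pid + 1
      for (s in seq_len(segs_per_patient)) {
        v <- lab * gap / 2 + rnorm(n_feat)
        rows[[length(rows) + 1]] <- c(pid = pid, label = lab, v)
      }
    }
  }
  d <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  names(d) <- c("pid", "label", sprintf("f%02d", seq_len(n_feat)))
  d$patient_id <- sprintf("p%03d", d$pid)
  d$pid <- NULL
  d
}

# single-rhythm test record builder (samples treated as already filtered)
make_record <- function(patient_id, samples, rhythm, fs = 250,
                        rate_bpm = NA_real_, record_id = NULL) {
  ecg_record(
    patient_id, fs, samples,
    tibble::tibble(
      start_s = 0, end_s = length(samples) / fs, rhythm = rhythm,
      rate_bpm = rate_bpm
    ),
    record_id = record_id
  )
}

# prediction tibble with exact Se/Sp (counts of correct calls per class)
make_predictions <- function(n_pos, correct_pos, n_neg, correct_neg,
                             n_patients = 10) {
  tibble::tibble(
    patient_id = rep_len(sprintf("p%02d", seq_len(n_patients)),
      n_pos + n_neg
    ),
    label = rep(c(1, -1), c(n_pos, n_neg)),
    pred = c(
      rep(c(1, -1), c(correct_pos, n_pos - correct_pos)),
      rep(c(-1, 1), c(correct_neg, n_neg - correct_neg))
    )
  )
}
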