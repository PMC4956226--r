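#' Population profiles for the synthetic ECG corpus generator
#'
#' Two stated worlds: `public_like` emulates Holter-database populations
#' (coarse, fast VF near rhythm onset: peak-to-peak 400--1500 uV, dominant
#' frequency 3.5--6.5 Hz; mostly narrow-QRS organized rhythms at normal
#' rates) and `ohca_like` emulates out-of-hospital cardiac-arrest
#' populations minutes into the arrest (degraded VF: 150--600 uV, 2--4.5
#' Hz; bradycardic PEA/PR with wide, aberrant QRS down to very low rates,
#' more asystole). The `separability` knob (0..1) controls how much
#' cross-class morphology contaminates each epoch (organized complexes
#' inside VF, fibrillatory baseline inside organized rhythms); the
#' ohca-like default is deliberately lower -- borderline VF/PEA cases are
#' what makes OHCA rhythm analysis hard.
#'
#' @param profile `"public_like"` or `"ohca_like"`.
#' @param ... overrides for any profile field (e.g. `prevalence`,
#'   `separability`, `vf_amp`, `vf_f0`, `nsh_rate`, `qrs_width_ms`,
#'   `aberrant_frac`, `noise_sd`).
#' @return a list of generator settings.
#' @export
rhythm_profile <- function(profile = c("public_like", "ohca_like"), ...) {
  profile <- match.arg(profile)
  base <- if (profile == "public_like") {
    list(
      profile = profile,
      prevalence = c(
        VF = 0.25, VT = 0.10, NSR = 0.30, SVT = 0.10, PEA = 0.08,
        PR = 0.05, AS = 0.02, NOISE = 0.10
      ),
      vf_amp = c(400, 1500), vf_f0 = c(3.5, 6.5),
      nsh_amp = c(600, 1500), nsh_rate = c(50, 160),
      qrs_width_ms = c(60, 100), aberrant_frac = 0.10,
      vt_rate = c(120, 240),
      noise_sd = 150, separability = 0.9,
      patient_amp_sdlog = 0.25, epoch_s = c(12, 16, 20)
    )
  } else {
    list(
      profile = profile,
      prevalence = c(
        VF = 0.25, VT = 0.05, NSR = 0.05, SVT = 0.05, PEA = 0.25,
        PR = 0.15, AS = 0.10, NOISE = 0.10
      ),
      vf_amp = c(150, 600), vf_f0 = c(2, 4.5),
      nsh_amp = c(300, 900), nsh_rate = c(10, 120),
      qrs_width_ms = c(80, 160), aberrant_frac = 0.40,
      vt_rate = c(120, 240),
      noise_sd = 150, separability = 0.55,
      patient_amp_sdlog = 0.25, epoch_s = c(12, 16, 20)
    )
  }
  over <- list(...)
  cfg <- utils::modifyList(base, over)
  if (abs(sum(cfg$prevalence) - 1) > 1e-9) {
    abort("prevalences must sum to 1", class = "shockable_error")
  }
  if (any(diff(cfg$vf_amp) < 0) || any(diff(cfg$vf_f0) < 0)) {
    abort("profile ranges must be ordered", class = "shockable_error")
  }
  cfg
}

#' Generate a ventricular fibrillation waveform
#'
#' Phenomenological oscillation model (not an electrophysiological
#' simulation): 3--5 sinusoidal components with random detunes within
#' +/-0.35 Hz of a slowly drifting instantaneous frequency centred on
#' `f0`, random phases, and slow amplitude modulation. The spectral peak
#' stays within about +/-0.3 Hz of `f0` and the waveform has no
#' isoelectric baseline. Realized peak-to-peak amplitude is
#' `amplitude` x U(0.85, 1.15).
#'
#' @param duration length in seconds.
#' @param amplitude target peak-to-peak amplitude in microvolts.
#' @param f0 dominant (fibrillation) frequency in Hz, within 1.5--7.
#' @param fs sampling rate in Hz.
#' @param seed optional RNG seed (bit-identical output for equal seeds).
#' @return numeric vector of `duration * fs` samples (microvolts).
#' @examples
#' x <- gen_vf(8, 400, 4.5, seed = 1)
#' @export
gen_vf <- function(duration, amplitude, f0, fs = 250, seed = NULL) {
  if (f0 < 1.5 || f0 > 7) {
    abort("f0 must lie in [1.5, 7] Hz", class = "shockable_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  drift <- 0.10 * sin(2 * pi * 0.11 * t + runif(1, 0, 2 * pi)) +
    0.05 * sin(2 * pi * 0.23 * t + runif(1, 0, 2 * pi))
  phase0 <- 2 * pi * cumsum(f0 + drift) / fs
  ncomp <- sample(3:5, 1)
  detune <- c(0, runif(ncomp - 1, -0.35, 0.35))
  amps <- c(1, runif(ncomp - 1, 0.15, 0.45))
  x <- numeric(n)
  for (k in seq_len(ncomp)) {
    x <- x + amps[k] *
      sin(phase0 + 2 * pi * detune[k] * t + runif(1, 0, 2 * pi))
  }
  x <- x * (1 + 0.25 * sin(2 * pi * 0.3 * t + runif(1, 0, 2 * pi)))
  x / (max(x) - min(x)) * amplitude * runif(1, 0.85, 1.15)
}

# biphasic QRS-like wavelet (Gaussian derivative); width_ms spans the
# visible complex; aberrant adds a delayed opposite lobe (wide, bizarre)
qrs_kernel <- function(width_ms, fs, aberrant = FALSE) {
  sigma <- width_ms / 1000 / 5
  half <- max(3L, as.integer(round(3.5 * sigma * fs)))
  t <- (-half:half) / fs
  g <- -t / sigma^2 * exp(-t^2 / (2 * sigma^2))
  if (aberrant) {
    t2 <- t - 0.6 * width_ms / 1000
    g <- g + 0.7 * t2 / sigma^2 * exp(-t2^2 / (2 * (1.4 * sigma)^2))
  }
  g / (max(g) - min(g))
}

gauss_wave <- function(center_s, sigma_s, amp, t) {
  amp * exp(-(t - center_s)^2 / (2 * sigma_s^2))
}

#' Generate an organized (QRS-train) rhythm
#'
#' QRS complexes built from a parameterized biphasic wavelet placed at the
#' requested rate with small RR jitter; narrow-complex rhythms at
#' plausible rates get low-amplitude P- and T-like components. `aberrant`
#' widens and distorts the complex (conduction-problem morphology). At
#' very low rates the first beat is placed in 0.5--1 s so that slow-PEA
#' beat counts over a window are well defined.
#'
#' @param duration seconds.
#' @param rate_bpm heart rate, 10--250 bpm.
#' @param qrs_width_ms QRS width in milliseconds.
#' @param aberrant wide/aberrant morphology flag.
#' @param amplitude QRS peak-to-peak in microvolts.
#' @param fs sampling rate.
#' @param seed optional RNG seed.
#' @param rr_jitter SD of the RR-interval jitter, fraction of the RR.
#' @param noise_uv SD of additive measurement noise (microvolts).
#' @return numeric vector of samples.
#' @examples
#' x <- gen_organized(8, 15, 140, aberrant = TRUE, seed = 2)
#' @export
gen_organized <- function(duration, rate_bpm, qrs_width_ms = 80,
                          aberrant = FALSE, amplitude = 1000, fs = 250,
                          seed = NULL, rr_jitter = 0.02, noise_uv = 8) {
  if (rate_bpm < 10 || rate_bpm > 250) {
    abort("rate must lie in [10, 250] bpm", class = "shockable_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  rr <- 60 / rate_bpm
  t0 <- if (rr >= 2) runif(1, 0.5, 1) else runif(1, 0.05, rr)
  beats <- t0
  while (tail(beats, 1) < duration + rr) {
    beats <- c(beats, tail(beats, 1) + rr * (1 + rr_jitter * rnorm(1)))
  }
  beats <- beats[beats < duration]
  x <- numeric(n)
  ker <- qrs_kernel(qrs_width_ms, fs, aberrant)
  half <- (length(ker) - 1L) %/% 2L
  for (bt in beats) {
    ci <- as.integer(round(bt * fs)) + 1L
    lo <- max(1L, ci - half)
    hi <- min(n, ci + half)
    x[lo:hi] <- x[lo:hi] + amplitude * ker[(lo - ci + half + 1L):
    (hi - ci + half + 1L)]
  }
  if (!aberrant && rate_bpm <= 160 && rr > 0.45) {
    for (bt in beats) {
      x <- x + gauss_wave(bt - 0.18, 0.025, 0.12 * amplitude, t) +
        gauss_wave(bt + 0.28, 0.06, 0.22 * amplitude, t)
    }
  }
  x + rnorm(n, sd = noise_uv)
}

#' @rdname gen_organized
#' @param sd_uv noise standard deviation in microvolts.
#' @param wander_uv amplitude of the 0.3 Hz baseline wander component.
#' @return `gen_noise()`: band-limited artifact noise; `gen_asystole()`:
#'   asystole-level trace (peak-to-peak well under 100 uV).
#' @export
gen_noise <- function(duration, sd_uv = 150, fs = 250, seed = NULL,
                      wander_uv = 2 * sd_uv) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  lp <- butter_filter(4, 25, fs, "low")
  w <- filtfilt(lp, rnorm(n, sd = sd_uv)) * 2
  w + wander_uv * sin(2 * pi * 0.3 * t + runif(1, 0, 2 * pi))
}

#' @rdname gen_organized
#' @export
gen_asystole <- function(duration, fs = 250, seed = NULL, sd_uv = 8) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration * fs))
  lp <- butter_filter(4, 15, fs, "low")
  filtfilt(lp, rnorm(n, sd = sd_uv)) * 2
}

#' Generate a patient-structured annotated synthetic corpus
#'
#' Each patient draws persistent morphology parameters once (amplitude
#' scale, VF frequency offset, QRS width/rate, aberrancy), then each
#' record is a concatenation of single-rhythm epochs drawn from the
#' profile prevalences, with annotations written per epoch. Consecutive
#' epochs of different rhythms create the transition boundaries, and
#' `NOISE`/`AS` epochs exercise the exclusion rules. The separability knob
#' injects cross-class morphology as described in [rhythm_profile()].
#'
#' @param profile a [rhythm_profile()] (or profile name).
#' @param n_patients number of patients (>= 2).
#' @param records_per_patient records per patient.
#' @param seed master RNG seed; corpora are bit-identical for equal
#'   (profile, sizes, seed).
#' @param record_s approximate record length in seconds.
#' @param fs sampling rate.
#' @return a corpus tibble (rows as from [ecg_record()]) with the
#'   generation config in the `"config"` attribute.
#' @export
gen_corpus <- function(profile = "public_like", n_patients = 20,
                       records_per_patient = 2, seed = 1, record_s = 64,
                       fs = 250) {
  if (is.character(profile)) profile <- rhythm_profile(profile)
  if (n_patients < 2) {
    abort("need at least 2 patients", class = "shockable_error")
  }
  set.seed(seed)
  recs <- vector("list", n_patients * records_per_patient)
  ri <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("%s_p%03d", profile$profile, p)
    amp_scale <- exp(rnorm(1, 0, profile$patient_amp_sdlog))
    f0_pat <- runif(1, profile$vf_f0[1], profile$vf_f0[2])
    vf_amp_pat <- runif(1, profile$vf_amp[1], profile$vf_amp[2])
    nsh_amp_pat <- runif(1, profile$nsh_amp[1], profile$nsh_amp[2])
    rate_pat <- runif(1, profile$nsh_rate[1], profile$nsh_rate[2])
    qrs_pat <- runif(1, profile$qrs_width_ms[1], profile$qrs_width_ms[2])
    aberrant_pat <- runif(1) < profile$aberrant_frac
    # which side of the Sh/NSh boundary this patient blurs: organized
    # complexes inside VF, fibrillatory baseline inside organized rhythms,
    # or both -- heterogeneous failure modes spread the discriminative
    # burden over several feature families
    contam_type <- sample(c("vf", "org", "both"), 1,
      prob = c(0.35, 0.35, 0.3)
    )
    for (r in seq_len(records_per_patient)) {
      ri <- ri + 1L
      samples <- numeric(0)
      ann <- list()
      t_cur <- 0
      while (t_cur < record_s) {
        ep <- sample(profile$epoch_s, 1)
        rhythm <- sample(names(profile$prevalence), 1,
          prob = profile$prevalence
        )
        gen <- gen_epoch(
          rhythm, ep, profile, fs,
          amp_scale = amp_scale, f0_pat = f0_pat,
          vf_amp_pat = vf_amp_pat, nsh_amp_pat = nsh_amp_pat,
          rate_pat = rate_pat, qrs_pat = qrs_pat,
          aberrant_pat = aberrant_pat, contam_type = contam_type
        )
        samples <- c(samples, gen$x)
        ann[[length(ann) + 1L]] <- tibble(
          start_s = t_cur, end_s = t_cur + ep, rhythm = rhythm,
          rate_bpm = gen$rate
        )
        t_cur <- t_cur + ep
      }
      recs[[ri]] <- ecg_record(
        pid, fs, samples, bind_rows(ann),
        record_id = sprintf("%s_r%d", pid, r)
      )
    }
  }
  out <- bind_rows(recs)
  attr(out, "config") <- list(
    profile = profile, n_patients = n_patients,
    records_per_patient = records_per_patient, seed = seed,
    record_s = record_s, fs = fs
  )
  out
}

gen_epoch <- function(rhythm, ep, profile, fs, amp_scale, f0_pat,
                      vf_amp_pat, nsh_amp_pat, rate_pat, qrs_pat,
                      aberrant_pat, contam_type = "both") {
  s <- profile$separability
  base <- min((1 - s) * 1.6, 1) # saturates: contaminant never dominates
  contam_vf <- if (contam_type %in% c("vf", "both")) base else 0
  contam_org <- if (contam_type %in% c("org", "both")) base else 0
  rate <- NA_real_
  x <- switch(rhythm,
    VF = {
      f0 <- min(max(f0_pat + rnorm(1, 0, 0.15), 1.5), 7)
      amp <- vf_amp_pat * amp_scale * runif(1, 0.9, 1.1)
      v <- gen_vf(ep, amp, f0, fs)
      if (contam_vf > 0) {
        v <- v + gen_organized(ep, 60, 100,
          aberrant = TRUE,
          amplitude = contam_vf * amp, fs = fs, noise_uv = 0
        )
      }
      v
    },
    VT = {
      rate <- runif(1, profile$vt_rate[1], profile$vt_rate[2])
      amp <- vf_amp_pat * amp_scale * runif(1, 1.0, 1.4)
      gen_organized(ep, rate, 1.6 * qrs_pat,
        aberrant = TRUE,
        amplitude = amp, fs = fs
      )
    },
    NSR = {
      rate <- min(max(rate_pat, 45), 110)
      org_epoch(ep, rate, qrs_pat, FALSE, nsh_amp_pat * amp_scale,
        fs, contam_org,
        f0 = f0_pat
      )
    },
    SVT = {
      rate <- runif(1, 160, 220)
      org_epoch(ep, rate, qrs_pat, FALSE, nsh_amp_pat * amp_scale,
        fs, contam_org,
        f0 = f0_pat
      )
    },
    PEA = {
      # pulseless organized activity: bradycardic to moderate rates; wide
      # complexes above ~120 bpm would be indistinguishable from VT and
      # are not a plausible PEA annotation
      rate <- min(max(rate_pat * runif(1, 0.6, 1.0), 12.5), 120)
      org_epoch(
        ep, rate, 1.4 * qrs_pat, TRUE,
        nsh_amp_pat * amp_scale * 0.8, fs, contam_org,
        f0 = f0_pat
      )
    },
    PR = {
      rate <- max(rate_pat, 30)
      org_epoch(ep, rate, qrs_pat, aberrant_pat, nsh_amp_pat * amp_scale,
        fs, contam_org,
        f0 = f0_pat
      )
    },
    AS = gen_asystole(ep, fs),
    NOISE = gen_noise(ep, profile$noise_sd, fs)
  )
  list(x = x, rate = rate)
}

# organized epoch with optional fibrillatory contamination (borderline
# VF/PEA morphology controlled by the separability knob)
org_epoch <- function(ep, rate, qrs_w, aberrant, amp, fs, contam, f0) {
  x <- gen_organized(ep, rate, qrs_w, aberrant, amp, fs)
  if (contam > 0) {
    x <- x + gen_vf(ep, contam * amp, min(max(f0, 1.5), 7), fs)
  }
  x
}
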