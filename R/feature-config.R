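#' Constants used by the 30 VF-detection features
#'
#' Every tunable constant of the feature library lives here, in one place,
#' so that the oracle tests can pin them and alternative conventions can be
#' swapped in deliberately. Sources: threshold-crossing analyses follow the
#' classic 1-s stage / 20%-of-maximum convention (Thakor-style TCI); the
#' tapered 3-s sub-window with relative threshold 0.2 follows the TCSC
#' literature; sample entropy uses m = 2, r = 0.2 SD; the phase-space and
#' Hilbert occupancy measures use a 40 x 40 grid with a 0.5 s delay. The
#' narrow band-pass analysis band is 13--16.5 Hz. Features whose published
#' definitions are only characterised qualitatively (bCP, bWT, bW, the
#' count and x-family thresholds) are documented reinterpretations; their
#' constants below are package conventions.
#'
#' @return a named list of constants.
#' @export
feature_constants <- function() {
  list(
    tci = list(stage_s = 1, thr = 0.2),
    tcsc = list(win_s = 3, step_s = 1, taper_s = 0.25, thr = 0.2),
    exp = list(tau_s = 3),
    expmod = list(tau_s = 1),
    mav = list(win_s = 2),
    # counts of narrow-band activity relative to the segment amplitude;
    # thresholds sit below the band-pass gain of in-band VF oscillations so
    # sustained fibrillatory content registers while being well above the
    # stop-band floor
    counts = list(thr1 = 0.004, thr2 = 0.008, thr3 = 0.016),
    bp = list(lo_hz = 13, hi_hz = 16.5, order = 2),
    x2 = list(thr = 0.1),
    spectral = list(
      band_lo = 0.5, band_hi = 30, peak_lo = 0.5, peak_hi = 9,
      a1_hi_frac = 0.5, a2_lo_frac = 0.7, a2_hi_frac = 1.4,
      a3_lo_frac = 1.6
    ),
    xbands = list(
      x3 = c(13, 16.5), x4_num = c(13, 16.5), x4_den = c(2, 7),
      x5 = c(9, 30)
    ),
    psr = list(tau_s = 0.5, grid = 40),
    hilb = list(grid = 40),
    samen = list(m = 2, r_sd = 0.2),
    binary = list(thr = 0.2, cv_win_s = 0.5),
    wavelet = list(levels = 5)
  )
}

# Daubechies-4 (8-tap) analysis low-pass; sums to sqrt(2)
db4_lowpass <- c(
  0.230377813308855, 0.714846570552542, 0.630880767929590,
  -0.027983769416984, -0.187034811718881, 0.030841381835987,
  0.032883011666983, -0.010597401784997
)

#' Periodized discrete wavelet transform (Daubechies-4)
#'
#' Zero-pads to the next power of two and applies the pyramid algorithm
#' with periodic boundary handling. At 250 Hz and 5 levels the detail bands
#' are d1: 62.5--125, d2: 31.25--62.5, d3: 15.6--31.25, d4: 7.8--15.6,
#' d5: 3.9--7.8 Hz, with the approximation a5 covering 0--3.9 Hz.
#'
#' @param x numeric signal.
#' @param levels decomposition depth.
#' @return list with `details` (list d1..dL of coefficient vectors),
#'   `approx` (aL) and `n_pad` (padded length).
#' @export
dwt_db4 <- function(x, levels = 5) {
  h <- db4_lowpass
  g <- rev(h) * (-1)^(seq_along(h) - 1) # quadrature mirror high-pass
  n2 <- 2^ceiling(log2(length(x)))
  a <- c(x, rep(0, n2 - length(x)))
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    n <- length(a)
    half <- n %/% 2
    d_new <- numeric(half)
    a_new <- numeric(half)
    for (i in seq_len(half)) {
      idx <- ((2 * (i - 1) + seq_along(h) - 1) %% n) + 1
      a_new[i] <- sum(h * a[idx])
      d_new[i] <- sum(g * a[idx])
    }
    details[[j]] <- d_new
    a <- a_new
  }
  names(details) <- paste0("d", seq_len(levels))
  list(details = details, approx = a, n_pad = n2)
}
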