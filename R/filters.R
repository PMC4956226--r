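#' Digital filter design and zero-phase filtering
#'
#' Minimal Butterworth design (bilinear transform) and forward-backward
#' (zero-phase) filtering, sufficient for the 1--30 Hz AED monitor bandwidth
#' used throughout the package. Filters are returned as transfer-function
#' coefficient lists `list(b, a)` in the usual `b[1] + b[2] z^-1 + ...`
#' convention.
#'
#' @param n filter order.
#' @param fc cutoff frequency in Hz (-3 dB point).
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return `butter_filter()`: a list with elements `b` and `a`.
#' @examples
#' f <- butter_filter(4, 30, 250, "low")
#' round(filter_gain(f, c(1, 10, 30, 60), 250), 3)
#' @export
butter_filter <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, fc > 0, fc < fs / 2)
  wc <- 2 * fs * tan(pi * fc / fs) # prewarped analog cutoff
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n)) # unit Butterworth poles
  if (type == "low") {
    poles <- wc * proto
    zeros_z <- rep(-1 + 0i, n) # n analog zeros at infinity
  } else {
    poles <- wc / proto
    zeros_z <- rep(1 + 0i, n) # n analog zeros at s = 0
  }
  poles_z <- (2 * fs + poles) / (2 * fs - poles)
  b <- Re(poly_from_roots(zeros_z))
  a <- Re(poly_from_roots(poles_z))
  # unit gain in the passband (DC for low-pass, Nyquist for high-pass)
  zref <- if (type == "low") 1 + 0i else -1 + 0i
  g <- abs(polyval_rev(a, zref) / polyval_rev(b, zref))
  list(b = b * g, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# evaluate sum coef[k] z^-(k-1)
polyval_rev <- function(coef, z) {
  sum(coef * z^(-(seq_along(coef) - 1)))
}

#' @rdname butter_filter
#' @param filt a filter produced by [butter_filter()] (or any `list(b, a)`).
#' @param f frequencies (Hz) at which to evaluate the magnitude response.
#' @return `filter_gain()`: magnitude response at `f` (single causal pass;
#'   [filtfilt()] applies the square of this).
#' @export
filter_gain <- function(filt, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  vapply(z, function(zi) {
    abs(polyval_rev(filt$b, zi) / polyval_rev(filt$a, zi))
  }, numeric(1))
}

#' @rdname butter_filter
#' @param x numeric signal.
#' @return `filtfilt()`: the zero-phase filtered signal (same length as `x`).
#' @export
filtfilt <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  n <- length(x)
  nfact <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= nfact + 1L) {
    abort("signal too short for the requested filter", class = "shockable_error")
  }
  # odd-reflection padding limits startup transients
  pre <- 2 * x[1] - x[(nfact + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - nfact)]
  ext <- c(pre, x, post)
  y <- .iir_filter(b, a, ext)
  y <- rev(.iir_filter(b, a, rev(y)))
  y[(nfact + 1):(nfact + n)]
}

#' @rdname butter_filter
#' @param width moving-average length in samples (odd).
#' @return `moving_average()`: centered moving average with replicated edges.
#' @export
moving_average <- function(x, width = 5L) {
  stopifnot(width %% 2 == 1)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  ext <- c(rep(x[1], h), x, rep(x[n], h))
  as.numeric(stats::filter(ext, rep(1 / width, width), sides = 2))[
    (h + 1):(h + n)
  ]
}

#' Halve the sampling rate of a signal
#'
#' Anti-alias low-pass filtering (4th-order Butterworth at 0.4 times the
#' target Nyquist rate, applied zero-phase) followed by decimation by two.
#' Used to bring 500 Hz defibrillator recordings to the 250 Hz analysis rate.
#'
#' @param x numeric signal sampled at `fs`.
#' @param fs input sampling rate in Hz (must be even).
#' @return signal sampled at `fs / 2`.
#' @export
decimate_by_two <- function(x, fs) {
  lp <- butter_filter(4, 0.4 * (fs / 4) * 2, fs, "low")
  y <- filtfilt(lp, x)
  y[seq(1, length(y), by = 2L)]
}
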