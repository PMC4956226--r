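# Shared per-segment intermediates, computed lazily and cached, so that
# computing a small feature subset (the AED deployment case) only pays for
# the transforms that subset actually needs.

feature_context <- function(x, fs = 250) {
  if (!is.numeric(x) || length(x) < fs) {
    abort("segment too short", class = "shockable_error")
  }
  if (stats::var(x) == 0) {
    abort("zero-variance segment (degenerate input)",
      class = "shockable_degenerate"
    )
  }
  ctx <- new.env(parent = emptyenv())
  ctx$x <- as.numeric(x)
  ctx$fs <- fs
  ctx$n <- length(x)
  ctx
}

ctx_get <- function(ctx, field, compute) {
  if (is.null(ctx[[field]])) ctx[[field]] <- compute(ctx)
  ctx[[field]]
}

ctx_ax <- function(ctx) ctx_get(ctx, "ax", function(c) abs(c$x))

# rectified 13-16.5 Hz narrow band-pass output
ctx_bp <- function(ctx) {
  ctx_get(ctx, "bp", function(c) {
    k <- feature_constants()$bp
    hp <- butter_filter(k$order, k$lo_hz, c$fs, "high")
    lp <- butter_filter(k$order, k$hi_hz, c$fs, "low")
    abs(filtfilt(lp, filtfilt(hp, c$x)))
  })
}

# one-sided Hamming-windowed amplitude spectrum + dominant frequency
ctx_spec <- function(ctx) {
  ctx_get(ctx, "spec", function(c) {
    n <- c$n
    w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    X <- fft(c$x * w)
    m <- n %/% 2 + 1
    freq <- (seq_len(m) - 1) * c$fs / n
    amp <- Mod(X[seq_len(m)])
    k <- feature_constants()$spectral
    peak_band <- which(freq >= k$peak_lo & freq <= k$peak_hi)
    fp <- freq[peak_band[which.max(amp[peak_band])]]
    list(freq = freq, amp = amp, pow = amp^2, fp = fp)
  })
}

ctx_dwt <- function(ctx) {
  ctx_get(ctx, "dwt", function(c) {
    lv <- feature_constants()$wavelet$levels
    d <- dwt_db4(c$x, lv)
    e_det <- vapply(d$details, function(v) sum(v^2), numeric(1))
    e_app <- sum(d$approx^2)
    list(e_det = e_det, e_app = e_app, e_tot = sum(e_det) + e_app)
  })
}

ctx_hilb <- function(ctx) {
  ctx_get(ctx, "hilb", function(c) {
    n <- c$n
    X <- fft(c$x)
    h <- numeric(n)
    if (n %% 2 == 0) {
      h[1] <- 1
      h[2:(n / 2)] <- 2
      h[n / 2 + 1] <- 1
    } else {
      h[1] <- 1
      h[2:((n + 1) / 2)] <- 2
    }
    Im(fft(X * h, inverse = TRUE) / n)
  })
}

band_sum <- function(freq, val, lo, hi) sum(val[freq >= lo & freq <= hi])

# fraction of visited cells in a g x g occupancy grid of (u, v), each axis
# normalized to its own range
grid_occupancy <- function(u, v, g) {
  su <- (u - min(u)) / (max(u) - min(u))
  sv <- (v - min(v)) / (max(v) - min(v))
  iu <- pmin(floor(su * g), g - 1)
  iv <- pmin(floor(sv * g), g - 1)
  length(unique(iu * g + iv)) / g^2
}
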