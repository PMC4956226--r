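#' Compute the VF-detection features of one segment
#'
#' The 30-feature library splits into four groups. *Temporal* (11): TCI,
#' TCSC, Exp, Expmod, MAV, Count1--3, x1, x2, bCP. *Spectral* (10): vFleak,
#' M, A1, A2, A3, x3, x4, x5, bWT, bW. *Time-frequency* (1): Li.
#' *Complexity* (8): CM, CVbin, abin, Frqbin, Kurt, PSR, HILB, SamEn.
#' All operate on a preprocessed (1--30 Hz, 250 Hz) single-rhythm segment;
#' thresholds are relative to segment amplitude or SD, so the features are
#' invariant to amplitude scaling except where a rate/frequency is being
#' measured. Constants are pinned in [feature_constants()]. Values returned
#' here are *raw*; [transform_features()] applies the count normalization
#' and the variance-stabilising monotone maps.
#'
#' @param x numeric segment samples (microvolts, preprocessed).
#' @param fs sampling rate in Hz.
#' @return named numeric vector of the group's features.
#' @export
compute_temporal <- function(x, fs = 250) {
  ctx <- feature_context(x, fs)
  vapply(
    c(
      "TCI", "TCSC", "Exp", "Expmod", "MAV", "Count1", "Count2", "Count3",
      "x1", "x2", "bCP"
    ),
    function(f) feature_funs()[[f]](ctx), numeric(1)
  )
}

#' @rdname compute_temporal
#' @export
compute_spectral <- function(x, fs = 250) {
  ctx <- feature_context(x, fs)
  vapply(
    c("vFleak", "M", "A1", "A2", "A3", "x3", "x4", "x5", "bWT", "bW"),
    function(f) feature_funs()[[f]](ctx), numeric(1)
  )
}

#' @rdname compute_temporal
#' @export
compute_li <- function(x, fs = 250) {
  ctx <- feature_context(x, fs)
  c(Li = feature_funs()$Li(ctx))
}

#' @rdname compute_temporal
#' @export
compute_complexity <- function(x, fs = 250) {
  ctx <- feature_context(x, fs)
  vapply(
    c("CM", "CVbin", "abin", "Frqbin", "Kurt", "PSR", "HILB", "SamEn"),
    function(f) feature_funs()[[f]](ctx), numeric(1)
  )
}

# ---- individual feature definitions -------------------------------------

f_tci <- function(ctx) {
  k <- feature_constants()$tci
  fs <- ctx$fs
  ax <- ctx_ax(ctx)
  n <- ctx$n
  stage <- as.integer(k$stage_s * fs)
  nstages <- n %/% stage
  bin <- logical(n)
  for (s in seq_len(nstages)) {
    i0 <- (s - 1L) * stage + 1L
    i1 <- s * stage
    bin[i0:i1] <- ax[i0:i1] >= k$thr * max(ax[i0:i1])
  }
  starts <- which(bin & !c(FALSE, bin[-n]))
  t_start <- (starts - 1) / fs
  interior <- if (nstages >= 3) 2:(nstages - 1) else seq_len(nstages)
  vals <- vapply(interior, function(s) {
    s0 <- (s - 1) * k$stage_s
    s1 <- s * k$stage_s
    inside <- t_start[t_start >= s0 & t_start < s1]
    if (!length(inside)) return(1000)
    before <- t_start[t_start < s0]
    after <- t_start[t_start >= s1]
    t2 <- inside[1] - s0
    t1 <- if (length(before)) s0 - max(before) else Inf
    t3 <- s1 - max(inside)
    t4 <- if (length(after)) min(after) - s1 else Inf
    frac_in <- if (is.finite(t1) && t1 + t2 > 0) t2 / (t1 + t2) else 0
    frac_out <- if (is.finite(t4) && t3 + t4 > 0) t3 / (t3 + t4) else 0
    den <- (length(inside) - 1) + frac_in + frac_out
    if (den <= 0) 1000 else min(1000 / den, 1000)
  }, numeric(1))
  mean(vals)
}

tcsc_taper <- function(win, fs, taper_s) {
  t <- (seq_len(win) - 1) / fs
  tt <- win / fs - 1 / fs
  w <- rep(1, win)
  ramp <- t < taper_s
  w[ramp] <- 0.5 * (1 - cos(pi * t[ramp] / taper_s))
  ramp2 <- t > tt - taper_s
  w[ramp2] <- 0.5 * (1 - cos(pi * (tt - t[ramp2]) / taper_s))
  w
}

f_tcsc <- function(ctx) {
  k <- feature_constants()$tcsc
  fs <- ctx$fs
  win <- as.integer(k$win_s * fs)
  step <- as.integer(k$step_s * fs)
  taper <- tcsc_taper(win, fs, k$taper_s)
  starts <- seq(1L, ctx$n - win + 1L, by = step)
  fr <- vapply(starts, function(s) {
    v <- abs(ctx$x[s:(s + win - 1L)]) * taper
    mean(v / max(v) > k$thr)
  }, numeric(1))
  mean(fr)
}

f_exp <- function(ctx) {
  k <- feature_constants()$exp
  ax <- ctx_ax(ctx)
  t <- (seq_len(ctx$n) - 1) / ctx$fs
  imax <- which.max(ax)
  env <- ax[imax] * exp(-abs(t - t[imax]) / k$tau_s)
  d <- ax - env
  s <- ifelse(d >= 0, 1, -1)
  sum(s[-1] != s[-ctx$n]) / (ctx$n / ctx$fs)
}

f_expmod <- function(ctx) {
  k <- feature_constants()$expmod
  ax <- ctx_ax(ctx)
  decay <- exp(-1 / (ctx$fs * k$tau_s))
  env <- ax[1]
  count <- 0L
  below_prev <- FALSE
  for (i in 2:ctx$n) {
    env <- env * decay
    if (ax[i] >= env) {
      if (below_prev) count <- count + 1L
      env <- ax[i]
      below_prev <- FALSE
    } else {
      below_prev <- TRUE
    }
  }
  count / (ctx$n / ctx$fs)
}

f_mav <- function(ctx) {
  k <- feature_constants()$mav
  win <- as.integer(k$win_s * ctx$fs)
  starts <- seq(1L, ctx$n - win + 1L, by = win)
  mean(vapply(starts, function(s) {
    v <- abs(ctx$x[s:(s + win - 1L)])
    mean(v) / max(v)
  }, numeric(1)))
}

f_count <- function(ctx, which) {
  k <- feature_constants()$counts
  thr <- k[[paste0("thr", which)]] * max(ctx_ax(ctx))
  sum(ctx_bp(ctx) >= thr) # raw count; window-size normalization later
}

f_x1 <- function(ctx) {
  bp <- ctx_bp(ctx)
  mean(bp) / max(bp)
}

f_x2 <- function(ctx) {
  k <- feature_constants()$x2
  bp <- ctx_bp(ctx)
  mean(bp >= k$thr * max(bp))
}

f_bcp <- function(ctx) {
  d <- abs(diff(ctx$x))
  mean(d) / max(d)
}

f_vfleak <- function(ctx) {
  x <- ctx$x
  n <- ctx$n
  dsum <- sum(abs(diff(x)))
  if (dsum == 0) return(1)
  np <- max(1L, min(n - 1L, as.integer(floor(pi * sum(abs(x)) / dsum + 0.5))))
  i <- (np + 1L):n
  sum(abs(x[i] + x[i - np])) / sum(abs(x[i]) + abs(x[i - np]))
}

f_m <- function(ctx) {
  sp <- ctx_spec(ctx)
  k <- feature_constants()$spectral
  idx <- sp$freq >= k$band_lo & sp$freq <= k$band_hi
  centroid <- sum(sp$amp[idx] * sp$freq[idx]) / sum(sp$amp[idx])
  centroid / sp$fp
}

f_a1 <- function(ctx) {
  sp <- ctx_spec(ctx)
  k <- feature_constants()$spectral
  tot <- band_sum(sp$freq, sp$amp, k$band_lo, k$band_hi)
  band_sum(sp$freq, sp$amp, k$band_lo, k$a1_hi_frac * sp$fp) / tot
}

f_a2 <- function(ctx) {
  sp <- ctx_spec(ctx)
  k <- feature_constants()$spectral
  tot <- band_sum(sp$freq, sp$amp, k$band_lo, k$band_hi)
  band_sum(sp$freq, sp$amp, k$a2_lo_frac * sp$fp, k$a2_hi_frac * sp$fp) / tot
}

f_a3 <- function(ctx) {
  sp <- ctx_spec(ctx)
  k <- feature_constants()$spectral
  tot <- band_sum(sp$freq, sp$amp, k$band_lo, k$band_hi)
  band_sum(sp$freq, sp$amp, k$a3_lo_frac * sp$fp, k$band_hi) / tot
}

f_x3 <- function(ctx) {
  sp <- ctx_spec(ctx)
  k <- feature_constants()
  b <- k$xbands$x3
  tot <- band_sum(sp$freq, sp$pow, k$spectral$band_lo, k$spectral$band_hi)
  band_sum(sp$freq, sp$pow, b[1], b[2]) / tot
}

f_x4 <- function(ctx) {
  sp <- ctx_spec(ctx)
  k <- feature_constants()$xbands
  num <- band_sum(sp$freq, sp$pow, k$x4_num[1], k$x4_num[2])
  den <- band_sum(sp$freq, sp$pow, k$x4_den[1], k$x4_den[2])
  num / den
}

f_x5 <- function(ctx) {
  sp <- ctx_spec(ctx)
  k <- feature_constants()
  b <- k$xbands$x5
  tot <- band_sum(sp$freq, sp$pow, k$spectral$band_lo, k$spectral$band_hi)
  band_sum(sp$freq, sp$pow, b[1], b[2]) / tot
}

f_bwt <- function(ctx) {
  d <- ctx_dwt(ctx)
  d$e_app / d$e_tot
}

f_bw <- function(ctx) {
  d <- ctx_dwt(ctx)
  d$e_det[["d3"]] / d$e_tot
}

f_li <- function(ctx) {
  d <- ctx_dwt(ctx)
  lv <- feature_constants()$wavelet$levels
  (d$e_app + d$e_det[[paste0("d", lv)]]) / d$e_tot
}

f_cm <- function(ctx) {
  b <- as.integer(ctx$x > mean(ctx$x))
  .lz_complexity(b) * log2(ctx$n) / ctx$n
}

binary_signal <- function(ctx) {
  k <- feature_constants()$binary
  ax <- ctx_ax(ctx)
  as.integer(ax >= k$thr * max(ax))
}

f_cvbin <- function(ctx) {
  k <- feature_constants()$binary
  b <- binary_signal(ctx)
  win <- as.integer(k$cv_win_s * ctx$fs)
  starts <- seq(1L, ctx$n - win + 1L, by = win)
  fr <- vapply(starts, function(s) mean(b[s:(s + win - 1L)]), numeric(1))
  if (mean(fr) == 0) 0 else sd(fr) / mean(fr)
}

f_abin <- function(ctx) mean(binary_signal(ctx))

f_frqbin <- function(ctx) {
  b <- binary_signal(ctx)
  sum(b[-1] == 1L & b[-ctx$n] == 0L) / (ctx$n / ctx$fs)
}

f_kurt <- function(ctx) {
  xc <- ctx$x - mean(ctx$x)
  mean(xc^4) / mean(xc^2)^2
}

f_psr <- function(ctx) {
  k <- feature_constants()$psr
  lag <- as.integer(k$tau_s * ctx$fs)
  u <- ctx$x[1:(ctx$n - lag)]
  v <- ctx$x[(lag + 1):ctx$n]
  lo <- min(ctx$x)
  hi <- max(ctx$x)
  g <- k$grid
  iu <- pmin(floor((u - lo) / (hi - lo) * g), g - 1)
  iv <- pmin(floor((v - lo) / (hi - lo) * g), g - 1)
  length(unique(iu * g + iv)) / g^2
}

f_hilb <- function(ctx) {
  k <- feature_constants()$hilb
  grid_occupancy(ctx$x, ctx_hilb(ctx), k$grid)
}

f_samen <- function(ctx) {
  k <- feature_constants()$samen
  .sampen(ctx$x, k$m, k$r_sd * sd(ctx$x))
}

# registry: feature name -> function(ctx), plus relative cost weights used
# by feature_cost()
feature_funs <- function() {
  list(
    TCI = f_tci, TCSC = f_tcsc, Exp = f_exp, Expmod = f_expmod, MAV = f_mav,
    Count1 = function(c) f_count(c, 1), Count2 = function(c) f_count(c, 2),
    Count3 = function(c) f_count(c, 3), x1 = f_x1, x2 = f_x2, bCP = f_bcp,
    vFleak = f_vfleak, M = f_m, A1 = f_a1, A2 = f_a2, A3 = f_a3,
    x3 = f_x3, x4 = f_x4, x5 = f_x5, bWT = f_bwt, bW = f_bw, Li = f_li,
    CM = f_cm, CVbin = f_cvbin, abin = f_abin, Frqbin = f_frqbin,
    Kurt = f_kurt, PSR = f_psr, HILB = f_hilb, SamEn = f_samen
  )
}

#' Names of the 30 features, in reporting order
#' @return character vector of length 30.
#' @export
feature_names <- function() {
  names(feature_funs())
}
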