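# Independent brute-force oracles: straight-line transcriptions of each
# feature's definition, written against the constants table but sharing no
# code path with the package implementations (explicit loops, direct DFT,
# own convolution/filter recursions).

oracle_iir <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  nb <- length(b)
  na <- length(a)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(nb)) {
      if (i - k + 1 >= 1) acc <- acc + b[k] * x[i - k + 1]
    }
    if (na > 1) {
      for (k in 2:na) {
        if (i - k + 1 >= 1) acc <- acc - a[k] * y[i - k + 1]
      }
    }
    y[i] <- acc
  }
  y
}

# forward-backward filtering with the documented odd-reflection padding
oracle_filtfilt <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  n <- length(x)
  nfact <- 3L * (max(length(a), length(b)) - 1L)
  ext <- c(2 * x[1] - x[(nfact + 1):2], x, 2 * x[n] - x[(n - 1):(n - nfact)])
  y <- oracle_iir(b, a, ext)
  y <- rev(oracle_iir(b, a, rev(y)))
  y[(nfact + 1):(nfact + n)]
}

oracle_bp <- function(x, fs) {
  k <- feature_constants()$bp
  hp <- butter_filter(k$order, k$lo_hz, fs, "high")
  lp <- butter_filter(k$order, k$hi_hz, fs, "low")
  abs(oracle_filtfilt(lp, oracle_filtfilt(hp, x)))
}

# direct DFT (O(n^2)) amplitude spectrum with Hamming window
oracle_spectrum <- function(x, fs) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- x * w
  m <- n %/% 2 + 1
  amp <- numeric(m)
  for (i in seq_len(m)) {
    ph <- -2 * pi * (i - 1) * (seq_len(n) - 1) / n
    amp[i] <- Mod(sum(xw * complex(modulus = 1, argument = ph)))
  }
  freq <- (seq_len(m) - 1) * fs / n
  kk <- feature_constants()$spectral
  pk <- which(freq >= kk$peak_lo & freq <= kk$peak_hi)
  list(freq = freq, amp = amp, pow = amp^2, fp = freq[pk[which.max(amp[pk])]])
}

oracle_tci <- function(x, fs) {
  k <- feature_constants()$tci
  ax <- abs(x)
  n <- length(x)
  stage <- as.integer(k$stage_s * fs)
  nstages <- n %/% stage
  bin <- logical(n)
  for (s in seq_len(nstages)) {
    i0 <- (s - 1) * stage + 1
    thr <- k$thr * max(ax[i0:(s * stage)])
    for (i in i0:(s * stage)) bin[i] <- ax[i] >= thr
  }
  starts <- c()
  for (i in seq_len(n)) {
    if (bin[i] && (i == 1 || !bin[i - 1])) starts <- c(starts, (i - 1) / fs)
  }
  interior <- if (nstages >= 3) 2:(nstages - 1) else seq_len(nstages)
  vals <- c()
  for (s in interior) {
    s0 <- (s - 1) * k$stage_s
    s1 <- s * k$stage_s
    inside <- starts[starts >= s0 & starts < s1]
    if (length(inside) == 0) {
      vals <- c(vals, 1000)
      next
    }
    before <- starts[starts < s0]
    after <- starts[starts >= s1]
    t2 <- inside[1] - s0
    t1 <- if (length(before)) s0 - max(before) else Inf
    t3 <- s1 - max(inside)
    t4 <- if (length(after)) min(after) - s1 else Inf
    a <- if (is.finite(t1) && t1 + t2 > 0) t2 / (t1 + t2) else 0
    b <- if (is.finite(t4) && t3 + t4 > 0) t3 / (t3 + t4) else 0
    den <- (length(inside) - 1) + a + b
    vals <- c(vals, if (den <= 0) 1000 else min(1000 / den, 1000))
  }
  mean(vals)
}

oracle_tcsc <- function(x, fs) {
  k <- feature_constants()$tcsc
  n <- length(x)
  win <- as.integer(k$win_s * fs)
  step <- as.integer(k$step_s * fs)
  tt <- (win - 1) / fs
  taper <- numeric(win)
  for (i in seq_len(win)) {
    ti <- (i - 1) / fs
    taper[i] <- if (ti < k$taper_s) {
      0.5 * (1 - cos(pi * ti / k$taper_s))
    } else if (ti > tt - k$taper_s) {
      0.5 * (1 - cos(pi * (tt - ti) / k$taper_s))
    } else {
      1
    }
  }
  fr <- c()
  for (s in seq(1, n - win + 1, by = step)) {
    v <- abs(x[s:(s + win - 1)]) * taper
    fr <- c(fr, sum(v / max(v) > k$thr) / win)
  }
  mean(fr)
}

oracle_exp <- function(x, fs) {
  k <- feature_constants()$exp
  ax <- abs(x)
  n <- length(x)
  imax <- which.max(ax)
  cross <- 0
  prev_sign <- NULL
  for (i in seq_len(n)) {
    env <- ax[imax] * exp(-abs((i - imax) / fs) / k$tau_s)
    s <- if (ax[i] - env >= 0) 1 else -1
    if (!is.null(prev_sign) && s != prev_sign) cross <- cross + 1
    prev_sign <- s
  }
  cross / (n / fs)
}

oracle_expmod <- function(x, fs) {
  k <- feature_constants()$expmod
  ax <- abs(x)
  decay <- exp(-1 / (fs * k$tau_s))
  env <- ax[1]
  count <- 0
  below <- FALSE
  for (i in 2:length(ax)) {
    env <- env * decay
    if (ax[i] >= env) {
      if (below) count <- count + 1
      env <- ax[i]
      below <- FALSE
    } else {
      below <- TRUE
    }
  }
  count / (length(ax) / fs)
}

oracle_mav <- function(x, fs) {
  k <- feature_constants()$mav
  win <- as.integer(k$win_s * fs)
  vals <- c()
  for (s in seq(1, length(x) - win + 1, by = win)) {
    v <- abs(x[s:(s + win - 1)])
    vals <- c(vals, mean(v) / max(v))
  }
  mean(vals)
}

oracle_counts <- function(x, fs) {
  k <- feature_constants()$counts
  bp <- oracle_bp(x, fs)
  mx <- max(abs(x))
  c(
    Count1 = sum(bp >= k$thr1 * mx),
    Count2 = sum(bp >= k$thr2 * mx),
    Count3 = sum(bp >= k$thr3 * mx)
  )
}

oracle_x1 <- function(x, fs) {
  bp <- oracle_bp(x, fs)
  mean(bp) / max(bp)
}

oracle_x2 <- function(x, fs) {
  k <- feature_constants()$x2
  bp <- oracle_bp(x, fs)
  sum(bp >= k$thr * max(bp)) / length(bp)
}

oracle_bcp <- function(x) {
  d <- abs(x[-1] - x[-length(x)])
  mean(d) / max(d)
}

oracle_vfleak <- function(x) {
  n <- length(x)
  num <- 0
  den <- 0
  for (i in 2:n) den <- den + abs(x[i] - x[i - 1])
  for (i in 1:n) num <- num + abs(x[i])
  np <- floor(pi * num / den + 0.5)
  np <- max(1, min(n - 1, np))
  a <- 0
  b <- 0
  for (i in (np + 1):n) {
    a <- a + abs(x[i] + x[i - np])
    b <- b + abs(x[i]) + abs(x[i - np])
  }
  a / b
}

oracle_spectral_feats <- function(x, fs) {
  sp <- oracle_spectrum(x, fs)
  k <- feature_constants()$spectral
  xb <- feature_constants()$xbands
  inb <- function(lo, hi) sp$freq >= lo & sp$freq <= hi
  tot_a <- sum(sp$amp[inb(k$band_lo, k$band_hi)])
  tot_p <- sum(sp$pow[inb(k$band_lo, k$band_hi)])
  centroid <- sum((sp$amp * sp$freq)[inb(k$band_lo, k$band_hi)]) / tot_a
  c(
    M = centroid / sp$fp,
    A1 = sum(sp$amp[inb(k$band_lo, k$a1_hi_frac * sp$fp)]) / tot_a,
    A2 = sum(sp$amp[inb(k$a2_lo_frac * sp$fp, k$a2_hi_frac * sp$fp)]) / tot_a,
    A3 = sum(sp$amp[inb(k$a3_lo_frac * sp$fp, k$band_hi)]) / tot_a,
    x3 = sum(sp$pow[inb(xb$x3[1], xb$x3[2])]) / tot_p,
    x4 = sum(sp$pow[inb(xb$x4_num[1], xb$x4_num[2])]) /
      sum(sp$pow[inb(xb$x4_den[1], xb$x4_den[2])]),
    x5 = sum(sp$pow[inb(xb$x5[1], xb$x5[2])]) / tot_p
  )
}

# pyramid DWT by explicit circular convolution with the db4 pair
oracle_dwt_energies <- function(x, levels) {
  h <- shockable:::db4_lowpass
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  n2 <- 2^ceiling(log2(length(x)))
  a <- c(x, rep(0, n2 - length(x)))
  e_det <- numeric(levels)
  for (j in seq_len(levels)) {
    n <- length(a)
    half <- n / 2
    anew <- numeric(half)
    dnew <- numeric(half)
    for (i in seq_len(half)) {
      sa <- 0
      sdv <- 0
      for (kk in seq_along(h)) {
        idx <- ((2 * (i - 1) + kk - 1) %% n) + 1
        sa <- sa + h[kk] * a[idx]
        sdv <- sdv + g[kk] * a[idx]
      }
      anew[i] <- sa
      dnew[i] <- sdv
    }
    e_det[j] <- sum(dnew^2)
    a <- anew
  }
  list(e_det = e_det, e_app = sum(a^2), e_tot = sum(e_det) + sum(a^2))
}

oracle_wavelet_feats <- function(x) {
  lv <- feature_constants()$wavelet$levels
  e <- oracle_dwt_energies(x, lv)
  c(
    bWT = e$e_app / e$e_tot,
    bW = e$e_det[3] / e$e_tot,
    Li = (e$e_app + e$e_det[lv]) / e$e_tot
  )
}

# Lempel-Ziv 1976 parsing by substring search over the exhaustive history:
# each word is the shortest string starting at i that does not occur inside
# s[1 : i+l-2] (overlap with the word's own prefix allowed)
oracle_lz <- function(s) {
  str <- paste(s, collapse = "")
  n <- nchar(str)
  c_count <- 0
  i <- 1
  while (i <= n) {
    l <- 1
    while (i + l - 1 <= n) {
      sub <- substr(str, i, i + l - 1)
      hist <- substr(str, 1, i + l - 2)
      if (!grepl(sub, hist, fixed = TRUE)) break
      l <- l + 1
    }
    c_count <- c_count + 1
    i <- i + l
  }
  c_count
}

oracle_cm <- function(x) {
  b <- as.integer(x > mean(x))
  oracle_lz(b) * log2(length(x)) / length(x)
}

oracle_binary_feats <- function(x, fs) {
  k <- feature_constants()$binary
  ax <- abs(x)
  b <- as.integer(ax >= k$thr * max(ax))
  n <- length(b)
  win <- as.integer(k$cv_win_s * fs)
  fr <- c()
  for (s in seq(1, n - win + 1, by = win)) {
    fr <- c(fr, sum(b[s:(s + win - 1)]) / win)
  }
  trans <- 0
  for (i in 2:n) if (b[i] == 1 && b[i - 1] == 0) trans <- trans + 1
  xc <- x - mean(x)
  c(
    CVbin = if (mean(fr) == 0) 0 else sd(fr) / mean(fr),
    abin = sum(b) / n,
    Frqbin = trans / (n / fs),
    Kurt = mean(xc^4) / mean(xc^2)^2
  )
}

oracle_psr <- function(x, fs) {
  k <- feature_constants()$psr
  lag <- as.integer(k$tau_s * fs)
  n <- length(x)
  lo <- min(x)
  hi <- max(x)
  g <- k$grid
  seen <- matrix(FALSE, g, g)
  for (i in 1:(n - lag)) {
    iu <- min(floor((x[i] - lo) / (hi - lo) * g), g - 1) + 1
    iv <- min(floor((x[i + lag] - lo) / (hi - lo) * g), g - 1) + 1
    seen[iu, iv] <- TRUE
  }
  sum(seen) / g^2
}

oracle_hilb <- function(x) {
  k <- feature_constants()$hilb
  n <- length(x)
  # analytic signal via direct DFT/IDFT with the one-sided multiplier
  ph <- -2 * pi * outer(seq_len(n) - 1, seq_len(n) - 1) / n
  X <- as.vector(exp(1i * ph) %*% x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- as.vector(exp(-1i * ph) %*% (X * h)) / n
  q <- Im(z)
  g <- k$grid
  seen <- matrix(FALSE, g, g)
  for (i in seq_len(n)) {
    iu <- min(floor((x[i] - min(x)) / (max(x) - min(x)) * g), g - 1) + 1
    iv <- min(floor((q[i] - min(q)) / (max(q) - min(q)) * g), g - 1) + 1
    seen[iu, iv] <- TRUE
  }
  sum(seen) / g^2
}

# sample entropy via the full Chebyshev-distance match matrices (closed
# matrix formulation, m = 2), upper triangle, self-matches excluded
oracle_samen <- function(x) {
  k <- feature_constants()$samen
  stopifnot(k$m == 2)
  r <- k$r_sd * sd(x)
  n <- length(x)
  D <- abs(outer(x, x, "-")) <= r
  i2 <- seq_len(n - 2)
  match2 <- D[i2, i2] & D[i2 + 1, i2 + 1]
  match3 <- match2 & D[i2 + 2, i2 + 2]
  B <- sum(match2[upper.tri(match2)])
  A <- sum(match3[upper.tri(match3)])
  -log(A / B)
}

# all 30 raw features of one segment, oracle route
oracle_features <- function(x, fs = 250) {
  c(
    TCI = oracle_tci(x, fs), TCSC = oracle_tcsc(x, fs),
    Exp = oracle_exp(x, fs), Expmod = oracle_expmod(x, fs),
    MAV = oracle_mav(x, fs), oracle_counts(x, fs),
    x1 = oracle_x1(x, fs), x2 = oracle_x2(x, fs), bCP = oracle_bcp(x),
    vFleak = oracle_vfleak(x), oracle_spectral_feats(x, fs),
    oracle_wavelet_feats(x), CM = oracle_cm(x),
    oracle_binary_feats(x, fs), PSR = oracle_psr(x, fs),
    HILB = oracle_hilb(x), SamEn = oracle_samen(x)
  )
}
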