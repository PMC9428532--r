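# FFT-domain signal-processing helpers shared by the room and stimuli modules.
# No IIR filtering package is assumed: every filter here is a zero-phase
# frequency-domain mask with raised-cosine transition bands, applied on a
# zero-padded buffer so circular wrap-around is negligible.

# folded (two-sided) frequency axis of an n-point DFT
freq_axis <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

# raised-cosine transition from 0 at f0 to 1 at f1 (f1 > f0)
rc_edge <- function(f, f0, f1) {
  out <- numeric(length(f))
  out[f >= f1] <- 1
  idx <- f > f0 & f < f1
  out[idx] <- 0.5 - 0.5 * cos(pi * (f[idx] - f0) / (f1 - f0))
  out
}

# zero-phase band-pass amplitude mask with raised-cosine edges.
# `trans_oct` is the transition width in octaves around each edge.
bandpass_mask <- function(n, fs, f_lo = 0, f_hi = fs / 2, trans_oct = 1/3) {
  f <- freq_axis(n, fs)
  m <- rep(1, n)
  if (f_lo > 0) {
    w <- f_lo * (2^(trans_oct / 2) - 2^(-trans_oct / 2))
    m <- m * rc_edge(f, f_lo - w / 2, f_lo + w / 2)
  }
  if (f_hi < fs / 2) {
    w <- f_hi * (2^(trans_oct / 2) - 2^(-trans_oct / 2))
    m <- m * (1 - rc_edge(f, f_hi - w / 2, f_hi + w / 2))
  }
  m
}

# apply an amplitude mask zero-phase, with zero-padding against circular wrap
apply_mask <- function(x, fs, mask_fun, pad = round(0.1 * fs)) {
  n0 <- length(x)
  n <- stats::nextn(n0 + pad, 2)
  m <- mask_fun(n, fs)
  y <- Re(stats::fft(stats::fft(c(x, numeric(n - n0))) * m, inverse = TRUE)) / n
  y[seq_len(n0)]
}

# zero-phase low-pass / high-pass / band-pass convenience wrappers
fft_lowpass <- function(x, fs, f_hi, trans_oct = 1/3)
  apply_mask(x, fs, function(n, fs) bandpass_mask(n, fs, 0, f_hi, trans_oct))

fft_highpass <- function(x, fs, f_lo, trans_oct = 1/3)
  apply_mask(x, fs, function(n, fs) bandpass_mask(n, fs, f_lo, fs / 2, trans_oct))

fft_bandpass <- function(x, fs, f_lo, f_hi, trans_oct = 1/3)
  apply_mask(x, fs, function(n, fs) bandpass_mask(n, fs, f_lo, f_hi, trans_oct))

# DC / infrasound removal: raised cosine from f_stop (0) to f_pass (1).
# Room simulation creates an inaudible DC build-up that must never enter
# level or modulation computations, so this is applied systematically.
remove_dc <- function(x, fs, f_stop = 20, f_pass = 30) {
  apply_mask(x, fs, function(n, fs) {
    f <- freq_axis(n, fs)
    rc_edge(f, f_stop, f_pass)
  })
}

# amplitude-complementary octave filterbank masks: bands partition
# [0, fs/2] at the geometric means of adjacent centres, with raised-cosine
# crossfades, so that sum(masks) == 1 and identical band inputs reconstruct
# the original signal exactly (zero phase).
octave_band_masks <- function(n, fs, centres, trans_oct = 1/3) {
  f <- freq_axis(n, fs)
  nb <- length(centres)
  edges <- sqrt(centres[-1] * centres[-nb])
  lo <- c(0, edges)
  hi <- c(edges, fs / 2)
  M <- matrix(0, n, nb)
  for (b in seq_len(nb)) {
    M[, b] <- as.numeric(f >= lo[b] & f < hi[b])
    for (side in 1:2) {
      e <- if (side == 1) lo[b] else hi[b]
      if (e <= 0 || e >= fs / 2) next
      w <- e * (2^(trans_oct / 2) - 2^(-trans_oct / 2))
      idx <- which(abs(f - e) < w / 2)
      ramp <- 0.5 - 0.5 * cos(pi * (f[idx] - (e - w / 2)) / w)
      M[idx, b] <- if (side == 1) ramp else 1 - ramp
    }
  }
  M
}

# linear FFT convolution (full length: length(x) + length(h) - 1)
fft_convolve <- function(x, h) {
  nx <- length(x); nh <- length(h)
  n <- stats::nextn(nx + nh - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(n - nx))) *
                     stats::fft(c(h, numeric(n - nh))), inverse = TRUE)) / n
  y[seq_len(nx + nh - 1)]
}

# magnitude of the analytic signal (FFT Hilbert method). The input is
# zero-padded to a 2-3-5-smooth length first: R's mixed-radix FFT degrades
# badly on lengths with large prime factors, and envelope edge effects from
# padding are negligible for the multi-second signals analysed here.
analytic_envelope <- function(x) {
  n0 <- length(x)
  n <- smooth_length(n0)
  x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

# smallest 2-3-5-smooth integer >= n (FFT-friendly length)
smooth_length <- function(n) {
  if (n <= 2) return(2L)
  best <- 2^ceiling(log2(n))
  p5 <- 1
  while (p5 < best) {
    p35 <- p5
    while (p35 < best) {
      k <- p35 * 2^max(0, ceiling(log2(n / p35)))
      if (k >= n && k < best) best <- k
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

# largest 2-3-5-smooth integer <= n
smooth_floor <- function(n) {
  best <- 1
  p5 <- 1
  while (p5 <= n) {
    p35 <- p5
    while (p35 <= n) {
      k <- p35 * 2^floor(log2(n / p35))
      if (k > best) best <- k
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

rms <- function(x) sqrt(mean(x^2))

db <- function(ratio) 10 * log10(ratio)

amp_db <- function(x, ref = 1) 20 * log10(rms(x) / ref)

# third-octave band power levels (dB) between f_lo and f_hi, used as the
# testable surrogate for long-term excitation-pattern comparisons
third_octave_levels <- function(x, fs, f_lo = 100, f_hi = 8000) {
  n0 <- length(x)
  n <- smooth_length(n0)
  x <- c(x, numeric(n - n0))
  centres <- 1000 * 2^(seq(-20, 20) / 3)
  centres <- centres[centres >= f_lo & centres <= min(f_hi, fs / 2 / 2^(1/6))]
  X2 <- Mod(stats::fft(x))^2 / n0
  f <- freq_axis(n, fs)
  lev <- vapply(centres, function(fc) {
    sel <- f >= fc * 2^(-1/6) & f < fc * 2^(1/6)
    sum(X2[sel])
  }, numeric(1))
  data.frame(centre = centres, power = lev, level_db = 10 * log10(lev))
}

# 10 ms raised-cosine on/off ramps (in place over the first/last ramp_s)
apply_ramps <- function(x, fs, ramp_s = 0.010) {
  nr <- min(round(ramp_s * fs), floor(length(x) / 2))
  if (nr < 1) return(x)
  r <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 0.5) / nr)
  x[seq_len(nr)] <- x[seq_len(nr)] * r
  x[(length(x) - nr + 1):length(x)] <- x[(length(x) - nr + 1):length(x)] * rev(r)
  x
}
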