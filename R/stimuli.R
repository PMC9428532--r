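# Target and masker construction: synthetic speech tokens, noise vocoding,
# phase-randomized stationary noise, long-term spectral matching, envelope
# modulation spectra, and reverberant mixing at a prescribed SNR.

# digital level convention: 0 dBFS RMS corresponds to this many dB SPL
DBFS_REF_SPL <- 100

#' Construct a signal object
#'
#' @param samples numeric amplitude sequence.
#' @param fs sample rate in Hz.
#' @param label role tag: `"target"`, `"masker_mod"`, `"masker_stat"` or
#'   `"other"`.
#' @return object of class `signal`.
#' @export
signal <- function(samples, fs, label = "other") {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("signal samples must be finite")
  if (label %in% c("target", "masker_mod", "masker_stat") &&
      (length(samples) == 0 || rms(samples) == 0))
    stop("a '", label, "' signal must not be silent")
  structure(list(samples = samples, fs = fs, label = label), class = "signal")
}

#' @exportS3Method base::print
print.signal <- function(x, ...) {
  cat(sprintf("signal [%s]: %.2f s at %g Hz, RMS %.4g\n", x$label,
              length(x$samples) / x$fs, x$fs, rms(x$samples)))
  invisible(x)
}

# speech-shaped spectral amplitude: flat below the knee, then falling.
# Approximates a long-term average speech spectrum closely enough for
# masker construction tests (the real corpus is copyrighted).
speech_shape <- function(f, knee = 500, slope_db_oct = -8) {
  a <- rep(1, length(f))
  hi <- f > knee
  a[hi] <- 10^(slope_db_oct * log2(f[hi] / knee) / 20)
  a[f < 100] <- a[f < 100] * (f[f < 100] / 100)^2
  a
}

#' Generate a synthetic matrix-style sentence
#'
#' A stand-in for a recorded five-word closed-set sentence: a sequence of
#' consonant-vowel-like noise bursts with a speech-shaped long-term spectrum
#' and a syllabic (3-5 Hz) envelope. Not intelligible speech; it carries the
#' spectro-temporal statistics the masker pipeline needs.
#'
#' @param n_syllables number of syllabic bursts (a five-word sentence has
#'   around 7).
#' @param fs sample rate, Hz.
#' @param seed RNG seed (sentences are seed-deterministic).
#' @return a `signal` with label `"target"`.
#' @export
synth_sentence <- function(n_syllables = 7, fs = 16000, seed = 1) {
  with_seed(seed, {
    parts <- list()
    for (s in seq_len(n_syllables)) {
      dur <- stats::runif(1, 0.12, 0.20)
      gap <- stats::runif(1, 0.04, 0.10)
      n <- round(dur * fs)
      env <- (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n))^0.7
      burst <- stats::rnorm(n) * env
      parts[[length(parts) + 1]] <- burst
      parts[[length(parts) + 1]] <- numeric(round(gap * fs))
    }
    x <- unlist(parts)
    x <- c(x, numeric(smooth_length(length(x)) - length(x))) # FFT-friendly
    # impose the speech-shaped long-term spectrum, zero phase
    x <- apply_mask(x, fs, function(n, fs) speech_shape(freq_axis(n, fs)))
    x <- x / max(rms(x), .Machine$double.eps)
    signal(x, fs, "target")
  })
}

#' Generate a corpus of synthetic sentences
#'
#' @param n_sentences corpus size (the masker recipe uses 288 source
#'   sentences).
#' @param fs sample rate, Hz.
#' @param seed RNG seed; sentence `i` uses sub-seed `seed + i`.
#' @return list of `signal` objects.
#' @export
synth_corpus <- function(n_sentences, fs = 16000, seed = 1) {
  lapply(seq_len(n_sentences), function(i)
    synth_sentence(fs = fs, seed = seed * 1000L + i))
}

#' Randomize the phase spectrum of a signal
#'
#' Keeps the magnitude spectrum exactly and draws new phases uniformly,
#' producing a stationary noise with the same long-term spectrum as the
#' input (the standard recipe for a spectrum-matched stationary masker).
#'
#' @param sig a `signal`.
#' @param seed RNG seed (same seed, same output).
#' @return a `signal` with label `"masker_stat"`.
#' @export
phase_randomize <- function(sig, seed = 1) {
  stopifnot(inherits(sig, "signal"))
  x <- sig$samples
  n <- length(x)
  if (n == 0) stop("empty input")
  X <- stats::fft(x)
  mag <- Mod(X)
  with_seed(seed, {
    half <- floor((n - 1) / 2)
    ph <- stats::runif(half, 0, 2 * pi)
    Y <- complex(real = numeric(n), imaginary = numeric(n))
    Y[1] <- mag[1] # DC stays real
    if (half > 0) {
      idx <- 2:(half + 1)
      Y[idx] <- mag[idx] * exp(1i * ph)
      Y[n + 2 - idx] <- Conj(Y[idx])
    }
    if (n %% 2 == 0) # Nyquist bin stays real, random sign
      Y[n / 2 + 1] <- mag[n / 2 + 1] * sign(stats::runif(1) - 0.5)
    y <- Re(stats::fft(Y, inverse = TRUE)) / n
    signal(y, sig$fs, "masker_stat")
  })
}

# ERB-rate scale (Glasberg & Moore)
hz_to_erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Noise-vocode a sentence corpus into a one-voice vocoded stream
#'
#' The sentences are concatenated, split into `n_channels` bands with edges
#' equally spaced on an ERB scale over \[100 Hz, min(8 kHz, Nyquist)\]; each
#' band's envelope (magnitude of the analytic signal, low-passed at
#' `env_cutoff`) is imposed on a band-limited noise carrier and the channels
#' are summed.
#'
#' @param corpus list of `signal` objects (sentences).
#' @param n_channels number of vocoder channels (default 3).
#' @param env_cutoff envelope low-pass cut-off, Hz (default 60).
#' @param seed RNG seed for the noise carriers.
#' @return a `signal` with label `"masker_mod"` (one voice).
#' @export
vocode <- function(corpus, n_channels = 3, env_cutoff = 60, seed = 1) {
  if (length(corpus) == 0) stop("empty corpus")
  stopifnot(all(vapply(corpus, inherits, logical(1), "signal")))
  fs <- corpus[[1]]$fs
  if (env_cutoff >= fs / 2) stop("env_cutoff must be below Nyquist")
  if (n_channels < 1) stop("n_channels must be >= 1")
  x <- unlist(lapply(corpus, `[[`, "samples"))
  f_hi <- min(8000, 0.95 * fs / 2)
  edges <- erb_to_hz(seq(hz_to_erb(100), hz_to_erb(f_hi),
                         length.out = n_channels + 1))
  n <- length(x)
  out <- numeric(n)
  with_seed(seed, {
    for (ch in seq_len(n_channels)) {
      band <- fft_bandpass(x, fs, edges[ch], edges[ch + 1])
      env <- analytic_envelope(band)
      env <- pmax(fft_lowpass(env, fs, env_cutoff), 0)
      carrier <- fft_bandpass(stats::rnorm(n), fs, edges[ch], edges[ch + 1])
      cr <- rms(carrier)
      if (cr > 0) carrier <- carrier / cr
      out <- out + carrier * env
    }
  })
  structure(signal(if (all(out == 0)) out else out, fs,
                   if (all(out == 0)) "other" else "masker_mod"),
            n_channels = n_channels, env_cutoff = env_cutoff)
}

#' Build the two-voice speech-modulated masker
#'
#' Splits the source corpus into two halves, vocodes each half into a
#' one-voice stream (independent carriers) and sums the two streams,
#' truncated to the shorter one.
#'
#' @param corpus list of `signal` sentences (the study recipe uses 288,
#'   yielding two 144-sentence streams).
#' @inheritParams vocode
#' @return a `signal` with label `"masker_mod"`; attributes
#'   `sentences_per_stream` and `n_streams = 2`.
#' @export
make_modulated_masker <- function(corpus, n_channels = 3, env_cutoff = 60,
                                  seed = 1) {
  if (length(corpus) < 2) stop("need at least two sentences to form two streams")
  half <- as.integer(length(corpus) %/% 2)
  s1 <- vocode(corpus[seq_len(half)], n_channels, env_cutoff, seed = seed)
  s2 <- vocode(corpus[(half + 1):(2 * half)], n_channels, env_cutoff,
               seed = seed + 1)
  n <- min(length(s1$samples), length(s2$samples))
  structure(signal(s1$samples[seq_len(n)] + s2$samples[seq_len(n)],
                   s1$fs, "masker_mod"),
            sentences_per_stream = half, n_streams = 2L)
}

#' Build the spectrum-matched stationary masker
#'
#' Concatenates the source sentences and randomizes the phase spectrum:
#' same long-term spectrum, no envelope modulation.
#'
#' @param corpus list of `signal` sentences.
#' @param seed RNG seed.
#' @return a `signal` with label `"masker_stat"`.
#' @export
make_stationary_masker <- function(corpus, seed = 1) {
  if (length(corpus) == 0) stop("empty corpus")
  x <- unlist(lapply(corpus, `[[`, "samples"))
  # trim to an FFT-friendly length (a few ms at most; the DFT of an
  # awkward-length concatenation is needlessly expensive)
  x <- x[seq_len(smooth_floor(length(x)))]
  phase_randomize(signal(x, corpus[[1]]$fs, "target"), seed = seed)
}

#' Match the long-term spectrum of a signal to a reference
#'
#' Designs a linear-phase FIR whose magnitude response is the third-octave
#' level difference between `reference` and `signal` (interpolated across
#' frequency) and applies it, so the output's long-term third-octave
#' spectrum matches the reference within about 1 dB per band over
#' \[100, 8000\] Hz.
#'
#' @param sig a `signal` to be re-shaped.
#' @param reference a `signal` providing the target spectrum.
#' @param fir_length FIR length in taps (default 1024).
#' @return the filtered `signal` (label preserved), RMS-matched to the
#'   input.
#' @export
spectral_match <- function(sig, reference, fir_length = 1024) {
  stopifnot(inherits(sig, "signal"), inherits(reference, "signal"))
  if (rms(sig$samples) == 0 || rms(reference$samples) == 0)
    stop("both signals must be non-silent")
  fs <- sig$fs
  ls <- third_octave_levels(sig$samples, fs)
  lr <- third_octave_levels(reference$samples, fs)
  if (any(!is.finite(lr$level_db)))
    stop("reference has empty third-octave bands")
  # per-sample spectral density difference (bandwidth cancels)
  gain_db <- (lr$level_db - ls$level_db)
  # interpolate gain over log-frequency, flat extrapolation
  nfir <- fir_length
  f <- freq_axis(nfir, fs)
  lf <- log(pmax(f, 1))
  g <- stats::approx(log(ls$centre), gain_db, xout = lf, rule = 2)$y
  amp <- 10^(g / 20)
  # zero-phase prototype -> linear phase by circular shift + Hann window
  h <- Re(stats::fft(amp, inverse = TRUE)) / nfir
  h <- c(h[(nfir / 2 + 1):nfir], h[1:(nfir / 2)])
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfir) - 0.5) / nfir)
  h <- h * w
  y <- fft_convolve(sig$samples, h)
  y <- y[seq_along(sig$samples) + round(nfir / 2)]
  y <- y * rms(sig$samples) / rms(y)
  signal(y, fs, sig$label)
}

#' Envelope modulation spectrum in octave bands 1-16 Hz
#'
#' Extracts the envelope (magnitude of the analytic signal), divides it by
#' its mean, removes the DC component, and integrates the power spectrum in
#' octave bands centred at 1, 2, 4, 8 and 16 Hz.
#'
#' @param sig a `signal` of at least 2 s (to resolve the 1 Hz band).
#' @return object of class `modulation_spectrum`: data.frame with
#'   `band_centre` (Hz), `power` (linear, normalized-envelope units) and
#'   `level_db`.
#' @export
modulation_spectrum <- function(sig) {
  stopifnot(inherits(sig, "signal"))
  x <- sig$samples; fs <- sig$fs
  if (length(x) / fs < 2) stop("signal must be at least 2 s long")
  env <- analytic_envelope(x)
  m <- mean(env)
  if (m <= 0) stop("silent signal: mean envelope is zero")
  env <- env / m - 1
  n0 <- length(env)
  n <- smooth_length(n0) # FFT-friendly length; padding adds no band power
  env <- c(env, numeric(n - n0))
  P <- Mod(stats::fft(env))^2 / n0^2  # power relative to squared mean
  f <- freq_axis(n, fs)
  centres <- c(1, 2, 4, 8, 16)
  pow <- vapply(centres, function(fc) {
    sel <- f >= fc / sqrt(2) & f < fc * sqrt(2)
    2 * sum(P[sel & seq_len(n) <= n / 2 + 1]) # one-sided
  }, numeric(1))
  structure(data.frame(band_centre = centres, power = pow,
                       level_db = 10 * log10(pmax(pow, 1e-300))),
            class = c("modulation_spectrum", "data.frame"))
}

#' Assemble a single trial stimulus
#'
#' Applies reverberation to target and/or masker, draws a random masker
#' excerpt one second longer than the (reverberated) target with a uniform
#' 300-700 ms onset lead, gates the excerpt with 10 ms raised-cosine ramps,
#' fixes the target presentation level and sets the masker level to realize
#' the requested SNR (broadband RMS over the target's extent, measured
#' after reverberation).
#'
#' @param target a `signal` (dry target sentence).
#' @param masker a long `signal` (dry masker stream).
#' @param snr signal-to-noise ratio in dB.
#' @param reverb_application one of `"speech_only"`, `"noise_only"`,
#'   `"both"`, `"none"`.
#' @param rirs list with elements `speech` and `noise` (normalized `rir`
#'   objects); only the ones required by `reverb_application` are used.
#' @param seed RNG seed (excerpt position and onset lead).
#' @param target_level_db target presentation level, dB SPL (digital
#'   convention: 0 dBFS RMS = 100 dB SPL).
#' @param rt_label nominal reverberation-time label carried as metadata.
#' @return object of class `trial_stimulus`: `target`, `masker` (aligned,
#'   equal length), `mix`, `masker_start` (sample index of the excerpt in
#'   the source masker), `snr`, `onset_lead` (s), `reverb_application`,
#'   `rt_label`, `target_level_db`, `fs`.
#' @export
make_trial_stimulus <- function(target, masker, snr,
                                reverb_application = c("none", "speech_only",
                                                       "noise_only", "both"),
                                rirs = NULL, seed = 1,
                                target_level_db = 50, rt_label = NA_real_) {
  reverb_application <- match.arg(reverb_application)
  stopifnot(inherits(target, "signal"), inherits(masker, "signal"))
  if (!is.finite(snr)) stop("snr must be finite")
  fs <- target$fs
  conv <- function(x, r) {
    stopifnot(inherits(r, "rir"))
    fft_convolve(x, r$samples)
  }
  tgt <- target$samples
  msk <- masker$samples
  if (reverb_application %in% c("speech_only", "both"))
    tgt <- conv(tgt, rirs$speech)
  if (reverb_application %in% c("noise_only", "both"))
    msk <- conv(msk, rirs$noise)

  n_t <- length(tgt)
  n_exc <- n_t + round(1 * fs)                 # excerpt = target + 1 s
  if (length(msk) < n_exc)
    stop("masker shorter than target + 1 s")
  with_seed(seed, {
    start <- sample.int(length(msk) - n_exc + 1, 1)
    onset_lead <- stats::runif(1, 0.300, 0.700)
  })
  exc <- apply_ramps(msk[start:(start + n_exc - 1)], fs)
  lead_n <- round(onset_lead * fs)
  tgt_al <- c(numeric(lead_n), tgt, numeric(n_exc - n_t - lead_n))

  # calibration: target at fixed level; masker level realizes the SNR,
  # both measured as broadband RMS over the target's extent
  tgt_rms_target <- 10^((target_level_db - DBFS_REF_SPL) / 20)
  tgt_al <- tgt_al * tgt_rms_target / rms(tgt)
  span <- (lead_n + 1):(lead_n + n_t)
  msk_rms <- rms(exc[span])
  exc <- exc * tgt_rms_target * 10^(-snr / 20) / msk_rms

  structure(list(target = signal(tgt_al, fs, "target"),
                 masker = signal(exc, fs, masker$label),
                 mix = signal(tgt_al + exc, fs, "other"),
                 masker_start = start,
                 snr = snr, onset_lead = onset_lead,
                 reverb_application = reverb_application,
                 rt_label = rt_label, target_level_db = target_level_db,
                 fs = fs),
            class = "trial_stimulus")
}

#' @exportS3Method base::print
print.trial_stimulus <- function(x, ...) {
  cat(sprintf(
    "trial stimulus: SNR %+g dB, reverb '%s' (RT label %s), onset lead %.0f ms\n",
    x$snr, x$reverb_application, x$rt_label, 1000 * x$onset_lead))
  invisible(x)
}
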