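# stimuli module: phase randomization, vocoding, spectral matching,
# modulation spectra, trial assembly

test_that("phase randomization preserves the magnitude spectrum exactly", {
  s <- synth_sentence(seed = 5)
  pr <- phase_randomize(s, seed = 9)
  expect_equal(length(pr$samples), length(s$samples))
  m0 <- Mod(stats::fft(s$samples)); m1 <- Mod(stats::fft(pr$samples))
  expect_lt(max(abs(m1 - m0)) / max(m0), 1e-6)
  expect_identical(pr$samples, phase_randomize(s, seed = 9)$samples)
  expect_false(identical(pr$samples, phase_randomize(s, seed = 10)$samples))
})

test_that("phase randomization flattens the 1-16 Hz modulation spectrum", {
  corp <- synth_corpus(10, seed = 2)
  xs <- unlist(lapply(corp, `[[`, "samples"))
  xs <- xs[seq_len(revspeech:::smooth_floor(length(xs)))]
  x <- signal(xs, 16000, "target")
  ms_in <- modulation_spectrum(x)
  ms_out <- modulation_spectrum(phase_randomize(x, seed = 1))
  drop_db <- 10 * log10(sum(ms_in$power) / sum(ms_out$power))
  expect_gt(drop_db, 10)
})

test_that("vocoder imposes the band envelope on noise carriers", {
  fs <- 16000
  # band-limited AM input: 1 kHz-centred noise with a 3 Hz envelope
  n <- 6 * fs; t <- (seq_len(n) - 1) / fs
  env <- 1 + 0.95 * sin(2 * pi * 3 * t)
  set.seed(4)
  carrier <- revspeech:::fft_bandpass(rnorm(n), fs, 700, 1400)
  x <- signal(carrier * env, fs, "target")
  v <- vocode(list(x), n_channels = 3, seed = 6)
  env_out <- revspeech:::fft_lowpass(revspeech:::analytic_envelope(v$samples),
                                     fs, 20)
  expect_gt(stats::cor(env_out, env), 0.8)
  # silent corpus -> silent output
  sil <- structure(list(samples = numeric(fs), fs = fs, label = "other"),
                   class = "signal")
  expect_equal(max(abs(vocode(list(sil), seed = 1)$samples)), 0)
  expect_error(vocode(list()), "empty corpus")
})

test_that("two-voice masker splits the corpus into equal streams", {
  corp <- synth_corpus(12, seed = 3)
  mm <- make_modulated_masker(corp, seed = 5)
  expect_identical(attr(mm, "sentences_per_stream"), 6L)
  expect_identical(attr(mm, "n_streams"), 2L)
  expect_identical(mm$label, "masker_mod")
})

test_that("spectral matching reaches the long-term reference spectrum", {
  fs <- 16000
  tol <- revspeech:::third_octave_levels
  dev_db <- function(a, b) {
    la <- tol(a, fs)$level_db; lb <- tol(b, fs)$level_db
    max(abs((la - mean(la)) - (lb - mean(lb))))
  }
  set.seed(8)
  # identity: reference == signal
  w <- signal(rnorm(fs * 8), fs, "other")
  expect_lt(dev_db(spectral_match(w, w)$samples, w$samples), 0.5)
  # white noise matched to a pink reference recovers the -3 dB/oct slope
  pink <- signal(revspeech:::apply_mask(rnorm(fs * 8), fs, function(n, fs)
    1 / sqrt(pmax(revspeech:::freq_axis(n, fs), 1))), fs, "other")
  expect_lt(dev_db(spectral_match(w, pink)$samples, pink$samples), 1)
  # stationary masker matched to the speech corpus spectrum
  corp <- synth_corpus(8, seed = 2)
  tgt <- signal(unlist(lapply(corp, `[[`, "samples")), fs, "target")
  sm <- spectral_match(make_stationary_masker(corp, seed = 3), tgt)
  expect_lt(dev_db(sm$samples, tgt$samples), 1)
  expect_error(spectral_match(signal(numeric(100), fs), w), "non-silent")
})

test_that("modulation spectrum isolates the imposed AM rate", {
  fs <- 16000; n <- 6 * fs; t <- (seq_len(n) - 1) / fs
  tone <- signal(sin(2 * pi * 1000 * t), fs, "other")
  ms_tone <- modulation_spectrum(tone)
  expect_lt(max(ms_tone$power), 1e-6)
  am <- signal(sin(2 * pi * 1000 * t) * (1 + sin(2 * pi * 4 * t)), fs, "other")
  ms_am <- modulation_spectrum(am)
  expect_equal(ms_am$band_centre[which.max(ms_am$power)], 4)
  # sinusoidal AM of depth 1: normalized-envelope power 1/2 in the 4 Hz band
  expect_equal(ms_am$power[ms_am$band_centre == 4], 0.5, tolerance = 0.01)
  expect_error(modulation_spectrum(signal(numeric(fs), fs)), "at least 2 s")
  expect_error(modulation_spectrum(signal(rep(0, 3 * fs), fs)), "silent")
})

test_that("reverberation reduces masker modulation in every band", {
  corp <- synth_corpus(10, seed = 12)
  mm <- make_modulated_masker(corp, seed = 13)
  r_lo <- quick_rir(0.15, seed = 2)
  r_hi <- quick_rir(1.5, seed = 2)
  conv <- function(sig, r) signal(
    revspeech:::fft_convolve(sig$samples, r$samples), sig$fs, sig$label)
  ms_lo <- modulation_spectrum(conv(mm, r_lo))
  ms_hi <- modulation_spectrum(conv(mm, r_hi))
  expect_true(all(ms_hi$power < ms_lo$power))
})

test_that("trial stimulus realizes level, timing and reverb routing", {
  fs <- 16000
  corp <- synth_corpus(10, seed = 21)
  masker <- make_stationary_masker(corp, seed = 22)
  target <- corp[[1]]
  rirs <- list(speech = quick_rir(0.8, seed = 1),
               noise = quick_rir(0.8, seed = 1))
  ts <- make_trial_stimulus(target, masker, snr = 0, "none", seed = 30)
  # snr 0: equal RMS over the target extent, within 0.1 dB
  lead_n <- round(ts$onset_lead * fs)
  span <- (lead_n + 1):(lead_n + length(target$samples))
  lvl_diff <- 20 * log10(revspeech:::rms(ts$target$samples[span]) /
                         revspeech:::rms(ts$masker$samples[span]))
  expect_lt(abs(lvl_diff - 0), 0.1)
  # masker one second longer than the target
  expect_equal(length(ts$masker$samples), length(target$samples) + fs)
  # speech_only never convolves the masker: the excerpt equals the dry
  # source segment up to ramps and a level scalar
  ts_sp <- make_trial_stimulus(target, masker, 0, "speech_only",
                               rirs = rirs, seed = 30)
  n_exc <- length(ts_sp$masker$samples)
  dry <- revspeech:::apply_ramps(
    masker$samples[ts_sp$masker_start:(ts_sp$masker_start + n_exc - 1)], fs)
  expect_gt(abs(stats::cor(ts_sp$masker$samples, dry)), 1 - 1e-12)
  # ... while 'both' does convolve it
  ts_bo <- make_trial_stimulus(target, masker, 0, "both",
                               rirs = rirs, seed = 30)
  dry_bo <- revspeech:::apply_ramps(
    masker$samples[ts_bo$masker_start:(ts_bo$masker_start +
                                       length(ts_bo$masker$samples) - 1)], fs)
  expect_lt(abs(stats::cor(ts_bo$masker$samples, dry_bo)), 0.99)
  # short masker errors
  expect_error(make_trial_stimulus(target, corp[[2]], 0, "none", seed = 1),
               "shorter")
})

test_that("onset leads are uniform on [300, 700] ms", {
  corp <- synth_corpus(4, seed = 31)
  masker <- make_stationary_masker(corp, seed = 32)
  target <- synth_sentence(n_syllables = 2, seed = 33)
  leads <- vapply(seq_len(1000), function(i)
    make_trial_stimulus(target, masker, 0, "none", seed = i)$onset_lead,
    numeric(1))
  expect_true(all(leads >= 0.3 & leads <= 0.7))
  ks <- suppressWarnings(stats::ks.test(leads, "punif", 0.3, 0.7))
  expect_gt(ks$p.value, 0.01)
})
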