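# room module: absorption scaling, RIR synthesis, RT / DRR metrics

test_that("scale_absorption divides per band and validates", {
  base <- c(17.4, 20.7, 28.8, 29.1, 29.7, 27.3) / 100
  expect_identical(scale_absorption(base, 1), base)
  expect_equal(scale_absorption(base, 2) * 100,
               c(8.7, 10.35, 14.4, 14.55, 14.85, 13.65))
  expect_equal(scale_absorption(base, 3) * 100,
               c(5.8, 6.9, 9.6, 9.7, 9.9, 9.1))
  expect_error(scale_absorption(base, 0.17), "invalid absorption")
  expect_error(scale_absorption(base, -1), "positive")
})

test_that("room_spec validates geometry and absorption", {
  expect_error(room_spec(c(5, 9, 2.7), rep(0.3, 6), c(0, 1, 1), c(2, 2, 1)),
               "inside the room")
  expect_error(room_spec(c(5, 9, 2.7), rep(1.2, 6), c(1, 1, 1), c(2, 2, 1)),
               "absorption")
  expect_error(simulate_rir(room_spec(c(5, 9, 2.7), rep(0.3, 6),
                                      c(1, 1, 1), c(1, 1, 1))),
               "degenerate")
})

test_that("near-anechoic RIR is dominated by the direct sound", {
  spec <- room_spec(c(5, 9, 2.7), rep(0.999, 6),
                    c(1.75, 3.75, 1.5), c(3.25, 5, 1.5))
  r <- simulate_rir(spec, duration = 0.3, seed = 1)
  expect_gt(direct_to_reverberant_ratio(r), 8) # rev-to-direct < -8 dB
})

test_that("RIR synthesis is bit-deterministic given spec and seed", {
  a <- simulate_rir(virtual_room(0.5), duration = 0.5, seed = 7)
  b <- simulate_rir(virtual_room(0.5), duration = 0.5, seed = 7)
  c2 <- simulate_rir(virtual_room(0.5), duration = 0.5, seed = 8)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c2$samples))
})

test_that("normalization gives unit energy and leaves DRR unchanged", {
  r <- simulate_rir(virtual_room(0.8), seed = 2)
  rn <- normalize_energy(r)
  expect_equal(sum(rn$samples^2), 1, tolerance = 1e-9)
  expect_equal(direct_to_reverberant_ratio(rn),
               direct_to_reverberant_ratio(r), tolerance = 1e-12)
  silent <- structure(list(samples = numeric(100), fs = 16000,
                           direct_arrival_index = 1L), class = "rir")
  expect_error(normalize_energy(silent), "silent")
})

test_that("convolution with normalized RIRs preserves broadband RMS", {
  set.seed(3)
  x <- rnorm(16000)
  r1 <- quick_rir(0.5, seed = 4)
  r2 <- quick_rir(1.5, seed = 4)
  lvl <- function(y) 20 * log10(sqrt(mean(y^2)))
  y1 <- revspeech:::fft_convolve(x, r1$samples)[seq_along(x)]
  y2 <- revspeech:::fft_convolve(x, r2$samples)[seq_along(x)]
  expect_lt(abs(lvl(y1) - lvl(x)), 1)
  expect_lt(abs(lvl(y2) - lvl(x)), 1)
})

test_that("T30 recovers an exact exponential decay", {
  fs <- 16000; T <- 0.6
  t <- (0:(fs * 1.4 - 1)) / fs
  set.seed(5)
  h <- rnorm(length(t)) * 10^(-3 * t / T)
  r <- structure(list(samples = h, fs = fs, direct_arrival_index = 1L),
                 class = "rir")
  expect_equal(reverberation_time(r), T, tolerance = 0.02)
})

test_that("insufficient decay range is flagged, not silently returned", {
  r <- simulate_rir(virtual_room(1.5), duration = 0.25, seed = 1)
  rt <- reverberation_time(r)
  expect_identical(attr(rt, "flag"), "insufficient_decay")
})

test_that("Schroeder curve is non-increasing", {
  r <- simulate_rir(virtual_room(0.8), seed = 6)
  sc <- schroeder_curve(r)
  expect_true(all(diff(sc$level_db) <= 1e-12))
})

test_that("DRR handles the degenerate and symmetric cases", {
  fs <- 16000
  delta <- structure(list(samples = c(numeric(50), 1, numeric(10)), fs = fs,
                          direct_arrival_index = 51L), class = "rir")
  expect_identical(direct_to_reverberant_ratio(delta), Inf)
  # equal direct and tail energies -> 0 dB
  h <- numeric(400); h[51] <- 1; h[200] <- 1
  r <- structure(list(samples = h, fs = fs, direct_arrival_index = 51L),
                 class = "rir")
  expect_equal(direct_to_reverberant_ratio(r), 0)
})

test_that("halving absorption increases the reverberation time", {
  spec1 <- virtual_room(0.5)
  spec2 <- room_spec(spec1$dimensions, spec1$absorption / 2,
                     spec1$source, spec1$receiver, fs = spec1$fs)
  rt1 <- as.numeric(reverberation_time(simulate_rir(spec1, seed = 1)))
  rt2 <- as.numeric(reverberation_time(simulate_rir(spec2, seed = 1)))
  expect_gt(rt2, rt1)
})

test_that("per-band T30 tracks the Sabine prediction for alpha <= 0.15", {
  spec <- virtual_room(0.8) # base absorption / 2: all bands <= 0.1485
  expect_true(all(spec$absorption <= 0.15))
  r <- simulate_rir(spec, seed = 9)
  V <- prod(spec$dimensions)
  S <- 2 * sum(spec$dimensions * spec$dimensions[c(2, 3, 1)])
  sabine <- 0.161 * V / (S * spec$absorption)
  for (b in seq_along(OCTAVE_CENTRES)) {
    rt <- as.numeric(reverberation_time(r, OCTAVE_CENTRES[b]))
    expect_lt(abs(rt - sabine[b]) / sabine[b], 0.25)
  }
})

test_that("RIR WAV round trip preserves samples and metadata", {
  r <- normalize_energy(simulate_rir(virtual_room(0.5), duration = 0.4,
                                     seed = 3))
  path <- tempfile(fileext = ".wav")
  write_rir(r, path)
  r2 <- read_rir(path)
  expect_equal(r2$fs, r$fs)
  expect_equal(r2$direct_arrival_index, r$direct_arrival_index)
  expect_equal(r2$samples, r$samples, tolerance = 1e-6) # float32 storage
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$seed, 3)
  unlink(c(path, paste0(path, ".json")))
})
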