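# psychometric fitting, RAU, derived statistics

test_that("sigmoid anchors hold at machine precision", {
  m <- -4; w <- 8
  for (g in c(0, 0.1)) for (l in c(0, 0.02, 0.05)) {
    expect_equal(psychometric(m, m, w, g, l), g + (1 - g - l) / 2)
    expect_equal(psychometric(m + w / 2, m, w, g, l), g + (1 - g - l) * 0.95)
    expect_equal(psychometric(m - w / 2, m, w, g, l), g + (1 - g - l) * 0.05)
  }
  expect_equal(psychometric(-4, -4, 8, 0.1, 0.02), 0.54)
  expect_error(psychometric(0, 0, -1), "w must be")
})

test_that("RAU closed form and monotonicity", {
  expect_equal(rau(0), -23)
  expect_equal(rau(1), 123)
  expect_equal(rau(0.5), 50)
  p <- seq(0, 1, 0.01)
  expect_true(all(diff(rau(p)) > 0))
  expect_error(rau(1.2), "0, 1")
  # integer-score form stays within the same range and ordering
  expect_true(all(diff(rau_score(0:50, 50)) > 0))
  expect_equal(rau_score(25, 50), 50, tolerance = 1)
})

test_that("rau of the psychometric curve preserves SNR ordering", {
  snr <- seq(-20, 5, 0.5)
  r <- rau(psychometric(snr, -6, 9, 0.1, 0.03))
  expect_true(all(diff(r) > 0))
})

test_that("ML fitting recovers parameters from dense data", {
  snrs <- seq(-14, 2, 4)
  truth <- list(m = -7, w = 8, lambda = 0.02)
  set.seed(101)
  k <- rbinom(length(snrs), 5000,
              psychometric(snrs, truth$m, truth$w, 0.1, truth$lambda))
  f <- fit_psychometric(snrs, k, rep(5000, length(snrs)))
  expect_true(f$converged)
  expect_lt(abs(f$m - truth$m), 0.2)
  expect_lt(abs(f$w - truth$w) / truth$w, 0.1)
})

test_that("fitting is invariant to SNR-axis translation", {
  snrs <- seq(-14, 2, 4)
  set.seed(102)
  k <- rbinom(length(snrs), 50, psychometric(snrs, -6, 8, 0.1, 0.01))
  f0 <- fit_psychometric(snrs, k, rep(50, length(snrs)))
  f1 <- fit_psychometric(snrs + 7.5, k, rep(50, length(snrs)))
  expect_equal(f1$m - f0$m, 7.5, tolerance = 1e-3)
  expect_equal(f1$w, f0$w, tolerance = 1e-3)
})

test_that("floor-only data are flagged non-converged", {
  snrs <- seq(-14, 2, 4)
  set.seed(103)
  f <- fit_psychometric(snrs, rbinom(length(snrs), 50, 0.1),
                        rep(50, length(snrs)))
  expect_false(f$converged)
  expect_error(fit_psychometric(c(-4, 0), c(10, 20), c(50, 50)), "3 distinct")
})

test_that("group-mean curve averages parameters", {
  mk <- function(m, w) structure(list(m = m, w = w, gamma = 0.1,
                                      lambda = 0.01, loglik = 0,
                                      converged = TRUE, shape = "logistic"),
                                 class = "psychometric_fit")
  g <- mean_group_curve(list(mk(-6, 8), mk(-2, 10)))
  expect_equal(g$m, -4)
  expect_equal(g$w, 9)
  expect_equal(predict(g, g$m), 0.1 + (1 - 0.1 - 0.01) / 2)
  g1 <- mean_group_curve(list(mk(-6, 8), mk(-6, 8)))
  expect_equal(g1$m, -6)
  expect_error(mean_group_curve(list()), "length")
})

test_that("optimal SNR maximizes in-bounds scores with low-SNR tie break", {
  mk <- function(m) structure(list(m = m, w = 6, gamma = 0.1, lambda = 0,
                                   converged = TRUE, shape = "logistic"),
                              class = "psychometric_fit")
  # all fits inside bounds only at -4
  fits <- lapply(c(-5, -4, -3), mk)
  expect_equal(as.numeric(optimal_snr(fits, c(-20, -4, 12))), -4)
  # symmetric tie -> lower SNR
  fits2 <- list(mk(-6), mk(-2))
  cnt <- attr(optimal_snr(fits2, c(-6, -2)), "counts")
  expect_equal(unname(cnt[1]), unname(cnt[2]))
  expect_equal(as.numeric(optimal_snr(fits2, c(-6, -2))), -6)
  expect_error(optimal_snr(fits, numeric(0)), "empty")
  # brute-force oracle on a random cohort
  set.seed(104)
  fits3 <- lapply(runif(40, -12, 0), mk)
  grid <- seq(-16, 4, 2)
  counts <- sapply(grid, function(s)
    sum(sapply(fits3, function(f) {p <- predict(f, s); p > 0.15 && p < 0.95})))
  oracle <- grid[which.max(counts)] # which.max takes the first (lowest) max
  expect_equal(as.numeric(optimal_snr(fits3, grid)), oracle)
})

test_that("dip benefit behaves at identity, ceiling, and shifted curves", {
  mk <- function(m) structure(list(m = m, w = 8, gamma = 0.1, lambda = 0.01,
                                   converged = TRUE, shape = "logistic"),
                              class = "psychometric_fit")
  expect_equal(dip_benefit(mk(-6), mk(-6), -6), 0)
  expect_lt(abs(dip_benefit(mk(-10), mk(-6), 30)), 0.5) # both at ceiling
  expect_gt(dip_benefit(mk(-10), mk(-6), -8), 5)        # mid-slope
})

test_that("SRT closed form matches root finding", {
  mk <- function(g, l) structure(list(m = -5, w = 9, gamma = g, lambda = l,
                                      converged = TRUE, shape = "logistic"),
                                 class = "psychometric_fit")
  expect_equal(srt(mk(0, 0)), -5)
  expect_lt(srt(mk(0.1, 0)), -5)
  f <- mk(0.1, 0.03)
  root <- stats::uniroot(function(s) predict(f, s) - 0.5, c(-30, 20),
                         tol = 1e-9)$root
  expect_equal(srt(f), root, tolerance = 1e-6)
  expect_error(srt(mk(0.6, 0)), "not attainable")
})
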