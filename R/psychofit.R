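# Psychometric-function machinery: the logistic sigmoid with guess and
# lapse asymptotes, maximum-likelihood fitting on binomial word counts,
# rationalized arcsine units, group-mean curves, and the derived statistics
# (optimal SNR, dip-listening benefit, SRT).

LOG19 <- log(1 / 0.05 - 1) # = log(19); ties the width to the 5%-95% span

#' Psychometric function
#'
#' Proportion correct at a given SNR for a logistic sigmoid parametrized by
#' threshold `m` (inflexion point), width `w` (the SNR range containing the
#' central 90 per cent of the rise: psi reaches 5% / 95% of its range at
#' `m -/+ w/2`), guess rate `gamma` and lapse rate `lambda`:
#' \deqn{\psi(x) = \gamma + \frac{1-\gamma-\lambda}{1 + e^{-2\ln(19)(x-m)/w}}}
#'
#' @param snr SNR value(s), dB.
#' @param m threshold (dB).
#' @param w width (dB), > 0.
#' @param gamma guess rate (default 0.1: closed set with 10 alternatives).
#' @param lambda lapse rate in \[0, 0.05\].
#' @return proportion(s) correct in \[gamma, 1 - lambda\].
#' @export
psychometric <- function(snr, m, w, gamma = 0.1, lambda = 0) {
  if (any(w <= 0)) stop("width w must be > 0")
  gamma + (1 - gamma - lambda) / (1 + exp(-2 * LOG19 * (snr - m) / w))
}

# Gaussian-CDF variant with the same (m, w, gamma, lambda) meaning:
# w spans the 5%-95% range, i.e. sd = w / (2 * qnorm(0.95))
psychometric_gauss <- function(snr, m, w, gamma = 0.1, lambda = 0) {
  if (any(w <= 0)) stop("width w must be > 0")
  gamma + (1 - gamma - lambda) *
    stats::pnorm(snr, mean = m, sd = w / (2 * stats::qnorm(0.95)))
}

#' Rationalized arcsine transform (continuous proportions)
#'
#' Studebaker's rationalized arcsine units for a continuous proportion:
#' \eqn{R = (146/\pi)\,2\arcsin\sqrt{p} - 23}, mapping 0 to -23, 0.5 to 50
#' and 1 to 123. Used on fitted psychometric curves, where proportions are
#' continuous.
#'
#' @param p proportion(s) in \[0, 1\].
#' @return value(s) in rationalized arcsine units.
#' @seealso [rau_score()] for the integer-count form applied to raw scores.
#' @export
rau <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportions must lie in [0, 1]")
  146 / pi * (2 * asin(sqrt(p))) - 23
}

#' Rationalized arcsine transform for integer scores
#'
#' The original small-sample form for `x` correct out of `n`:
#' \eqn{\theta = \arcsin\sqrt{x/(n+1)} + \arcsin\sqrt{(x+1)/(n+1)}},
#' \eqn{R = (146/\pi)\theta - 23}.
#'
#' @param x number correct.
#' @param n number presented.
#' @return rationalized arcsine units.
#' @export
rau_score <- function(x, n) {
  if (any(x < 0 | x > n)) stop("need 0 <= x <= n")
  th <- asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))
  146 / pi * th - 23
}

#' Fit a psychometric function by maximum likelihood
#'
#' Maximizes the binomial log-likelihood of per-SNR word counts over
#' `(m, w, lambda)` with the guess rate fixed (closed-set chance level),
#' the lapse rate box-constrained to \[0, `lambda_max`\], and a multistart
#' grid over `m` to avoid local optima. The `converged` flag is honest:
#' data with no usable rise (all floor or all ceiling) are flagged
#' non-converged and the parameters marked unreliable.
#'
#' @param snr vector of SNRs (dB), one per row of counts.
#' @param n_correct,n_words word counts per SNR (same length as `snr`).
#' @param gamma_fixed guess rate (default 0.1).
#' @param lambda_max upper bound for the lapse rate (default 0.05).
#' @param shape `"logistic"` (the reference form) or `"gaussian"`.
#' @return object of class `psychometric_fit`: list with `m`, `w`, `gamma`,
#'   `lambda`, `loglik`, `converged`, plus the data and settings.
#' @export
fit_psychometric <- function(snr, n_correct, n_words, gamma_fixed = 0.1,
                             lambda_max = 0.05,
                             shape = c("logistic", "gaussian")) {
  shape <- match.arg(shape)
  stopifnot(length(snr) == length(n_correct), length(snr) == length(n_words),
            all(n_correct >= 0), all(n_correct <= n_words))
  # aggregate duplicate SNRs
  agg <- stats::aggregate(cbind(n_correct, n_words) ~ snr,
                          data = data.frame(snr, n_correct, n_words), sum)
  if (nrow(agg) < 3) stop("need data at >= 3 distinct SNRs")
  x <- agg$snr; k <- agg$n_correct; nn <- agg$n_words
  psi_fun <- if (shape == "logistic") psychometric else psychometric_gauss

  nll <- function(par) {
    p <- psi_fun(x, par[1], exp(par[2]), gamma_fixed, par[3])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(k, nn, p, log = TRUE))
  }
  span <- diff(range(x))
  m_grid <- seq(min(x) - 5, max(x) + 5, length.out = 7)
  w_grid <- c(4, 10)
  best <- NULL; best_ok <- NULL
  for (m0 in m_grid) for (w0 in w_grid) {
    fit <- tryCatch(
      stats::optim(c(m0, log(w0), 0.01), nll, method = "L-BFGS-B",
                   lower = c(min(x) - 5, log(1), 0),
                   upper = c(max(x) + 5, log(30), lambda_max),
                   control = list(factr = 1e6)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0 &&
        (is.null(best_ok) || fit$value < best_ok$value)) best_ok <- fit
  }
  if (is.null(best)) stop("optimization failed at every start")

  # honesty check: does the sigmoid beat the best constant-rate model?
  # a start that ended with a line-search hiccup still counts as converged
  # when a cleanly converged start corroborates the same optimum
  phat <- sum(k) / sum(nn)
  ll_flat <- sum(stats::dbinom(k, nn, max(min(phat, 1 - 1e-12), 1e-12),
                               log = TRUE))
  ll_fit <- -best$value
  opt_ok <- best$convergence == 0 ||
    (!is.null(best_ok) && best_ok$value - best$value < 1e-4)
  converged <- opt_ok && (ll_fit - ll_flat) > 2
  structure(list(m = best$par[1], w = exp(best$par[2]),
                 gamma = gamma_fixed, lambda = best$par[3],
                 loglik = ll_fit, converged = converged,
                 shape = shape,
                 data = data.frame(snr = x, n_correct = k, n_words = nn)),
            class = "psychometric_fit")
}

#' @exportS3Method base::print
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "psychometric fit (%s): m = %.2f dB, w = %.2f dB, gamma = %.2f, lambda = %.3f%s\n",
    x$shape, x$m, x$w, x$gamma, x$lambda,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Predict proportion correct from a fit
#' @param object a `psychometric_fit`.
#' @param snr SNR(s) at which to evaluate.
#' @param ... unused.
#' @export
predict.psychometric_fit <- function(object, snr, ...) {
  f <- if (object$shape == "logistic") psychometric else psychometric_gauss
  f(snr, object$m, object$w, object$gamma, object$lambda)
}

#' Group-mean psychometric curve
#'
#' Averages the parameters (`m`, `w`, `gamma`, `lambda`) across listeners'
#' fits; the group curve is the psychometric function at the averaged
#' parameters. Any RAU conversion is applied to this resulting curve, not
#' to averaged RAU values.
#'
#' @param fits list of `psychometric_fit` objects (non-converged fits are
#'   dropped with a warning).
#' @return a `psychometric_fit` holding the averaged parameters.
#' @export
mean_group_curve <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "psychometric_fit")))
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(ok)) stop("no converged fits to average")
  if (!all(ok)) warning(sum(!ok), " non-converged fit(s) dropped")
  fits <- fits[ok]
  pick <- function(f) vapply(fits, `[[`, numeric(1), f)
  structure(list(m = mean(pick("m")), w = mean(pick("w")),
                 gamma = mean(pick("gamma")), lambda = mean(pick("lambda")),
                 loglik = NA_real_, converged = TRUE,
                 shape = fits[[1]]$shape, data = NULL),
            class = "psychometric_fit")
}

#' Optimal SNR: the grid point with the fewest floor/ceiling cases
#'
#' For each grid SNR, counts how many individual predicted scores lie
#' strictly inside (`lo`, `hi`) (defaults 15% and 95%: the closed-set
#' chance level is 10%) and returns the SNR maximizing that count, ties
#' broken toward the lower SNR.
#'
#' @param fits list of `psychometric_fit` objects (one per
#'   listener-condition).
#' @param snr_grid candidate SNRs (dB).
#' @param lo,hi score bounds as proportions.
#' @return the selected SNR (dB), with the per-SNR counts as attribute
#'   `counts`.
#' @export
optimal_snr <- function(fits, snr_grid, lo = 0.15, hi = 0.95) {
  if (length(snr_grid) == 0) stop("empty SNR grid")
  counts <- vapply(snr_grid, function(s) {
    p <- vapply(fits, function(f) predict.psychometric_fit(f, s), numeric(1))
    sum(p > lo & p < hi)
  }, numeric(1))
  ord <- order(-counts, snr_grid)   # max count, then lower SNR
  structure(snr_grid[ord[1]], counts = stats::setNames(counts, snr_grid))
}

#' Dip-listening benefit at a given SNR
#'
#' Score difference, in rationalized arcsine units, between the
#' modulated-noise and stationary-noise conditions at the same SNR,
#' evaluated on the fitted curves.
#'
#' @param fit_modulated,fit_stationary `psychometric_fit` objects.
#' @param snr evaluation SNR (dB).
#' @return benefit in RAU (positive: modulated noise easier).
#' @export
dip_benefit <- function(fit_modulated, fit_stationary, snr) {
  rau(predict.psychometric_fit(fit_modulated, snr)) -
    rau(predict.psychometric_fit(fit_stationary, snr))
}

#' Speech reception threshold (SNR at 50% words correct)
#'
#' Closed-form inversion of the logistic psychometric function at
#' psi = 0.5; requires 0.5 to be attainable (gamma < 0.5 < 1 - lambda).
#'
#' @param fit a `psychometric_fit` (logistic shape).
#' @return SRT in dB.
#' @export
srt <- function(fit) {
  g <- fit$gamma; l <- fit$lambda
  if (0.5 <= g || 0.5 >= 1 - l)
    stop("50% point not attainable: outside (gamma, 1 - lambda)")
  if (fit$shape == "logistic") {
    fit$m - fit$w / (2 * LOG19) * log((1 - g - l) / (0.5 - g) - 1)
  } else {
    fit$m + fit$w / (2 * stats::qnorm(0.95)) *
      stats::qnorm((0.5 - g) / (1 - g - l))
  }
}
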