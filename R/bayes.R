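# Default-prior Bayes factors: JZS paired / two-sample t-tests by
# one-dimensional quadrature, and mixed-design repeated-measures ANOVA
# model comparisons (g-priors on standardized effect blocks, Cauchy scale
# 1/2 on fixed terms, scale 1 on the random subject block), computed by
# Laplace approximation over log(g) with optional importance-sampling
# refinement, or by a fast BIC surrogate for bulk simulation work.

#' Evidence categories for a Bayes factor
#'
#' Cut points 10, 3, 1/3 and 1/10: above 10 strong evidence for the effect,
#' above 3 moderate; below 1/3 moderate evidence for its absence, below
#' 1/10 strong; in between, no conclusion.
#'
#' @param bf a positive Bayes factor (alternative over null).
#' @return one of `"strong_alt"`, `"moderate_alt"`, `"inconclusive"`,
#'   `"moderate_null"`, `"strong_null"`.
#' @export
classify_evidence <- function(bf) {
  if (!is.numeric(bf) || length(bf) != 1 || !is.finite(bf) && !is.infinite(bf))
    stop("bf must be a single positive number")
  if (bf <= 0) stop("bf must be positive")
  if (bf > 10) "strong_alt"
  else if (bf > 3) "moderate_alt"
  else if (bf >= 1 / 3) "inconclusive"
  else if (bf >= 1 / 10) "moderate_null"
  else "strong_null"
}

# JZS Bayes factor from a t statistic (Rouder et al. 2009):
# one-dimensional integral over the g-prior, relative error < 1e-6
jzs_bf_from_t <- function(t, n_eff, df, scale) {
  if (!is.finite(t)) stop("non-finite t statistic")
  loglik <- function(g) {
    -0.5 * log1p(n_eff * g) -
      (df + 1) / 2 * log1p(t^2 / ((1 + n_eff * g) * df))
  }
  log_prior <- function(g) {
    # inverse-gamma(1/2, scale^2/2) density
    0.5 * log(scale^2 / 2) - lgamma(0.5) - 1.5 * log(g) - scale^2 / (2 * g)
  }
  # integrate on u = log(g) for numerical stability
  f <- function(u) exp(loglik(exp(u)) + log_prior(exp(u)) + u)
  num <- stats::integrate(Vectorize(f), -30, 30,
                          rel.tol = 1e-9, abs.tol = 0)$value
  den <- exp(-(df + 1) / 2 * log1p(t^2 / df))
  num / den
}

#' JZS paired-samples Bayes factor
#'
#' Bayes factor (alternative over null) for the mean of paired differences
#' being zero, with a Cauchy prior of scale `scale` on the standardized
#' effect size (numerical quadrature of the Jeffreys-Zellner-Siow
#' integral).
#'
#' @param differences vector of paired differences (n >= 2, finite, not
#'   all identical).
#' @param scale Cauchy prior scale (default 1/2).
#' @return object of class `bayes_result`: `bf10`, `t`, `n`, `df`,
#'   `prior_scale`, `method`.
#' @export
jzs_paired_bf <- function(differences, scale = 0.5) {
  d <- as.numeric(differences)
  if (length(d) < 2 || any(!is.finite(d))) stop("need >= 2 finite differences")
  s <- stats::sd(d)
  if (s == 0) stop("zero variance: all differences identical")
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  bf <- jzs_bf_from_t(t, n_eff = n, df = n - 1, scale = scale)
  structure(list(bf10 = bf, t = t, n = n, df = n - 1, prior_scale = scale,
                 method = "quadrature", mc_error = NA_real_,
                 models_compared = "mean(diff) != 0 vs = 0"),
            class = "bayes_result")
}

#' JZS two-sample Bayes factor
#'
#' Independent-groups version of [jzs_paired_bf()] (pooled-variance t, with
#' effective sample size n1*n2/(n1+n2)).
#'
#' @param x,y the two groups' values.
#' @param scale Cauchy prior scale (default 1/2).
#' @return a `bayes_result`.
#' @export
jzs_two_sample_bf <- function(x, y, scale = 0.5) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need >= 2 observations per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (sp2 == 0) stop("zero pooled variance")
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  n_eff <- n1 * n2 / (n1 + n2)
  bf <- jzs_bf_from_t(t, n_eff = n_eff, df = df, scale = scale)
  structure(list(bf10 = bf, t = t, n = c(n1, n2), df = df,
                 prior_scale = scale, method = "quadrature",
                 mc_error = NA_real_,
                 models_compared = "mean(x) != mean(y) vs equal"),
            class = "bayes_result")
}

#' @exportS3Method base::print
print.bayes_result <- function(x, ...) {
  bf <- x$bf10
  cat(sprintf("BF10 = %s  (%s; %s)%s\n",
              format(bf, digits = 4), classify_evidence(bf), x$method,
              if (is.finite(x$mc_error) && !is.na(x$mc_error))
                sprintf("  mc_error ~ %.1f%%", 100 * x$mc_error) else ""))
  invisible(x)
}

# ---- g-prior ANOVA machinery -------------------------------------------

# orthonormal sum-to-zero contrast matrix for a factor with `a` levels
orth_contrasts <- function(a) {
  if (a < 2) stop("factor needs >= 2 levels")
  C <- stats::contr.sum(a)
  qr.Q(qr(C)) # columns orthonormal and orthogonal to the unit vector
}

# design-matrix block for a term (possibly an interaction "f1:f2"):
# columnwise Kronecker (face-splitting) product of per-factor orthonormal
# contrast expansions
term_block <- function(term, data) {
  fac <- strsplit(term, ":", fixed = TRUE)[[1]]
  X <- matrix(1, nrow(data), 1)
  for (f in fac) {
    v <- factor(data[[f]])
    Q <- orth_contrasts(nlevels(v))
    Z <- Q[as.integer(v), , drop = FALSE]
    X <- X[, rep(seq_len(ncol(X)), each = ncol(Z)), drop = FALSE] *
         Z[, rep(seq_len(ncol(Z)), times = ncol(X)), drop = FALSE]
  }
  X
}

# log marginal likelihood of y given block variances g (sigma^2 and the
# intercept integrated out; constants shared across models are dropped).
# Uses the Woodbury identity: V = I + X G X'  with  X = [X_1 ... X_k].
log_py_given_g <- function(g, blocks, XtX, Xty, yty, n) {
  p <- vapply(blocks, ncol, integer(1))
  G <- rep(g, p)
  A <- XtX * sqrt(outer(G, G)) # G^{1/2} X'X G^{1/2}
  diag(A) <- diag(A) + 1
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  u <- sqrt(G) * Xty
  # u' A^{-1} u = || R^{-T} u ||^2  with A = R'R
  quad <- yty - sum(backsolve(ch, u, transpose = TRUE)^2)
  if (quad <= 0) return(-Inf)
  -0.5 * logdet - (n - 1) / 2 * log(quad)
}

log_invgamma <- function(g, scale) {
  0.5 * log(scale^2 / 2) - lgamma(0.5) - 1.5 * log(g) - scale^2 / (2 * g)
}

# log integrated marginal over the g's for one model (Laplace on log g,
# optional importance-sampling refinement returning an mc error estimate)
log_marginal_model <- function(terms, data, y, subject, scales,
                               refine_mc = 0, seed = NULL) {
  blocks <- lapply(terms, term_block, data = data)
  names(blocks) <- terms
  X <- do.call(cbind, blocks)
  y <- y - mean(y)
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y^2)
  n <- length(y)
  k <- length(blocks)
  r <- scales[terms]
  post <- function(u) { # u = log g
    g <- exp(u)
    log_py_given_g(g, blocks, XtX, Xty, yty, n) +
      sum(log_invgamma(g, r)) + sum(u)
  }
  opt <- stats::optim(rep(-1, k), function(u) -post(u), method = "BFGS",
                      hessian = TRUE)
  H <- opt$hessian
  ld <- determinant(H, logarithm = TRUE)
  laplace <- -opt$value + k / 2 * log(2 * pi) - 0.5 * as.numeric(ld$modulus)
  if (refine_mc > 0) {
    # importance sampling with a slightly overdispersed Gaussian proposal
    # centred at the Laplace mode: u ~ N(mode, 1.5 * H^{-1})
    if (!is.null(seed)) set.seed(seed)
    Sig <- tryCatch(solve(H), error = function(e) diag(k) * 0.5)
    ev <- eigen(Sig, symmetric = TRUE)
    sdv <- sqrt(pmax(ev$values, 1e-8) * 1.5)
    L <- ev$vectors %*% diag(sdv, k)
    Z <- matrix(stats::rnorm(refine_mc * k), k)
    Us <- L %*% Z + opt$par
    ldetL <- sum(log(sdv))
    lw <- apply(Us, 2, post) -
      (colSums(stats::dnorm(Z, log = TRUE)) - ldetL)
    mx <- max(lw)
    wts <- exp(lw - mx)
    est <- mx + log(mean(wts))
    attr(est, "mc_error") <- stats::sd(wts) / (mean(wts) * sqrt(length(wts)))
    return(est)
  }
  laplace
}

# terms entering the null model for a target interaction: every main
# effect and interaction of strictly lower order, plus same-order
# interactions not containing the target's factors as a subset
anova_terms <- function(factors, target) {
  tf <- strsplit(target, ":", fixed = TRUE)[[1]]
  all_terms <- character(0)
  for (ord in seq_along(factors)) {
    combs <- utils::combn(factors, ord, simplify = FALSE)
    all_terms <- c(all_terms,
                   vapply(combs, paste, character(1), collapse = ":"))
  }
  keep <- vapply(all_terms, function(tm) {
    f <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (setequal(f, tf)) return(FALSE)              # the target itself
    if (all(tf %in% f)) return(FALSE)               # contains the target
    length(f) <= length(tf)                         # no higher order
  }, logical(1))
  all_terms[keep]
}

#' Mixed-design repeated-measures ANOVA Bayes factor for an interaction
#'
#' Compares the model containing the target interaction (plus all
#' lower-order terms and a random subject intercept) against the same model
#' without it. Fixed-effect blocks carry g-priors with Cauchy scale
#' `prior_scale` on standardized effects; the subject block has scale 1.
#' `method = "laplace"` integrates the g's by Laplace approximation (with
#' `n_mc > 0`, importance sampling refines the estimate and reports a
#' relative Monte-Carlo error); `method = "bic"` uses the fast
#' Schwarz-criterion surrogate exp((BIC0 - BIC1)/2) from maximum-likelihood
#' `lme4` fits, suitable for bulk simulation.
#'
#' @param data long-format data.frame.
#' @param target_interaction e.g. `"rt:group"` or `"rt:noise:group"`.
#' @param score name of the response column (typically RAU scores at one
#'   SNR).
#' @param subject name of the subject-identifier column.
#' @param factors names of the factor columns entering the model (between
#'   and within factors alike).
#' @param prior_scale Cauchy scale for fixed effects (default 1/2).
#' @param method `"laplace"` or `"bic"`.
#' @param n_mc importance-sampling draws for refinement (0 = plain
#'   Laplace).
#' @param seed seed for the refinement draws.
#' @return a `bayes_result` with `bf10`, `models_compared`, `method`,
#'   `mc_error`.
#' @export
mixed_anova_bf <- function(data, target_interaction, score = "score",
                           subject = "listener",
                           factors = intersect(c("group", "rt", "noise",
                                                 "modulation"), names(data)),
                           prior_scale = 0.5,
                           method = c("laplace", "bic"),
                           n_mc = 0, seed = NULL) {
  method <- match.arg(method)
  tf <- strsplit(target_interaction, ":", fixed = TRUE)[[1]]
  if (!all(tf %in% factors))
    stop("target interaction uses factors not in `factors`")
  data <- as.data.frame(data)
  for (f in c(factors, subject)) data[[f]] <- factor(data[[f]])
  # every subject must be observed in all within-subject cells
  between <- factors[vapply(factors, function(f)
    all(rowSums(table(data[[subject]], data[[f]]) > 0) == 1), logical(1))]
  within <- setdiff(factors, between)
  if (length(within) > 0) {
    cells <- table(data[[subject]],
                   interaction(data[, within, drop = FALSE], drop = FALSE))
    if (any(cells == 0)) {
      bad <- which(cells == 0, arr.ind = TRUE)[1, ]
      stop("missing cell: subject ", rownames(cells)[bad[1]], " in ",
           colnames(cells)[bad[2]])
    }
  }
  y <- data[[score]]
  if (stats::var(y) == 0) stop("response has zero variance")

  null_terms <- anova_terms(factors, target_interaction)
  full_terms <- c(null_terms, target_interaction)

  if (method == "bic") {
    fml <- function(terms) stats::as.formula(paste(
      score, "~", paste(terms, collapse = " + "),
      "+ (1 |", subject, ")"))
    f1 <- suppressWarnings(suppressMessages(
      lme4::lmer(fml(full_terms), data = data, REML = FALSE)))
    f0 <- suppressWarnings(suppressMessages(
      lme4::lmer(fml(null_terms), data = data, REML = FALSE)))
    bf <- exp((stats::BIC(f0) - stats::BIC(f1)) / 2)
    return(structure(list(bf10 = bf, prior_scale = NA_real_,
                          method = "bic", mc_error = NA_real_,
                          models_compared = paste0("[", paste(full_terms,
                            collapse = " + "), "] vs without ",
                            target_interaction)),
                     class = "bayes_result"))
  }

  scales <- stats::setNames(rep(prior_scale, length(full_terms) + 1),
                            c(full_terms, subject))
  scales[subject] <- 1
  lm_full <- log_marginal_model(c(full_terms, subject), data, y, subject,
                                scales, refine_mc = n_mc, seed = seed)
  lm_null <- log_marginal_model(c(null_terms, subject), data, y, subject,
                                scales, refine_mc = n_mc,
                                seed = if (is.null(seed)) NULL else seed + 1)
  bf <- exp(as.numeric(lm_full) - as.numeric(lm_null))
  mc_err <- if (n_mc > 0) {
    sqrt(sum(c(attr(lm_full, "mc_error"), attr(lm_null, "mc_error"))^2))
  } else NA_real_
  structure(list(bf10 = bf, prior_scale = prior_scale,
                 method = if (n_mc > 0) "monte_carlo" else "laplace",
                 mc_error = mc_err,
                 models_compared = paste0("[", paste(full_terms,
                   collapse = " + "), "] vs without ", target_interaction)),
            class = "bayes_result")
}
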