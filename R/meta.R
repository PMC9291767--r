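#' DerSimonian-Laird between-study variance
#'
#' Moment estimator of the between-study variance tau^2 from Cochran's Q:
#' with fixed-effects weights `w_i = 1/s_i^2`,
#' `Q = sum w_i (y_i - ybar_FE)^2`, `C = sum w_i - sum w_i^2 / sum w_i`,
#' `tau^2 = max(0, (Q - (k-1)) / C)`.
#'
#' @param y per-study coefficients.
#' @param se per-study standard errors (positive).
#' @return `tau2` (scalar).
#' @export
dl_tau2 <- function(y, se) {
  check_meta_input(y, se)
  w <- 1 / se^2
  yb <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yb)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (length(y) - 1)) / C)
}

check_meta_input <- function(y, se) {
  if (length(y) < 2) stop("meta-analysis needs at least 2 studies")
  if (length(y) != length(se)) stop("'y' and 'se' must have equal length")
  if (any(se <= 0)) stop("standard errors must be positive")
  invisible(NULL)
}

#' Inverse-variance pooling under a random-effects model
#'
#' Weights `w_i = 1/(s_i^2 + tau^2)`; pooled coefficient
#' `sum(w_i y_i)/sum(w_i)` and standard error `sqrt(1/sum(w_i))`.
#'
#' @param y per-study coefficients.
#' @param se per-study standard errors.
#' @param tau2 between-study variance (default: [dl_tau2()]).
#' @return List: `beta`, `se`, `tau2`.
#' @export
pool_effects <- function(y, se, tau2 = dl_tau2(y, se)) {
  check_meta_input(y, se)
  if (tau2 < 0) stop("'tau2' must be non-negative")
  w <- 1 / (se^2 + tau2)
  list(beta = sum(w * y) / sum(w), se = sqrt(1 / sum(w)), tau2 = tau2)
}

# Random-effects normal log-likelihood at (beta, tau2).
re_loglik <- function(beta, tau2, y, se) {
  v <- se^2 + tau2
  sum(-0.5 * log(2 * pi * v) - (y - beta)^2 / (2 * v))
}

#' Han-Eskin RE2 likelihood-ratio test
#'
#' Tests the joint null `beta = 0, tau^2 = 0` against a random-effects
#' alternative: maximize the normal log-likelihood
#' `l(beta, tau^2) = sum[-log(2 pi (s_i^2 + tau^2))/2 -
#' (y_i - beta)^2 / (2 (s_i^2 + tau^2))]` over `beta` and `tau^2 >= 0`,
#' form `S = 2 (l_max - l(0, 0))`, and refer it to the asymptotic mixture
#' null `p = P(chi2_1 >= S)/2 + P(chi2_2 >= S)/2`. The maximization
#' profiles beta out analytically and optimizes the 1-D profile in tau^2;
#' if that fails, a grid search is used with a warning.
#'
#' @param y per-study coefficients.
#' @param se per-study standard errors.
#' @return List: `stat` (S), `p`, `beta_ml`, `tau2_ml`.
#' @export
han_eskin_p <- function(y, se) {
  check_meta_input(y, se)
  prof <- function(tau2) {
    w <- 1 / (se^2 + tau2)
    re_loglik(sum(w * y) / sum(w), tau2, y, se)
  }
  up <- max(stats::var(y) * 5, max(se^2), 1e-3)
  opt <- tryCatch(
    stats::optimize(prof, interval = c(0, up), maximum = TRUE, tol = 1e-12),
    error = function(e) NULL)
  if (is.null(opt)) {
    warning("profile optimizer failed; falling back to grid search",
            call. = FALSE)
    grid <- seq(0, up, length.out = 20001)
    vals <- vapply(grid, prof, 0)
    opt <- list(maximum = grid[which.max(vals)], objective = max(vals))
  }
  # the boundary tau2 = 0 competes with the interior optimum
  tau2_ml <- if (prof(0) >= opt$objective) 0 else opt$maximum
  lmax <- prof(tau2_ml)
  w <- 1 / (se^2 + tau2_ml)
  beta_ml <- sum(w * y) / sum(w)
  S <- max(0, 2 * (lmax - re_loglik(0, 0, y, se)))
  p <- 0.5 * stats::pchisq(S, 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(S, 2, lower.tail = FALSE)
  list(stat = S, p = p, beta_ml = beta_ml, tau2_ml = tau2_ml)
}

#' Random-effects meta-analysis of per-cohort coefficients
#'
#' The package's standard combination for multi-cohort PRS associations:
#' the reported pooled coefficient, between-study SD tau, and pooled SE
#' come from DerSimonian-Laird tau^2 with inverse-variance weights, while
#' the p-value is the Han-Eskin RE2 likelihood-ratio mixture test, which
#' retains fixed-effects-like power under heterogeneity.
#'
#' @param y per-study standardized coefficients.
#' @param se per-study standard errors.
#' @param n optional per-study sample sizes (summed into `n_total`).
#' @param labels optional study labels.
#' @return Object of class `"meta_re2"`: `beta`, `tau`, `tau2`, `se`,
#'   `stat`, `p`, `k`, `n_total`, `studies` (input data frame).
#' @export
meta_re2 <- function(y, se, n = NULL, labels = NULL) {
  check_meta_input(y, se)
  t2 <- dl_tau2(y, se)
  pooled <- pool_effects(y, se, t2)
  he <- han_eskin_p(y, se)
  structure(list(
    beta = pooled$beta, tau = sqrt(t2), tau2 = t2, se = pooled$se,
    stat = he$stat, p = he$p, k = length(y),
    n_total = if (is.null(n)) NA_integer_ else sum(n),
    studies = data.frame(
      label = labels %||% paste0("study", seq_along(y)),
      y = y, se = se, n = if (is.null(n)) NA_integer_ else n)
  ), class = "meta_re2")
}

#' @export
print.meta_re2 <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (%d studies%s)\n",
    x$k, if (is.na(x$n_total)) "" else sprintf(", combined n = %d", x$n_total)))
  cat(sprintf("  beta = %.*f, tau = %.*f, SE = %.*f, RE2 p = %.2e\n",
              digits, x$beta, digits, x$tau, digits, x$se, x$p))
  invisible(x)
}

#' Li-Ji effective number of independent tests
#'
#' From the eigenvalues `lambda_i` of the correlation matrix of all test
#' statistics' underlying variables (here: every PRS at every threshold),
#' `Meff = ceiling(sum f(|lambda_i|))` with
#' `f(x) = 1(x >= 1) + (x - floor(x))`.
#'
#' @param R symmetric correlation matrix with unit diagonal.
#' @return Object of class `"effective_tests"`: `meff`, `eigenvalues`,
#'   `m` (matrix dimension).
#' @export
meff_li_ji <- function(R) {
  R <- as.matrix(R)
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-6))
    stop("correlation matrix must have unit diagonal")
  lam <- abs(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  # f is discontinuous at integers; round off eigenvalue fuzz so that an
  # exact eigenvalue of k does not floor to k-1 and contribute ~1 extra
  lam <- round(lam, 10)
  f <- as.numeric(lam >= 1) + (lam - floor(lam))
  structure(list(meff = as.integer(ceiling(sum(f) - 1e-8)), eigenvalues = lam,
                 m = nrow(R)),
            class = "effective_tests")
}

#' @export
print.effective_tests <- function(x, ...) {
  cat(sprintf("Li-Ji effective number of tests: %d (of %d)\n", x$meff, x$m))
  invisible(x)
}

#' Bonferroni threshold for the effective number of tests
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param meff effective number of independent tests (or an
#'   `effective_tests` object).
#' @return `alpha / meff`.
#' @export
adjust_alpha <- function(alpha = 0.05, meff) {
  if (inherits(meff, "effective_tests")) meff <- meff$meff
  if (length(meff) != 1 || is.na(meff) || meff < 1)
    stop("'meff' must be a single integer >= 1")
  alpha / meff
}

#' Independence flag for a PRS in the mutually adjusted model
#'
#' A PRS is flagged as contributing independently when it is significant
#' after multiple-testing adjustment in the separate model AND remains
#' nominally significant in the mutually adjusted model.
#'
#' @param p_separate meta-analytic p-value from the separate PRS model.
#' @param p_mutual meta-analytic p-value from the mutually adjusted model.
#' @param alpha_adjusted multiplicity-adjusted threshold (e.g.
#'   [adjust_alpha()] output).
#' @param alpha_nominal nominal threshold for the mutual model
#'   (default 0.05).
#' @return Logical (vectorized).
#' @export
flag_independent <- function(p_separate, p_mutual, alpha_adjusted,
                             alpha_nominal = 0.05) {
  if (anyNA(p_separate) || anyNA(p_mutual)) stop("p-values must be present")
  (p_separate < alpha_adjusted) & (p_mutual < alpha_nominal)
}
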