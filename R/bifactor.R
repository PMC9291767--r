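#' Fit a bifactor measurement model by maximum likelihood
#'
#' Fits the Gaussian factor model `Sigma = Lg Lg' + sum_d Ls_d Ls_d' + Psi`
#' to the sample correlation matrix, where one general factor loads on all
#' subscales and each subscale additionally loads on exactly one
#' domain-specific factor (e.g. internalizing or externalizing). All
#' factors are orthogonal with unit variance. Estimation minimizes the ML
#' discrepancy `log det(Sigma) + tr(S Sigma^-1) - log det(S) - p` by
#' L-BFGS-B over the loadings and log-uniquenesses, with analytic
#' gradients; uniquenesses are bounded below at 1e-4, and a solution at
#' that floor is reported as a Heywood case with a warning.
#'
#' The deterministic start takes general loadings from the first principal
#' component and specific loadings at 0.2. Sign convention: the mean
#' general loading and each specific factor's mean loading are positive.
#'
#' @param x n x p matrix (or data frame) of subscale scores, standardized
#'   internally; alternatively `NULL` if `covmat` is given.
#' @param domains length-p factor/character map of each subscale to its
#'   specific factor. At least 3 subscales per specific factor.
#' @param covmat optional p x p covariance/correlation matrix to fit
#'   directly (converted to a correlation matrix); bypasses `x`.
#' @param n.obs number of observations behind `covmat`.
#' @param tol gradient tolerance passed to the optimizer (default 1e-8).
#' @param maxit maximum optimizer iterations.
#' @return An object of class `"bifactor"`: list with `loadings_general`,
#'   `loadings_specific`, `uniqueness`, `domains`, `Sigma` (implied
#'   correlation), `S` (sample correlation), `loglik`, `discrepancy`,
#'   `converged`, `heywood`, `n`, `center`, `scale`.
#' @export
fit_bifactor <- function(x = NULL, domains, covmat = NULL, n.obs = NA,
                         tol = 1e-8, maxit = 1000L) {
  domains <- as.character(domains)
  p <- length(domains)
  doms <- sort(unique(domains))
  if (any(table(domains) < 3))
    stop("need at least 3 subscales per specific factor")
  if (is.null(covmat)) {
    x <- as.matrix(x)
    if (ncol(x) != p) stop("ncol(x) must match length(domains)")
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    S <- stats::cor(x)
    n <- nrow(x)
  } else {
    if (!isSymmetric(unname(covmat), tol = 1e-8)) stop("'covmat' must be symmetric")
    if (nrow(covmat) != p) stop("dim(covmat) must match length(domains)")
    S <- stats::cov2cor(as.matrix(covmat))
    ctr <- rep(0, p); scl <- rep(1, p)
    n <- n.obs
  }
  dimnames(S) <- dimnames(S) %||% list(paste0("y", 1:p), paste0("y", 1:p))
  dmask <- outer(domains, doms, "==")  # p x ndom

  # no common variance: the factor part is unidentified, return the null fit
  if (max(abs(S[lower.tri(S)])) < 0.01) {
    warning("degenerate solution: subscales are essentially uncorrelated",
            call. = FALSE)
    zero <- stats::setNames(rep(0, p), colnames(S))
    return(structure(list(
      loadings_general = zero, loadings_specific = zero,
      uniqueness = zero + 1, domains = domains, domain_levels = doms,
      Sigma = diag(p), S = S, discrepancy = NA_real_,
      discrepancy_start = NA_real_, loglik = NA_real_,
      converged = TRUE, heywood = FALSE, n = n, center = ctr, scale = scl
    ), class = "bifactor"))
  }

  ml_fn <- function(theta) {
    lg <- theta[1:p]; ls <- theta[(p + 1):(2 * p)]
    psi <- exp(theta[(2 * p + 1):(3 * p)])
    Sig <- tcrossprod(lg)
    for (d in seq_along(doms)) {
      v <- ls * dmask[, d]
      Sig <- Sig + tcrossprod(v)
    }
    diag(Sig) <- diag(Sig) + psi
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- 2 * sum(log(diag(ch)))
    ldet + sum(diag(chol2inv(ch) %*% S))
  }
  ml_gr <- function(theta) {
    lg <- theta[1:p]; ls <- theta[(p + 1):(2 * p)]
    psi <- exp(theta[(2 * p + 1):(3 * p)])
    Sig <- tcrossprod(lg)
    for (d in seq_along(doms)) {
      v <- ls * dmask[, d]
      Sig <- Sig + tcrossprod(v)
    }
    diag(Sig) <- diag(Sig) + psi
    Si <- solve(Sig)
    A <- Si - Si %*% S %*% Si        # dF/dSigma
    g_lg <- 2 * A %*% lg
    g_ls <- numeric(p)
    for (d in seq_along(doms)) {
      v <- ls * dmask[, d]
      g_ls <- g_ls + (2 * A %*% v) * dmask[, d]
    }
    g_psi <- diag(A) * psi
    c(g_lg, g_ls, g_psi)
  }

  # deterministic start: general loadings from the first PC, specifics 0.2
  e1 <- eigen(S, symmetric = TRUE)
  lg0 <- e1$vectors[, 1] * sqrt(max(e1$values[1], 1))
  if (mean(lg0) < 0) lg0 <- -lg0
  lg0 <- pmin(pmax(lg0, -0.95), 0.95)
  ls0 <- rep(0.2, p)
  psi0 <- pmax(1 - lg0^2 - ls0^2, 0.1)
  theta0 <- c(lg0, ls0, log(psi0))
  lower <- c(rep(-Inf, 2 * p), rep(log(1e-4), p))

  opt <- stats::optim(theta0, ml_fn, ml_gr, method = "L-BFGS-B",
                      lower = lower,
                      control = list(maxit = maxit, pgtol = tol, factr = 10))
  lg <- opt$par[1:p]; ls <- opt$par[(p + 1):(2 * p)]
  psi <- exp(opt$par[(2 * p + 1):(3 * p)])
  if (mean(lg) < 0) lg <- -lg
  for (d in seq_along(doms)) {
    sel <- dmask[, d]
    if (mean(ls[sel]) < 0) ls[sel] <- -ls[sel]
  }
  heywood <- psi <= 1.5e-4
  if (any(heywood)) {
    psi[heywood] <- 1e-4
    warning("Heywood case: uniqueness clamped at floor for subscale(s) ",
            paste(which(heywood), collapse = ", "), call. = FALSE)
  }
  Sig <- tcrossprod(lg)
  for (d in seq_along(doms)) Sig <- Sig + tcrossprod(ls * dmask[, d])
  diag(Sig) <- diag(Sig) + psi
  dimnames(Sig) <- dimnames(S)
  if (max(abs(lg), abs(ls)) < 0.05)
    warning("degenerate solution: all loadings below 0.05", call. = FALSE)
  disc <- ml_fn(opt$par)
  ll <- if (is.na(n)) NA_real_ else {
    -(n - 1) / 2 * (determinant(Sig)$modulus[1] +
                      sum(diag(solve(Sig) %*% S)) + p * log(2 * pi))
  }
  structure(list(
    loadings_general = stats::setNames(lg, colnames(S)),
    loadings_specific = stats::setNames(ls, colnames(S)),
    uniqueness = stats::setNames(psi, colnames(S)),
    domains = domains, domain_levels = doms,
    Sigma = Sig, S = S, discrepancy = disc,
    discrepancy_start = ml_fn(theta0), loglik = ll,
    converged = opt$convergence == 0, heywood = any(heywood),
    n = n, center = ctr, scale = scl
  ), class = "bifactor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bifactor <- function(x, digits = 3, ...) {
  cat("Bifactor model (ML on the correlation matrix)\n")
  cat(sprintf("  %d subscales, specific factors: %s\n",
              length(x$domains), paste(x$domain_levels, collapse = ", ")))
  cat(sprintf("  converged: %s%s\n", x$converged,
              if (x$heywood) " (Heywood case, uniqueness at floor)" else ""))
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.bifactor <- function(object, ...) {
  L <- cbind(general = object$loadings_general)
  for (d in object$domain_levels)
    L <- cbind(L, ifelse(object$domains == d, object$loadings_specific, 0))
  colnames(L)[-1] <- paste0("spec_", object$domain_levels)
  cbind(L, uniqueness = object$uniqueness)
}

#' @export
summary.bifactor <- function(object, ...) {
  out <- list(loadings = coef(object),
              discrepancy = object$discrepancy,
              loglik = object$loglik,
              converged = object$converged,
              heywood = object$heywood,
              rmsr = sqrt(mean((object$S - object$Sigma)[
                lower.tri(object$S)]^2)))
  class(out) <- "summary.bifactor"
  out
}

#' @export
print.summary.bifactor <- function(x, digits = 3, ...) {
  print(round(x$loadings, digits))
  cat(sprintf("\nML discrepancy %.6g, off-diagonal RMSR %.4f, converged: %s\n",
              x$discrepancy, x$rmsr, x$converged))
  invisible(x)
}

#' @export
plot.bifactor <- function(x, ...) {
  L <- coef(x)[, -ncol(coef(x)), drop = FALSE]
  graphics::barplot(t(L), beside = TRUE, las = 2,
                    legend.text = colnames(L),
                    ylab = "loading", ...)
  invisible(x)
}

#' Regression (Thurstone) factor scores from a bifactor fit
#'
#' Scores each individual as `L' Sigma^-1 y` with `y` the standardized
#' subscale vector and `L` the p x 3 loading matrix (general plus the two
#' specific factors). Linear in the data; score variances are at most 1.
#'
#' @param fit a [fit_bifactor()] object.
#' @param x n x p matrix of subscale scores on the original scale;
#'   standardized with the fit's centering/scaling.
#' @return Matrix n x (1 + number of specific factors) with columns
#'   `general`, `spec_<domain>`.
#' @export
factor_scores <- function(fit, x) {
  stopifnot(inherits(fit, "bifactor"))
  if (!fit$converged)
    warning("factor scores from a non-converged fit", call. = FALSE)
  x <- as.matrix(x)
  p <- length(fit$domains)
  if (ncol(x) != p) stop("ncol(x) must match the fitted model")
  y <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  L <- cbind(fit$loadings_general,
             sapply(fit$domain_levels, function(d)
               ifelse(fit$domains == d, fit$loadings_specific, 0)))
  colnames(L) <- c("general", paste0("spec_", fit$domain_levels))
  Si <- tryCatch(solve(fit$Sigma), error = function(e)
    stop("implied covariance is singular; cannot compute scores"))
  scores <- y %*% Si %*% L
  rownames(scores) <- rownames(x)
  scores
}

#' @export
predict.bifactor <- function(object, newdata, ...) factor_scores(object, newdata)

#' Write / read factor scores as CSV
#'
#' Columns: `id`, then one column per factor.
#' @param scores matrix from [factor_scores()].
#' @param file path.
#' @return `read_factor_scores` returns the matrix; `write_factor_scores`
#'   the path, invisibly.
#' @export
write_factor_scores <- function(scores, file) {
  utils::write.csv(data.frame(id = rownames(scores), scores,
                              check.names = FALSE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_factor_scores
#' @export
read_factor_scores <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$id
  m
}
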