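#' Regress an outcome on a single PRS with covariate adjustment
#'
#' Ordinary least squares of a factor score on one polygenic score plus
#' covariates. Outcome and PRS are z-scored internally so the reported
#' coefficient is standardized (SD units); covariates enter untouched.
#' The incremental R-squared is the difference in R-squared between this
#' model and the covariates-only model.
#'
#' @param outcome numeric outcome vector (factor score).
#' @param prs numeric PRS vector.
#' @param covariates data frame or matrix of covariates (may be `NULL`).
#' @param trait,threshold,outcome_name optional labels copied to the output.
#' @return One-row data frame: `trait`, `threshold`, `outcome`, `beta`,
#'   `se`, `p`, `delta_r2`, `n`.
#' @export
fit_separate_model <- function(outcome, prs, covariates = NULL,
                               trait = NA_character_, threshold = NA_real_,
                               outcome_name = NA_character_) {
  X <- prepare_design(prs_cols = cbind(prs = prs), covariates, outcome)
  fit <- ols_fit(X$y, X$design)
  r2_cov <- if (ncol(X$cov_design) > 1) ols_fit(X$y, X$cov_design)$r2 else 0
  data.frame(trait = trait, threshold = threshold, outcome = outcome_name,
             beta = fit$coef["prs"], se = fit$se["prs"], p = fit$p["prs"],
             delta_r2 = fit$r2 - r2_cov, n = X$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mutually adjusted multi-PRS regression
#'
#' Joint OLS of an outcome on all supplied PRS columns (each z-scored)
#' plus covariates; one coefficient per PRS.
#'
#' @param outcome numeric outcome vector.
#' @param prs_matrix n x traits matrix of PRSs at their selected
#'   thresholds, one column per trait (column names label the output).
#' @param covariates data frame or matrix of covariates (may be `NULL`).
#' @param outcome_name optional label.
#' @return Data frame, one row per PRS column: `trait`, `outcome`, `beta`,
#'   `se`, `p`, `n`, with joint `delta_r2` (same value repeated) versus the
#'   covariates-only model.
#' @export
fit_mutual_model <- function(outcome, prs_matrix, covariates = NULL,
                             outcome_name = NA_character_) {
  prs_matrix <- as.matrix(prs_matrix)
  if (is.null(colnames(prs_matrix)))
    colnames(prs_matrix) <- paste0("prs", seq_len(ncol(prs_matrix)))
  X <- prepare_design(prs_matrix, covariates, outcome)
  fit <- ols_fit(X$y, X$design)
  r2_cov <- if (ncol(X$cov_design) > 1) ols_fit(X$y, X$cov_design)$r2 else 0
  traits <- colnames(prs_matrix)
  data.frame(trait = traits, outcome = outcome_name,
             beta = fit$coef[traits], se = fit$se[traits], p = fit$p[traits],
             delta_r2 = fit$r2 - r2_cov, n = X$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Shared design construction: complete cases, z-scored outcome and PRSs,
# explicit collinearity check naming the offending columns.
prepare_design <- function(prs_cols, covariates, outcome) {
  C <- if (is.null(covariates)) matrix(numeric(0), length(outcome), 0)
       else as.matrix(as.data.frame(covariates))
  cc <- stats::complete.cases(outcome, prs_cols, if (ncol(C)) C else NULL)
  y <- as.vector(scale(outcome[cc]))
  P <- scale(prs_cols[cc, , drop = FALSE])
  C <- C[cc, , drop = FALSE]
  design <- cbind(`(Intercept)` = 1, P, C)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(y = y, design = design,
       cov_design = cbind(`(Intercept)` = 1, C), n = sum(cc))
}

# Minimal OLS with coefficient SEs and two-sided p-values.
ols_fit <- function(y, X) {
  XtXi <- chol2inv(chol(crossprod(X)))
  beta <- drop(XtXi %*% crossprod(X, y))
  names(beta) <- colnames(X)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(XtXi) * sigma2)
  names(se) <- colnames(X)
  tval <- beta / se
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(coef = beta, se = se, p = 2 * stats::pt(-abs(tval), df), r2 = r2,
       df = df)
}

#' Select the best p-value threshold per trait and outcome
#'
#' Picks, for each trait-outcome pair, the threshold whose meta-analytic
#' p-value is smallest; ties are broken toward the larger (more inclusive)
#' threshold.
#'
#' @param meta_table data frame with columns `trait`, `outcome`,
#'   `threshold`, `p` (one row per trait x outcome x threshold).
#' @return Data frame with one row per trait x outcome: `trait`, `outcome`,
#'   `threshold`, `p`.
#' @export
select_best_threshold <- function(meta_table) {
  need <- c("trait", "outcome", "threshold", "p")
  if (!all(need %in% names(meta_table)))
    stop("meta table lacks column(s): ",
         paste(setdiff(need, names(meta_table)), collapse = ", "))
  if (anyNA(meta_table$p)) stop("missing meta-analytic p-values")
  split_by <- interaction(meta_table$trait, meta_table$outcome, drop = TRUE)
  rows <- lapply(split(meta_table, split_by), function(d) {
    best <- d$p == min(d$p)
    d[best, ][which.max(d$threshold[best]), c("trait", "outcome", "threshold", "p")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-validated incremental R-squared
#'
#' Repeated k-fold cross-validation of the out-of-fold R-squared of
#' `covariates + predictors` minus that of covariates only. Folds are a
#' simple random partition per repeat; out-of-fold R-squared is pooled as
#' `1 - SSE/SST` across folds within a repeat, then averaged over repeats.
#' Deterministic given `seed`.
#'
#' @param outcome numeric outcome vector.
#' @param predictors matrix of predictors of interest (e.g. PRSs).
#' @param covariates data frame or matrix of covariates (may be `NULL`).
#' @param k folds (default 10).
#' @param repeats repetitions of the partition (default 100).
#' @param seed integer seed.
#' @return List: `delta_r2`, `r2_full`, `r2_cov`, `k`, `repeats`.
#' @export
cv_delta_r2 <- function(outcome, predictors, covariates = NULL,
                        k = 10L, repeats = 100L, seed = 1L) {
  if (k < 2) stop("'k' must be at least 2")
  if (repeats < 1) stop("'repeats' must be at least 1")
  P <- as.matrix(predictors)
  C <- if (is.null(covariates)) matrix(numeric(0), length(outcome), 0)
       else as.matrix(as.data.frame(covariates))
  cc <- stats::complete.cases(outcome, P, if (ncol(C)) C else NULL)
  y <- outcome[cc]; P <- P[cc, , drop = FALSE]; C <- C[cc, , drop = FALSE]
  n <- length(y)
  if (k > n) stop("'k' exceeds the number of complete cases")
  Xf <- cbind(1, C, P)
  Xc <- cbind(1, C)
  oof_r2 <- function(X, folds) {
    sse <- 0
    for (f in seq_len(k)) {
      te <- folds == f
      b <- qr.coef(qr(X[!te, , drop = FALSE]), y[!te])
      b[is.na(b)] <- 0
      sse <- sse + sum((y[te] - X[te, , drop = FALSE] %*% b)^2)
    }
    1 - sse / sum((y - mean(y))^2)
  }
  with_seed(seed, {
    r2f <- r2c <- numeric(repeats)
    for (r in seq_len(repeats)) {
      folds <- sample(rep(seq_len(k), length.out = n))
      r2f[r] <- oof_r2(Xf, folds)
      r2c[r] <- oof_r2(Xc, folds)
    }
    list(delta_r2 = mean(r2f) - mean(r2c),
         r2_full = mean(r2f), r2_cov = mean(r2c),
         k = k, repeats = repeats)
  })
}

#' Clogg z-test comparing general- and specific-factor coefficients
#'
#' Tests the difference between two (approximately independent) estimated
#' coefficients: `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided
#' normal p-value. Appropriate here because the general and specific
#' factors are orthogonal by construction, so the covariance between the
#' two coefficient estimates is negligible.
#'
#' @param general,specific either `meta_re2` objects or numeric
#'   `c(beta, se)` pairs.
#' @return List: `z`, `p`, `diff` (b1 - b2).
#' @export
compare_general_specific <- function(general, specific) {
  gs <- extract_beta_se(general)
  sp <- extract_beta_se(specific)
  if (gs[2] <= 0 || sp[2] <= 0) stop("standard errors must be positive")
  z <- (gs[1] - sp[1]) / sqrt(gs[2]^2 + sp[2]^2)
  list(z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
       diff = unname(gs[1] - sp[1]))
}

extract_beta_se <- function(x) {
  if (inherits(x, "meta_re2")) c(x$beta, x$se)
  else if (is.numeric(x) && length(x) == 2) x
  else stop("expected a meta_re2 object or a (beta, se) pair")
}

#' Sample-size-weighted average R-squared across cohorts
#'
#' Pools per-cohort correlations (signed `r` values) by sample-size
#' weighting, then squares: `(sum(n_i r_i) / sum(n_i))^2`. Signs are kept
#' while averaging, so opposite-sign cohorts cancel before squaring.
#'
#' @param r per-cohort correlation (signed) between predictor and outcome.
#' @param n per-cohort sample sizes.
#' @return Pooled R-squared (scalar), with the weighted mean `r` as
#'   attribute `"r"`.
#' @export
average_r2 <- function(r, n) {
  if (length(r) != length(n)) stop("'r' and 'n' must have equal length")
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]")
  if (any(n <= 0)) stop("sample sizes must be positive")
  rbar <- sum(n * r) / sum(n)
  structure(rbar^2, r = rbar)
}

#' Write a per-cohort association table as TSV
#'
#' @param assoc data frame of association rows.
#' @param file path.
#' @return The path, invisibly.
#' @export
write_assoc_table <- function(assoc, file) {
  utils::write.table(assoc, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_assoc_table
#' @export
read_assoc_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
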