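#' Simulate an LD-blocked genotype dosage panel
#'
#' Generates hard-call dosages (0/1/2) for `n` individuals as the sum of two
#' independent haplotypes. Within each LD block, a haplotype is a
#' first-order Markov chain of Bernoulli alleles sharing the block's allele
#' frequency, with adjacent-allele correlation `within_block_rho`; the
#' transition probabilities keep the marginal frequency exact, so LD decays
#' geometrically with SNP distance inside a block and is zero across blocks.
#'
#' Variant coordinates place each block 150 kb after the previous one with
#' 5 kb between SNPs inside a block, so that a typical clumping window
#' (+/- 250 kb) spans neighbouring blocks.
#'
#' @param config a [sim_config()] object.
#' @param n number of individuals (default: first cohort size).
#' @param seed integer seed for the dosage draw; default derived from
#'   `config$seed`.
#' @param map optional variant map to reuse; by default built
#'   deterministically from `config$seed`, so panels simulated from the
#'   same config share one map (same SNPs, alleles and frequencies across
#'   cohorts) while their dosages are independent.
#' @return A `geno_panel`: list with `dosage` (n x SNPs matrix, individuals
#'   in rows) and `map` (data frame: `snp_id`, `chrom`, `pos`, `a1` counted
#'   allele, `a2` other allele, `maf`, `block`).
#' @export
simulate_genotypes <- function(config, n = config$cohort_sizes[1],
                               seed = stage_seed(config$seed, "genotypes"),
                               map = simulate_variant_map(config)) {
  validate_sim_config(config)
  rho <- config$within_block_rho
  m <- nrow(map)
  with_seed(seed, {
    X <- matrix(0L, n, m)
    for (b in seq_len(max(map$block))) {
      idx <- which(map$block == b)
      f <- map$maf[idx[1]]
      for (hap in 1:2) {
        h <- matrix(0L, n, length(idx))
        h[, 1] <- stats::rbinom(n, 1L, f)
        if (length(idx) > 1) for (k in 2:length(idx)) {
          # exact-marginal Markov transition: corr(h[k-1], h[k]) = rho
          p_cond <- ifelse(h[, k - 1] == 1L, f + rho * (1 - f), f * (1 - rho))
          h[, k] <- stats::rbinom(n, 1L, p_cond)
        }
        X[, idx] <- X[, idx] + h
      }
    }
    rownames(X) <- sprintf("id%05d", seq_len(n))
    colnames(X) <- map$snp_id
    structure(list(dosage = X, map = map), class = "geno_panel")
  })
}

#' Build the shared variant map for a configuration
#'
#' Draws one MAF per LD block, assigns allele pairs, and lays variants out
#' at 5 kb spacing within a block with 150 kb between block starts.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed.
#' @return Data frame: `snp_id`, `chrom`, `pos`, `a1`, `a2`, `maf`, `block`.
#' @export
simulate_variant_map <- function(config,
                                 seed = stage_seed(config$seed, "map")) {
  validate_sim_config(config)
  m <- config$n_snps
  bs <- config$block_size
  blocks <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
  with_seed(seed, {
    block_maf <- stats::runif(max(blocks), config$maf_range[1], config$maf_range[2])
    # allele pair per SNP: counted allele a1 (frequency = maf), other a2.
    # Transition:transversion ratio ~2 as on real arrays, so strand-ambiguous
    # A/T and C/G pairs make up ~1/6 of variants rather than 1/3.
    pairs <- matrix(c("A", "C", "A", "G", "A", "T", "C", "G", "C", "T", "G", "T"),
                    ncol = 2, byrow = TRUE)
    pick <- sample(nrow(pairs), m, replace = TRUE,
                   prob = c(1, 4, 1, 1, 4, 1) / 12)
    swap <- stats::runif(m) < 0.5
    a1 <- ifelse(swap, pairs[pick, 2], pairs[pick, 1])
    a2 <- ifelse(swap, pairs[pick, 1], pairs[pick, 2])
    data.frame(
      snp_id = sprintf("rs%06d", seq_len(m)),
      chrom = "1",
      pos = (blocks - 1L) * 150000L + ((seq_len(m) - 1L) %% bs) * 5000L + 1L,
      a1 = a1, a2 = a2, maf = block_maf[blocks], block = blocks,
      stringsAsFactors = FALSE
    )
  })
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d SNPs (%d LD blocks)\n",
              nrow(x$dosage), ncol(x$dosage), max(x$map$block)))
  invisible(x)
}

#' Draw true per-allele causal effects for all traits
#'
#' A shared causal SNP set (proportion `causal_fraction`) carries per-trait
#' effects drawn from a multivariate normal with correlation
#' `config$genetic_corr`, scaled so that each trait's causal SNPs jointly
#' explain `h2_trait` of trait variance on the panel's frequencies.
#'
#' @param config a [sim_config()] object.
#' @param map variant metadata from [simulate_genotypes()] (needs `maf`).
#' @param seed integer seed.
#' @return SNPs x traits matrix of per-allele effects (zero rows for
#'   non-causal SNPs), with attribute `"causal"` (logical vector).
#' @export
draw_true_effects <- function(config, map,
                              seed = stage_seed(config$seed, "effects")) {
  validate_sim_config(config)
  m <- nrow(map)
  with_seed(seed, {
    causal <- stats::runif(m) < config$causal_fraction
    if (!any(causal)) causal[sample(m, 1)] <- TRUE
    mc <- sum(causal)
    # per-SNP effect variance so that sum over causal SNPs of b^2*2f(1-f) = h2
    v2fq <- 2 * map$maf[causal] * (1 - map$maf[causal])
    sig2 <- config$h2_trait / (mc * mean(v2fq))
    L <- chol_psd(config$genetic_corr)
    Z <- matrix(stats::rnorm(mc * config$n_traits), mc) %*% L
    B <- matrix(0, m, config$n_traits)
    B[causal, ] <- Z * sqrt(sig2)
    colnames(B) <- sprintf("trait%02d", seq_len(config$n_traits))
    attr(B, "causal") <- causal
    B
  })
}

# Cholesky-like factor for a PSD (possibly singular) correlation matrix.
chol_psd <- function(G) {
  e <- eigen(G, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

#' Simulate discovery GWAS summary statistics for every trait
#'
#' Emulates single-SNP (marginal) association estimates, as real GWAS
#' summary statistics are: each SNP's expected estimate is the
#' LD-weighted sum of the causal effects in its block,
#' `beta_marginal_j = sum_k rho^|j-k| beta_k`, plus Gaussian noise with
#' standard error `1/sqrt(2 * N * f * (1 - f))`; two-sided p-values come
#' from the Wald z statistic. EAF is the counted-allele frequency with
#' discovery-sample sampling noise; INFO is drawn from a high-quality
#' imputation distribution with a small low-quality tail so that QC
#' filtering has something to remove.
#'
#' @param config a [sim_config()] object.
#' @param map variant metadata from [simulate_genotypes()].
#' @param true_effects SNPs x traits matrix from [draw_true_effects()].
#' @param seed integer seed.
#' @return Named list (one per trait) of summary-statistic data frames with
#'   columns `SNP, CHR, BP, A1, A2, BETA, SE, P, EAF, INFO`.
#' @export
simulate_discovery_gwas <- function(config, map, true_effects,
                                    seed = stage_seed(config$seed, "gwas")) {
  validate_sim_config(config)
  if (any(config$discovery_n <= 0)) stop("discovery sample size must be positive")
  stopifnot(nrow(true_effects) == nrow(map))
  m <- nrow(map)
  # population LD of the haplotype chain: corr(X_j, X_k) = rho^|j-k| within
  # a block, zero across blocks; marginal effects are the LD-tagged sums
  rho <- config$within_block_rho
  marginal <- true_effects
  if (rho > 0) {
    for (b in unique(map$block)) {
      idx <- which(map$block == b)
      if (length(idx) > 1) {
        R <- rho^abs(outer(seq_along(idx), seq_along(idx), "-"))
        marginal[idx, ] <- R %*% true_effects[idx, , drop = FALSE]
      }
    }
  }
  with_seed(seed, {
    info <- ifelse(stats::runif(m) < 0.03,
                   stats::runif(m, 0.5, 0.8),
                   stats::runif(m, 0.82, 1.0))
    lapply(stats::setNames(seq_len(config$n_traits),
                           colnames(true_effects)), function(t) {
      N <- config$discovery_n[t]
      se <- 1 / sqrt(2 * N * map$maf * (1 - map$maf))
      beta_hat <- marginal[, t] + stats::rnorm(m, 0, se)
      z <- beta_hat / se
      eaf <- map$maf + stats::rnorm(m, 0, sqrt(map$maf * (1 - map$maf) / (2 * N)))
      data.frame(
        SNP = map$snp_id, CHR = map$chrom, BP = map$pos,
        A1 = map$a1, A2 = map$a2,
        BETA = beta_hat, SE = se,
        P = pmax(2 * stats::pnorm(-abs(z)), 1e-300),
        EAF = pmin(pmax(eaf, 1e-4), 1 - 1e-4), INFO = info,
        stringsAsFactors = FALSE
      )
    })
  })
}

#' Simulate one cohort's symptom subscales, covariates and true factors
#'
#' The general psychopathology factor is a linear combination of the
#' traits' standardized true polygenic values (weights
#' `prs_effects_general`) plus Gaussian residual, scaled to unit variance.
#' Specific externalizing and internalizing factors are built the same way
#' from `prs_effects_ext` / `prs_effects_int`, with residuals independent
#' of the general factor's, so the three factors are orthogonal whenever
#' effects are not planted on the same trait for two factors. Each subscale
#' is `general_loading * g + specific_loading * s_domain + unique noise`,
#' unit variance by construction.
#'
#' Covariates: `sex` (0/1), `age` (uniform in the cohort's window), and
#' four ancestry-proxy components `pc1..pc4` (standard normal). A nonzero
#' `ancestry_confounding` adds `pc1` into the general factor before
#' rescaling, creating confounding the regression adjustment must absorb.
#'
#' @param config a [sim_config()] object.
#' @param panel `geno_panel` for this cohort.
#' @param true_effects SNPs x traits matrix from [draw_true_effects()].
#' @param cohort index of the cohort (selects the age window).
#' @param seed integer seed.
#' @return List with `subscales` (n x p matrix), `covariates` (data frame),
#'   `truth` (data frame with true `g`, `s_ext`, `s_int` and the true
#'   standardized polygenic value per trait).
#' @export
simulate_cohort_phenotypes <- function(config, panel, true_effects, cohort = 1L,
                                       seed = stage_seed(config$seed,
                                                         paste0("pheno", cohort))) {
  validate_sim_config(config)
  lg <- config$general_loadings
  ls <- config$specific_loadings
  uniq <- 1 - lg^2 - ls^2
  if (any(uniq <= 0)) stop("loadings imply non-positive unique variance")
  X <- panel$dosage
  n <- nrow(X)
  P <- scale(X %*% true_effects)  # true standardized polygenic values
  colnames(P) <- colnames(true_effects)
  with_seed(seed, {
    covars <- data.frame(
      sex = stats::rbinom(n, 1, 0.5),
      age = stats::runif(n, config$age_windows[[cohort]][1],
                         config$age_windows[[cohort]][2]),
      pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
      pc3 = stats::rnorm(n), pc4 = stats::rnorm(n),
      row.names = rownames(X)
    )
    mk_factor <- function(w, conf = 0) {
      signal <- as.vector(P %*% w) + conf * covars$pc1
      vs <- stats::var(signal)
      if (vs >= 1) stop("planted factor effects imply variance >= 1")
      signal + stats::rnorm(n, 0, sqrt(1 - vs))
    }
    g <- mk_factor(config$prs_effects_general, config$ancestry_confounding)
    s_ext <- mk_factor(config$prs_effects_ext)
    s_int <- mk_factor(config$prs_effects_int)
    s_dom <- cbind(int = s_int, ext = s_ext)[, config$domains, drop = FALSE]
    E <- matrix(stats::rnorm(n * length(lg)), n)
    Y <- g %o% lg + s_dom * rep(ls, each = n) + E * rep(sqrt(uniq), each = n)
    colnames(Y) <- sprintf("%s_sub%02d", config$domains,
                           stats::ave(seq_along(lg), config$domains, FUN = seq_along))
    rownames(Y) <- rownames(X)
    truth <- data.frame(g = g, s_ext = s_ext, s_int = s_int, row.names = rownames(X))
    truth <- cbind(truth, as.data.frame(P))
    list(subscales = Y, covariates = covars, truth = truth)
  })
}

#' Simulate a complete multi-cohort study
#'
#' Runs the full generator: a shared set of true causal effects, per-trait
#' discovery GWAS summary statistics, and per-cohort genotype panels,
#' symptom subscales and covariates.
#'
#' @param config a [sim_config()] object.
#' @return List with `gwas` (per-trait summary-stat tables), `effects`
#'   (true effect matrix), and `cohorts`, a list of per-cohort lists
#'   holding `panel`, `subscales`, `covariates`, `truth`.
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  # reference panel (largest cohort) defines MAFs used by the discovery GWAS
  panels <- lapply(seq_len(config$n_cohorts), function(i)
    simulate_genotypes(config, n = config$cohort_sizes[i],
                       seed = stage_seed(config$seed, paste0("genotypes", i))))
  map <- panels[[1]]$map
  effects <- draw_true_effects(config, map)
  gwas <- simulate_discovery_gwas(config, map, effects)
  cohorts <- lapply(seq_len(config$n_cohorts), function(i) {
    ph <- simulate_cohort_phenotypes(config, panels[[i]], effects, cohort = i)
    c(list(panel = panels[[i]]), ph)
  })
  names(cohorts) <- sprintf("cohort%d", seq_len(config$n_cohorts))
  list(gwas = gwas, effects = effects, cohorts = cohorts, config = config)
}
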