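#' Simulation configuration for a synthetic multi-cohort PRS study
#'
#' Bundles every knob of the synthetic-data generator: LD-blocked genotype
#' panels per cohort, discovery GWASs for a set of genetically correlated
#' traits, and multi-subscale symptom batteries generated from a bifactor
#' structure (one general factor plus orthogonal internalizing and
#' externalizing specific factors) with optional planted polygenic effects.
#'
#' Defaults emulate the study design the package targets: three cohorts of
#' 6575, 2418 and 254 children (9247 in total), 16 discovery traits with an
#' average pairwise genetic correlation of 0.4, and 12 symptom subscales
#' (6 internalizing, 6 externalizing) with loadings varying across
#' subscales (general 0.45-0.70, specific 0.30-0.50), as in real symptom
#' batteries. Heterogeneous loadings also keep the two-specific-factor
#' bifactor model identified, which constant within-domain loadings do
#' not.
#'
#' @param cohort_sizes integer vector, individuals per cohort.
#' @param n_snps number of variants on the synthetic panel.
#' @param block_size SNPs per LD block.
#' @param within_block_rho allelic correlation between adjacent SNPs in a
#'   block, in `[0, 1)`. LD decays as `rho^distance` within a block and is
#'   zero across blocks.
#' @param maf_range interval within `(0, 0.5]` from which each block's minor
#'   allele frequency is drawn (one MAF per block, shared by its SNPs, so
#'   the requested LD is always attainable).
#' @param n_traits number of discovery GWAS traits.
#' @param genetic_corr `n_traits x n_traits` positive-semidefinite matrix of
#'   genetic correlations between the traits' causal effects; default
#'   compound symmetry with off-diagonal 0.4.
#' @param discovery_n discovery GWAS sample size, recycled to `n_traits`.
#' @param causal_fraction proportion of panel SNPs that are causal, in
#'   `(0, 1]`. The causal set is shared across traits.
#' @param h2_trait variance of each trait explained by the panel's causal
#'   SNPs; sets the scale of true per-allele effects.
#' @param general_loadings,specific_loadings per-subscale loadings of the
#'   bifactor measurement model used to generate symptom subscales.
#' @param domains factor or character vector mapping each subscale to its
#'   specific domain (`"int"` or `"ext"`).
#' @param prs_effects_general,prs_effects_ext,prs_effects_int per-trait true
#'   standardized effects of the traits' polygenic values on the general,
#'   specific-externalizing and specific-internalizing factors.
#' @param ancestry_confounding size of a planted confounding path from the
#'   first ancestry component to the general factor (0 disables it).
#' @param age_windows list of `c(min, max)` assessment-age windows in years,
#'   one per cohort; recycled.
#' @param seed integer master seed.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [simulate_genotypes()], [simulate_discovery_gwas()],
#'   [simulate_cohort_phenotypes()], [simulate_study()]
#' @export
sim_config <- function(cohort_sizes = c(6575L, 2418L, 254L),
                       n_snps = 2000L,
                       block_size = 5L,
                       within_block_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_traits = 16L,
                       genetic_corr = NULL,
                       discovery_n = 5e5,
                       causal_fraction = 0.05,
                       h2_trait = 0.10,
                       general_loadings = rep(c(0.65, 0.55, 0.70, 0.50, 0.60, 0.45), 2),
                       specific_loadings = rep(c(0.35, 0.45, 0.30, 0.50, 0.40, 0.45), 2),
                       domains = rep(c("int", "ext"), each = 6),
                       prs_effects_general = numeric(n_traits),
                       prs_effects_ext = numeric(n_traits),
                       prs_effects_int = numeric(n_traits),
                       ancestry_confounding = 0,
                       age_windows = list(c(7.5, 8.3), c(6.0, 8.1), c(4.1, 6.2)),
                       seed = 1L) {
  if (is.null(genetic_corr)) {
    genetic_corr <- matrix(0.4, n_traits, n_traits)
    diag(genetic_corr) <- 1
  }
  cfg <- list(
    cohort_sizes = as.integer(cohort_sizes),
    n_cohorts = length(cohort_sizes),
    n_snps = as.integer(n_snps),
    block_size = as.integer(block_size),
    within_block_rho = within_block_rho,
    maf_range = maf_range,
    n_traits = as.integer(n_traits),
    genetic_corr = genetic_corr,
    discovery_n = rep_len(discovery_n, n_traits),
    causal_fraction = causal_fraction,
    h2_trait = h2_trait,
    general_loadings = general_loadings,
    specific_loadings = specific_loadings,
    domains = as.character(domains),
    prs_effects_general = rep_len(prs_effects_general, n_traits),
    prs_effects_ext = rep_len(prs_effects_ext, n_traits),
    prs_effects_int = rep_len(prs_effects_int, n_traits),
    ancestry_confounding = ancestry_confounding,
    age_windows = rep_len(age_windows, length(cohort_sizes)),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cohorts >= 1, all(cfg$cohort_sizes >= 1),
            cfg$n_snps >= 1, cfg$block_size >= 1)
  if (cfg$within_block_rho < 0 || cfg$within_block_rho >= 1)
    stop("'within_block_rho' must lie in [0, 1)")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("'maf_range' must be an interval within (0, 0.5]")
  G <- cfg$genetic_corr
  if (!isSymmetric(unname(G), tol = 1e-8))
    stop("'genetic_corr' must be symmetric")
  if (any(abs(diag(G) - 1) > 1e-8))
    stop("'genetic_corr' must have unit diagonal")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("'genetic_corr' must be positive semidefinite (smallest eigenvalue ",
         format(min(ev)), ")")
  if (any(cfg$discovery_n <= 0)) stop("'discovery_n' must be positive")
  if (cfg$causal_fraction <= 0 || cfg$causal_fraction > 1)
    stop("'causal_fraction' must lie in (0, 1]")
  p <- length(cfg$general_loadings)
  if (length(cfg$specific_loadings) != p || length(cfg$domains) != p)
    stop("loading vectors and domain map must have equal length")
  uniq <- 1 - cfg$general_loadings^2 - cfg$specific_loadings^2
  if (any(uniq <= 0))
    stop("loadings imply communality >= 1 for subscale(s) ",
         paste(which(uniq <= 0), collapse = ", "))
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic multi-cohort PRS study configuration\n")
  cat("  cohorts:", paste(x$cohort_sizes, collapse = "/"),
      sprintf("(total n = %d)\n", sum(x$cohort_sizes)))
  cat(sprintf("  panel: %d SNPs in blocks of %d, adjacent LD rho = %.2f\n",
              x$n_snps, x$block_size, x$within_block_rho))
  cat(sprintf("  traits: %d, discovery n = %s, causal fraction %.3f\n",
              x$n_traits, paste(unique(x$discovery_n), collapse = "/"),
              x$causal_fraction))
  cat(sprintf("  subscales: %d (%s)\n", length(x$domains),
              paste(sprintf("%d %s", table(x$domains), names(table(x$domains))),
                    collapse = ", ")))
  invisible(x)
}

# Run code with a private RNG stream; restores the caller's .Random.seed.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# Deterministic 32-bit sub-seed from a master seed and a stage label.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
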