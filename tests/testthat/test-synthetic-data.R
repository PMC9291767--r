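# Synthetic-data generator: genotypes, discovery GWAS, phenotypes.

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(within_block_rho = 1), "within_block_rho")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  G <- matrix(0.9, 3, 3); diag(G) <- 1; G[1, 2] <- G[2, 1] <- -0.9
  expect_error(sim_config(n_traits = 3, genetic_corr = G),
               "positive semidefinite")
  expect_error(sim_config(general_loadings = rep(0.9, 6),
                          specific_loadings = rep(0.5, 6),
                          domains = rep(c("int", "ext"), each = 3)),
               "communality")
  expect_error(sim_config(discovery_n = 0), "discovery_n")
})

test_that("dosages match the drawn allele frequency", {
  cfg <- sim_config(cohort_sizes = 10000, n_snps = 10, block_size = 5,
                    maf_range = c(0.3, 0.3), seed = 11)
  panel <- simulate_genotypes(cfg)
  expect_true(all(panel$dosage %in% 0:2))
  expect_lt(max(abs(colMeans(panel$dosage) - 0.6)), 0.02)
})

test_that("zero within-block correlation gives independent SNPs", {
  cfg <- sim_config(cohort_sizes = 10000, n_snps = 20, block_size = 5,
                    within_block_rho = 0, seed = 12)
  panel <- simulate_genotypes(cfg)
  R <- cor(panel$dosage)
  expect_lt(mean(abs(R[upper.tri(R)])), 0.03)
})

test_that("adjacent-SNP dosage r2 tracks the requested LD", {
  cfg <- sim_config(cohort_sizes = 10000, n_snps = 25, block_size = 5,
                    within_block_rho = 0.9, seed = 13)
  panel <- simulate_genotypes(cfg)
  r2 <- sapply(seq(1, 21, by = 5), function(j)
    sapply(j:(j + 3), function(k)
      cor(panel$dosage[, k], panel$dosage[, k + 1])^2))
  expect_true(all(r2 > 0.7 & r2 < 0.9))
  # across-block pairs are uncorrelated
  expect_lt(abs(cor(panel$dosage[, 5], panel$dosage[, 6])), 0.05)
})

test_that("null discovery GWAS z-statistics are calibrated", {
  cfg <- sim_config(cohort_sizes = 100, n_snps = 5000, block_size = 1,
                    n_traits = 1, discovery_n = 50000, seed = 14)
  map <- simulate_variant_map(cfg)
  B0 <- matrix(0, nrow(map), 1, dimnames = list(NULL, "trait01"))
  gw <- simulate_discovery_gwas(cfg, map, B0)[[1]]
  z2 <- (gw$BETA / gw$SE)^2
  expect_lt(abs(mean(z2) - 1), 0.05)
  expect_true(all(gw$P > 0 & gw$P <= 1))
  expect_true(all(gw$INFO >= 0 & gw$INFO <= 1))
})

test_that("causal-SNP z2 matches the noncentrality formula", {
  # beta = 0.05 at f = 0.3, N = 50000:
  # E[z2] = 1 + beta^2 * 2f(1-f) * N = 1 + 0.0025 * 0.42 * 50000 = 53.5
  cfg <- sim_config(cohort_sizes = 100, n_snps = 200, block_size = 1,
                    n_traits = 1, discovery_n = 50000,
                    maf_range = c(0.3, 0.3), seed = 15)
  map <- simulate_variant_map(cfg)
  B <- matrix(0.05, nrow(map), 1, dimnames = list(NULL, "trait01"))
  gw <- simulate_discovery_gwas(cfg, map, B)
  z2 <- (gw[[1]]$BETA / gw[[1]]$SE)^2
  ncp <- 1 + 0.05^2 * 2 * 0.3 * 0.7 * 50000
  expect_lt(abs(mean(z2) / ncp - 1), 0.2)
})

test_that("true causal effects carry the requested genetic correlation", {
  G <- matrix(0.5, 2, 2); diag(G) <- 1
  cfg <- sim_config(cohort_sizes = 100, n_snps = 2500, block_size = 1,
                    n_traits = 2, genetic_corr = G, causal_fraction = 0.8,
                    seed = 16)
  map <- simulate_variant_map(cfg)
  B <- draw_true_effects(cfg, map)
  causal <- attr(B, "causal")
  expect_gt(sum(causal), 1500)
  expect_lt(abs(cor(B[causal, 1], B[causal, 2]) - 0.5), 0.05)
})

test_that("subscale variances and factor structure are bookkept", {
  cfg <- sim_config(cohort_sizes = 10000, n_snps = 20, block_size = 5,
                    n_traits = 2, seed = 17)
  panel <- simulate_genotypes(cfg)
  B <- draw_true_effects(cfg, panel$map)
  ph <- simulate_cohort_phenotypes(cfg, panel, B)
  v <- apply(ph$subscales, 2, var)
  expect_lt(max(abs(v - 1)), 0.03)
  # empirical correlations converge to Lg Lg' + Ls Ls' + Psi
  lg <- cfg$general_loadings; ls <- cfg$specific_loadings
  dmask <- outer(cfg$domains, sort(unique(cfg$domains)), "==")
  Sig <- tcrossprod(lg) + tcrossprod(ls * dmask[, 1]) +
    tcrossprod(ls * dmask[, 2])
  diag(Sig) <- 1
  expect_lt(max(abs(cor(ph$subscales) - Sig)), 0.03)
  # orthogonal factors
  ct <- cor(ph$truth[, c("g", "s_ext", "s_int")])
  expect_lt(max(abs(ct[upper.tri(ct)])), 0.03)
  expect_equal(ncol(ph$covariates), 6)  # sex, age, 4 ancestry components
})

test_that("null polygenic weights leave the general factor unlinked", {
  cfg <- sim_config(cohort_sizes = 10000, n_snps = 20, block_size = 5,
                    n_traits = 2, seed = 18)
  panel <- simulate_genotypes(cfg)
  B <- draw_true_effects(cfg, panel$map)
  ph <- simulate_cohort_phenotypes(cfg, panel, B)
  expect_lt(abs(cor(ph$truth$trait01, ph$truth$g)), 0.03)
})

test_that("a planted general effect appears at its stated size", {
  cfg <- sim_config(cohort_sizes = 10000, n_snps = 20, block_size = 5,
                    n_traits = 2, prs_effects_general = c(0.10, 0),
                    seed = 19)
  panel <- simulate_genotypes(cfg)
  B <- draw_true_effects(cfg, panel$map)
  ph <- simulate_cohort_phenotypes(cfg, panel, B)
  expect_lt(abs(cor(ph$truth$trait01, ph$truth$g) - 0.10), 0.03)
  expect_lt(abs(var(ph$truth$g) - 1), 0.05)
})

test_that("invalid loadings and sizes raise errors in the generator", {
  cfg <- sim_config(cohort_sizes = 100, n_snps = 10, n_traits = 2, seed = 20)
  panel <- simulate_genotypes(cfg)
  B <- draw_true_effects(cfg, panel$map)
  bad <- cfg
  bad$general_loadings <- rep(0.9, 12)
  bad$specific_loadings <- rep(0.5, 12)
  expect_error(simulate_cohort_phenotypes(bad, panel, B), "communality")
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- sim_config(cohort_sizes = c(60, 40), n_snps = 30, n_traits = 2,
                    seed = 21)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohorts[[1]]$panel$dosage, s2$cohorts[[1]]$panel$dosage)
  expect_identical(s1$gwas, s2$gwas)
  expect_identical(s1$cohorts[[2]]$subscales, s2$cohorts[[2]]$subscales)
  # cohorts share one variant map but have independent dosages
  expect_identical(s1$cohorts[[1]]$panel$map, s1$cohorts[[2]]$panel$map)
})
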