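# C+T engine: QC, harmonization, clumping, scoring.

test_that("QC applies the MAF and INFO cutoffs", {
  ss <- make_sumstats(5)
  ss$EAF <- c(0.005, 0.02, 0.3, 0.15, 0.4)
  ss$INFO <- c(0.9, 0.7, 0.95, 0.85, 0.81)
  out <- qc_filter(ss)
  expect_equal(nrow(out), 3)
  expect_equal(out$SNP, c("s003", "s004", "s005"))
  qc <- attr(out, "qc")
  expect_equal(unname(qc["low_maf"] + qc["low_info"]), 2)
})

test_that("a variant at MAF 0.009 is excluded and 0.011 retained", {
  ss <- make_sumstats(2)
  ss$EAF <- c(0.009, 0.011)
  expect_equal(qc_filter(ss)$SNP, "s002")
  # EAF near 1 counts as low MAF too
  ss$EAF <- c(0.995, 0.5)
  expect_equal(qc_filter(ss)$SNP, "s002")
})

test_that("QC is the identity when everything passes", {
  ss <- make_sumstats(4)
  out <- qc_filter(ss)
  expect_equal(out$SNP, ss$SNP)
})

test_that("QC against a disjoint panel warns and returns empty", {
  ss <- make_sumstats(3)
  pm <- data.frame(snp_id = "zz", chrom = "9", pos = 1L, maf = 0.3)
  expect_warning(out <- qc_filter(ss, panel_map = pm), "no variants")
  expect_equal(nrow(out), 0)
})

test_that("allele harmonization orients effects to the panel", {
  pm <- data.frame(snp_id = c("s001", "s002", "s003"), chrom = "1",
                   pos = c(1000L, 2000L, 3000L),
                   a1 = c("A", "A", "A"), a2 = c("G", "G", "T"),
                   stringsAsFactors = FALSE)
  ss <- make_sumstats(3, pos = c(1000L, 2000L, 3000L))
  ss$A1 <- c("A", "G", "A"); ss$A2 <- c("G", "A", "T")
  ss$BETA <- c(0.1, 0.2, 0.5); ss$EAF <- c(0.3, 0.8, 0.3)
  out <- harmonize_alleles(ss, pm)
  rep <- attr(out, "harmonization")
  # same orientation: untouched; swapped: sign flip + EAF complement
  expect_equal(out$beta[out$snp_id == "s001"], 0.1)
  expect_equal(out$beta[out$snp_id == "s002"], -0.2)
  expect_equal(out$eaf[out$snp_id == "s002"], 0.2)
  # A/T ambiguous: dropped and tallied
  expect_false("s003" %in% out$snp_id)
  expect_equal(unname(rep["ambiguous"]), 1)
})

test_that("strand flips resolve and duplicates are named", {
  pm <- data.frame(snp_id = "s001", chrom = "1", pos = 1000L,
                   a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  ss <- make_sumstats(1, pos = 1000L)
  ss$A1 <- "T"; ss$A2 <- "C"; ss$BETA <- 0.3   # complement of A/G
  out <- harmonize_alleles(ss, pm)
  expect_equal(out$beta, 0.3)
  expect_equal(unname(attr(out, "harmonization")["strand_flipped"]), 1)
  pm2 <- rbind(pm, pm)
  expect_error(harmonize_alleles(ss, pm2), "1:1000")
})

test_that("greedy clumping keeps the most significant of an LD group", {
  set.seed(1)
  base <- rbinom(500, 2, 0.3)
  X <- cbind(base, base, base)
  X[sample(500, 60), 2] <- rbinom(60, 2, 0.3)
  X[sample(500, 60), 3] <- rbinom(60, 2, 0.3)
  panel <- make_panel(X, pos = c(1000L, 50000L, 100000L))
  eff <- data.frame(snp_id = panel$map$snp_id, chrom = "1",
                    pos = panel$map$pos, beta = 0.1,
                    p = c(1e-8, 1e-5, 1e-3), stringsAsFactors = FALSE)
  out <- clump(eff, panel, window_kb = 250, r2_max = 0.1)
  expect_equal(out$snp_id, "s001")
  expect_equal(attr(out, "n_removed"), 2L)
})

test_that("variants outside the window are both retained", {
  set.seed(2)
  base <- rbinom(500, 2, 0.3)
  panel <- make_panel(cbind(base, base), pos = c(1000L, 301000L))
  eff <- data.frame(snp_id = panel$map$snp_id, chrom = "1",
                    pos = panel$map$pos, beta = 0.1, p = c(1e-8, 1e-3),
                    stringsAsFactors = FALSE)
  out <- clump(eff, panel, window_kb = 250, r2_max = 0.1)
  expect_equal(nrow(out), 2)
})

test_that("monomorphic variants clump as if uncorrelated, with warning", {
  set.seed(3)
  X <- cbind(rbinom(200, 2, 0.3), rep(0, 200))
  panel <- make_panel(X, pos = c(1000L, 2000L))
  eff <- data.frame(snp_id = panel$map$snp_id, chrom = "1",
                    pos = panel$map$pos, beta = 0.1, p = c(1e-4, 1e-2),
                    stringsAsFactors = FALSE)
  expect_warning(out <- clump(eff, panel, 250, 0.1), "monomorphic")
  expect_equal(nrow(out), 2)
})

test_that("clumping matches the step-by-step reference trace", {
  for (seed in 1:25) {
    inst <- random_clump_instance(seed)
    got <- clump(inst$effects, inst$panel, window_kb = 100, r2_max = 0.2)
    expect_equal(sort(got$snp_id),
                 oracle_clump_ids(inst$effects, inst$panel, 100, 0.2),
                 info = paste("instance", seed))
  }
})

test_that("clump output is invariant to input row order", {
  inst <- random_clump_instance(99)
  got1 <- clump(inst$effects, inst$panel, 100, 0.2)
  set.seed(1)
  got2 <- clump(inst$effects[sample(nrow(inst$effects)), ], inst$panel,
                100, 0.2)
  expect_equal(got1$snp_id, got2$snp_id)
})

test_that("scores are threshold-masked dosage-weighted sums", {
  X <- matrix(c(0, 1, 2), 1, 3)
  panel <- make_panel(X, pos = c(1L, 1000000L, 2000000L))
  eff <- data.frame(snp_id = panel$map$snp_id, chrom = "1",
                    pos = panel$map$pos, beta = c(0.2, -0.1, 0.4),
                    p = c(0.01, 0.04, 0.2), stringsAsFactors = FALSE)
  pr <- prs_score(panel, eff, thresholds = c(1, 0.05), standardize = FALSE)
  expect_equal(unname(pr$scores[1, ]), c(0.7, -0.1))
  expect_equal(unname(pr$n_snps), c(3L, 2L))
  expect_error(prs_score(panel, eff, thresholds = numeric(0)), "empty")
})

test_that("SNP counts nest along the threshold grid", {
  inst <- random_clump_instance(7)
  pr <- prs_score(inst$panel, inst$effects, thresholds = default_thresholds(),
                  standardize = FALSE)
  expect_true(all(diff(pr$n_snps) <= 0))  # grid is stored descending
})

test_that("standardized profiles have zero mean and unit SD", {
  inst <- random_clump_instance(8)
  pr <- prs_score(inst$panel, inst$effects, thresholds = c(1, 0.5))
  expect_lt(max(abs(colMeans(pr$scores))), 1e-12)
  expect_lt(max(abs(apply(pr$scores, 2, sd) - 1)), 1e-12)
})

test_that("missing dosages are mean-imputed before scoring", {
  X <- matrix(c(0, 1, 2, NA), 2, 2)
  panel <- make_panel(X, pos = c(1000L, 2000L))
  eff <- data.frame(snp_id = panel$map$snp_id, chrom = "1",
                    pos = panel$map$pos, beta = c(1, 1), p = c(0.01, 0.01),
                    stringsAsFactors = FALSE)
  pr <- prs_score(panel, eff, thresholds = 1, standardize = FALSE)
  expect_equal(unname(pr$scores[, 1]), c(0 + 2, 1 + 2))
})

test_that("PRS accuracy grows with discovery sample size", {
  mk <- function(N) {
    cfg <- sim_config(cohort_sizes = 2000, n_snps = 300, n_traits = 1,
                      discovery_n = N, causal_fraction = 0.2, seed = 31)
    panel <- simulate_genotypes(cfg)
    B <- draw_true_effects(cfg, panel$map)
    gw <- simulate_discovery_gwas(cfg, panel$map, B)[[1]]
    eff <- harmonize_alleles(qc_filter(gw), panel$map)
    eff <- clump(eff, panel, 250, 0.1)
    pr <- prs_score(panel, eff, thresholds = 1)
    cor(pr$scores[, 1], panel$dosage %*% B[, 1])
  }
  expect_gt(abs(mk(5e5)), abs(mk(2e3)))
})

test_that("summary stats, panels and profiles round-trip through text", {
  tmp <- withr::local_tempdir()
  ss <- make_sumstats(4)
  f <- file.path(tmp, "ss.tsv")
  write_sumstats(ss, f)
  expect_equal(read_sumstats(f), ss)
  # column remapping on read
  ss2 <- ss; names(ss2)[names(ss2) == "P"] <- "pval"
  write_sumstats(ss2, f)
  expect_equal(read_sumstats(f, col_map = c(P = "pval"))$P, ss$P)

  cfg <- sim_config(cohort_sizes = 15, n_snps = 6, seed = 32)
  panel <- simulate_genotypes(cfg)
  write_panel(panel, file.path(tmp, "pan"))
  got <- read_panel(file.path(tmp, "pan"))
  expect_equal(got$dosage, panel$dosage)
  expect_equal(got$map$pos, panel$map$pos)

  inst <- random_clump_instance(5)
  pr <- prs_score(inst$panel, inst$effects, thresholds = c(1, 0.05))
  fp <- file.path(tmp, "prs.tsv")
  write_prs_profile(pr, fp)
  got <- read_prs_profile(fp)
  expect_equal(unname(got$scores), unname(pr$scores), tolerance = 1e-6)
  expect_equal(got$thresholds, pr$thresholds)
})
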