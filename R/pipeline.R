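#' Run all per-cohort stages: PRS construction, bifactor, associations
#'
#' For one cohort, runs summary-statistic QC, allele harmonization against
#' the cohort panel, greedy LD clumping, C+T scoring at the threshold
#' grid, bifactor fitting on the symptom subscales, regression factor
#' scores, and the separate PRS-outcome regressions for every
#' trait x threshold x outcome combination.
#'
#' @param cohort list with `panel` (`geno_panel`), `subscales` (n x p
#'   matrix) and `covariates` (data frame), as produced by
#'   [simulate_study()] or assembled from files.
#' @param gwas named list of summary-statistic data frames, one per trait.
#' @param thresholds p-value threshold grid (default
#'   [default_thresholds()]).
#' @param clump_kb,clump_r2 clumping window (kb) and r² threshold;
#'   cohort-specific values are passed here (e.g. 250/0.1 or 500/0.25).
#' @param domains subscale-to-domain map; by default parsed from subscale
#'   column names of the form `<domain>_<name>`.
#' @param maf_min,info_min QC cutoffs forwarded to [qc_filter()].
#' @param label cohort label used in messages and outputs.
#' @param verbose emit progress messages.
#' @return A cohort bundle: list with `label`, `n`, `prs` (named list of
#'   `prs_profile`), `fit` (`bifactor`), `scores`, `covariates`, `assoc`
#'   (association data frame), `skipped` (named reasons for any skipped
#'   trait).
#' @export
run_cohort <- function(cohort, gwas, thresholds = default_thresholds(),
                       clump_kb = 250, clump_r2 = 0.1, domains = NULL,
                       maf_min = 0.01, info_min = 0.80,
                       label = "cohort", verbose = FALSE) {
  panel <- cohort$panel
  Y <- as.matrix(cohort$subscales)
  if (is.null(domains)) domains <- sub("_.*$", "", colnames(Y))
  say <- function(...) if (verbose) message(sprintf(...))

  prs <- list()
  skipped <- character(0)
  for (tr in names(gwas)) {
    ss <- qc_filter(gwas[[tr]], maf_min = maf_min, info_min = info_min)
    eff <- harmonize_alleles(ss, panel$map)
    if (nrow(eff) == 0L) {
      skipped[tr] <- "no variants overlap the panel after harmonization"
      say("[%s] %s: skipped (%s)", label, tr, skipped[tr])
      next
    }
    eff <- clump(eff, panel, window_kb = clump_kb, r2_max = clump_r2)
    prs[[tr]] <- prs_score(panel, eff, thresholds, standardize = TRUE)
    say("[%s] %s: %d index SNPs at T = 1", label, tr,
        max(prs[[tr]]$n_snps))
  }

  fit <- fit_bifactor(Y, domains)
  sc <- factor_scores(fit, Y)
  outs <- colnames(sc)

  rows <- vector("list", length(prs) * length(thresholds) * length(outs))
  i <- 0
  for (tr in names(prs)) {
    S <- prs[[tr]]$scores
    for (k in seq_along(prs[[tr]]$thresholds)) {
      if (stats::sd(S[, k]) == 0) next  # empty threshold: no testable score
      for (o in outs) {
        i <- i + 1
        rows[[i]] <- fit_separate_model(
          sc[, o], S[, k], cohort$covariates,
          trait = tr, threshold = prs[[tr]]$thresholds[k], outcome_name = o)
      }
    }
  }
  assoc <- do.call(rbind, rows[seq_len(i)])
  list(label = label, n = nrow(sc), prs = prs, fit = fit, scores = sc,
       covariates = cohort$covariates, assoc = assoc, skipped = skipped)
}

#' Meta-analyze cohort bundles and assemble study-level results
#'
#' Pools the per-cohort separate-model coefficients per
#' trait x threshold x outcome with [meta_re2()], selects each
#' trait-outcome's best threshold by meta-analytic p, fits the mutually
#' adjusted all-PRS model for the general factor in every cohort and
#' meta-analyzes it, computes the Li-Ji effective number of tests from the
#' largest cohort's PRS correlation matrix, flags independent
#' contributions, and estimates the cross-validated incremental R-squared
#' of the joint PRS model per cohort.
#'
#' @param bundles list of cohort bundles from [run_cohort()]; at least 2.
#' @param alpha family-wise error rate (default 0.05).
#' @param cv_k,cv_repeats cross-validation folds and repeats.
#' @param seed integer seed for the cross-validation partitions.
#' @param cv logical; run the (relatively expensive) cross-validation
#'   stage (default `TRUE`).
#' @return Object of class `"prs_meta_study"`: list with `separate` (meta
#'   table: trait, outcome, threshold, beta, tau, se, p), `best`
#'   (selected thresholds), `mutual` (mutually adjusted meta table with
#'   `p_separate`, `significant_adjusted`, `independent` flags), `meff`,
#'   `alpha_adjusted`, `cv` (per-cohort and sample-size-weighted average
#'   delta R²), `n_total`, `cohorts`.
#' @export
run_meta <- function(bundles, alpha = 0.05, cv_k = 10L, cv_repeats = 100L,
                     seed = 1L, cv = TRUE) {
  if (length(bundles) < 2)
    stop("meta-analysis requires at least 2 cohorts; got ", length(bundles))
  labels <- vapply(bundles, `[[`, "", "label")
  traits <- Reduce(union, lapply(bundles, function(b) unique(b$assoc$trait)))
  grids <- lapply(bundles, function(b) sort(unique(b$assoc$threshold)))
  if (length(unique(vapply(grids, paste, "", collapse = ","))) != 1)
    stop("threshold grids differ between cohorts")
  n_total <- sum(vapply(bundles, `[[`, 0L, "n"))

  all_assoc <- do.call(rbind, lapply(seq_along(bundles), function(i)
    cbind(cohort = labels[i], bundles[[i]]$assoc)))
  key <- interaction(all_assoc$trait, all_assoc$outcome, all_assoc$threshold,
                     drop = TRUE)
  sep_rows <- lapply(split(all_assoc, key), function(d) {
    if (nrow(d) < 2) return(NULL)  # trait absent from all but one cohort
    m <- meta_re2(d$beta, d$se, n = d$n, labels = d$cohort)
    data.frame(trait = d$trait[1], outcome = d$outcome[1],
               threshold = d$threshold[1], beta = m$beta, tau = m$tau,
               se = m$se, p = m$p, n = m$n_total,
               stringsAsFactors = FALSE)
  })
  separate <- do.call(rbind, sep_rows)
  rownames(separate) <- NULL
  separate <- separate[order(separate$outcome, separate$trait,
                             -separate$threshold), ]

  best <- select_best_threshold(separate)

  # Li-Ji Meff from the largest cohort's PRSs at all thresholds
  big <- bundles[[which.max(vapply(bundles, `[[`, 0L, "n"))]]
  prs_all <- do.call(cbind, lapply(names(big$prs), function(tr) {
    S <- big$prs[[tr]]$scores
    colnames(S) <- paste0(tr, "_", colnames(S))
    S
  }))
  prs_all <- prs_all[, apply(prs_all, 2, stats::sd) > 0, drop = FALSE]
  meff <- meff_li_ji(stats::cor(prs_all))
  alpha_adj <- adjust_alpha(alpha, meff)

  # mutually adjusted all-PRS model for the general factor
  bg <- best[best$outcome == "general", ]
  mut_cohort <- lapply(bundles, function(b) {
    Pm <- sapply(seq_len(nrow(bg)), function(j) {
      pr <- b$prs[[bg$trait[j]]]
      pr$scores[, which(pr$thresholds == bg$threshold[j])]
    })
    colnames(Pm) <- bg$trait
    fit_mutual_model(b$scores[, "general"], Pm, b$covariates,
                     outcome_name = "general")
  })
  mut_all <- do.call(rbind, lapply(seq_along(mut_cohort), function(i)
    cbind(cohort = labels[i], mut_cohort[[i]])))
  mut_rows <- lapply(split(mut_all, mut_all$trait), function(d) {
    m <- meta_re2(d$beta, d$se, n = d$n, labels = d$cohort)
    data.frame(trait = d$trait[1], outcome = "general",
               threshold = bg$threshold[match(d$trait[1], bg$trait)],
               beta = m$beta, tau = m$tau, se = m$se, p = m$p,
               n = m$n_total, stringsAsFactors = FALSE)
  })
  mutual <- do.call(rbind, mut_rows)
  rownames(mutual) <- NULL
  mutual$p_separate <- bg$p[match(mutual$trait, bg$trait)]
  mutual$significant_adjusted <- mutual$p_separate < alpha_adj
  mutual$independent <- flag_independent(mutual$p_separate, mutual$p,
                                         alpha_adj)

  cv_out <- NULL
  if (cv) {
    cv_cohort <- vapply(seq_along(bundles), function(i) {
      b <- bundles[[i]]
      Pm <- sapply(seq_len(nrow(bg)), function(j) {
        pr <- b$prs[[bg$trait[j]]]
        pr$scores[, which(pr$thresholds == bg$threshold[j])]
      })
      cv_delta_r2(b$scores[, "general"], Pm, b$covariates,
                  k = cv_k, repeats = cv_repeats,
                  seed = stage_seed(seed, paste0("cv", i)))$delta_r2
    }, 0)
    ns <- vapply(bundles, `[[`, 0L, "n")
    cv_out <- list(per_cohort = stats::setNames(cv_cohort, labels),
                   average = sum(ns * cv_cohort) / sum(ns),
                   k = cv_k, repeats = cv_repeats)
  }

  structure(list(separate = separate, best = best, mutual = mutual,
                 meff = meff, alpha = alpha, alpha_adjusted = alpha_adj,
                 cv = cv_out, n_total = n_total, cohorts = labels),
            class = "prs_meta_study")
}

#' @export
print.prs_meta_study <- function(x, digits = 3, ...) {
  cat(sprintf("Multi-cohort PRS study: %d cohorts, combined n = %d\n",
              length(x$cohorts), x$n_total))
  cat(sprintf("  Li-Ji Meff = %d -> adjusted alpha = %.3g\n",
              x$meff$meff, x$alpha_adjusted))
  bg <- x$best[x$best$outcome == "general", ]
  sig <- x$mutual[x$mutual$significant_adjusted, ]
  cat(sprintf("  %d/%d traits significant (adjusted) for the general factor; %d independent\n",
              nrow(sig), nrow(bg), sum(x$mutual$independent)))
  if (!is.null(x$cv))
    cat(sprintf("  joint multi-PRS CV delta R2 (weighted avg) = %.4f\n",
                x$cv$average))
  invisible(x)
}

#' Simulate a study and run the full analysis end to end
#'
#' Convenience wrapper: [simulate_study()], [run_cohort()] for every
#' cohort, then [run_meta()].
#'
#' @param config a [sim_config()] object.
#' @param ... forwarded to [run_meta()] (e.g. `cv_repeats`, `cv`).
#' @param clump_kb,clump_r2 clumping parameters, recycled per cohort so
#'   cohort-specific settings (e.g. 250/0.1, 250/0.1, 500/0.25) are
#'   possible.
#' @param verbose emit progress messages.
#' @return List: `study` (`prs_meta_study`), `bundles`, `sim`.
#' @export
run_study <- function(config, clump_kb = 250, clump_r2 = 0.1,
                      verbose = FALSE, ...) {
  sim <- simulate_study(config)
  kb <- rep_len(clump_kb, config$n_cohorts)
  r2 <- rep_len(clump_r2, config$n_cohorts)
  bundles <- lapply(seq_len(config$n_cohorts), function(i)
    run_cohort(sim$cohorts[[i]], sim$gwas, clump_kb = kb[i], clump_r2 = r2[i],
               label = names(sim$cohorts)[i], verbose = verbose))
  study <- run_meta(bundles, seed = stage_seed(config$seed, "cv"), ...)
  list(study = study, bundles = bundles, sim = sim)
}

#' Write study-level tables as TSV files
#'
#' Writes `separate.tsv`, `mutual.tsv`, `best_thresholds.tsv` and a
#' one-line `summary.tsv` (Meff, adjusted alpha, combined n, CV delta R²)
#' into a directory.
#'
#' @param study `prs_meta_study` object.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_study_tables <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(study$separate, file.path(dir, "separate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$mutual, file.path(dir, "mutual.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$best, file.path(dir, "best_thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- data.frame(meff = study$meff$meff,
                     alpha_adjusted = study$alpha_adjusted,
                     n_total = study$n_total,
                     cv_delta_r2 = if (is.null(study$cv)) NA
                                   else study$cv$average)
  utils::write.table(summ, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
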