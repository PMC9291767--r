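#' Quality-control filter for GWAS summary statistics
#'
#' Excludes variants with minor allele frequency below `maf_min` or
#' imputation quality (INFO) below `info_min`. By default MAF and INFO are
#' taken from the summary-statistic table itself (MAF = `min(EAF, 1-EAF)`);
#' if a panel variant map with a `maf` column is supplied, its frequencies
#' take precedence and variants absent from the panel are dropped.
#'
#' @param records summary-statistic data frame with columns
#'   `SNP, CHR, BP, A1, A2, BETA, SE, P, EAF, INFO`.
#' @param panel_map optional panel variant map (`snp_id`, `chrom`, `pos`,
#'   `maf`) providing target-panel frequencies.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param info_min minimum INFO score (default 0.80).
#' @return The retained subset, with attribute `"qc"` = named counts
#'   (`input`, `low_maf`, `low_info`, `unmatched`, `retained`).
#' @export
qc_filter <- function(records, panel_map = NULL, maf_min = 0.01, info_min = 0.80) {
  check_sumstats(records)
  n_in <- nrow(records)
  unmatched <- 0L
  if (!is.null(panel_map)) {
    key <- paste(records$CHR, records$BP)
    pkey <- paste(panel_map$chrom, panel_map$pos)
    idx <- match(key, pkey)
    miss <- is.na(idx)
    idx[miss] <- match(records$SNP[miss], panel_map$snp_id)
    unmatched <- sum(is.na(idx))
    maf <- panel_map$maf[idx]
    if ("info" %in% names(panel_map)) {
      info <- panel_map$info[idx]
      info[is.na(info)] <- records$INFO[is.na(info)]
    } else info <- records$INFO
    keep_match <- !is.na(idx)
  } else {
    maf <- pmin(records$EAF, 1 - records$EAF)
    info <- records$INFO
    keep_match <- rep(TRUE, n_in)
  }
  low_maf <- keep_match & !is.na(maf) & maf < maf_min
  low_info <- keep_match & !is.na(info) & info < info_min
  keep <- keep_match & !low_maf & !low_info
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no variants retained after QC", call. = FALSE)
  attr(out, "qc") <- c(input = n_in, low_maf = sum(low_maf),
                       low_info = sum(low_info), unmatched = unmatched,
                       retained = nrow(out))
  out
}

check_sumstats <- function(records) {
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P", "EAF", "INFO")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("summary statistics lack column(s): ", paste(miss, collapse = ", "))
  if (any(records$P <= 0 | records$P > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  invisible(records)
}

AMBIGUOUS_PAIRS <- c("A/T", "T/A", "C/G", "G/C")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize summary-statistic alleles to a target panel
#'
#' Joins variants to the panel by chromosome and position (falling back to
#' rsid), orients every effect to the panel's counted allele, and drops
#' what cannot be resolved. If the effect allele equals the counted allele
#' the effect is kept as is; if it equals the panel's other allele the
#' effect is negated and the EAF complemented. Strand flips (both alleles
#' complemented) are resolved the same way; strand-ambiguous variants
#' (A/T, C/G) and allele mismatches are dropped and counted.
#'
#' @param records QC'd summary-statistic data frame.
#' @param panel_map panel variant map (`snp_id`, `chrom`, `pos`, `a1`, `a2`).
#' @return Data frame of matched effects aligned to panel variants, columns
#'   `snp_id, chrom, pos, beta, p, eaf`, with attribute `"harmonization"` =
#'   counts (`matched`, `flipped`, `strand_flipped`, `ambiguous`,
#'   `mismatched`, `unmatched`).
#' @export
harmonize_alleles <- function(records, panel_map) {
  check_sumstats(records)
  dup <- duplicated(paste(panel_map$chrom, panel_map$pos))
  if (any(dup))
    stop("duplicate panel positions: ",
         paste(unique(paste0(panel_map$chrom, ":", panel_map$pos)[dup]),
               collapse = ", "))
  dupr <- duplicated(paste(records$CHR, records$BP))
  if (any(dupr))
    stop("duplicate summary-statistic positions: ",
         paste(unique(paste0(records$CHR, ":", records$BP)[dupr]),
               collapse = ", "))
  key <- paste(records$CHR, records$BP)
  pkey <- paste(panel_map$chrom, panel_map$pos)
  idx <- match(key, pkey)
  miss <- is.na(idx)
  idx[miss] <- match(records$SNP[miss], panel_map$snp_id)
  unmatched <- sum(is.na(idx))

  ok <- !is.na(idx)
  r <- records[ok, , drop = FALSE]
  p <- panel_map[idx[ok], , drop = FALSE]
  ambig <- paste0(r$A1, "/", r$A2) %in% AMBIGUOUS_PAIRS |
    paste0(p$a1, "/", p$a2) %in% AMBIGUOUS_PAIRS
  same <- r$A1 == p$a1 & r$A2 == p$a2
  swapped <- r$A1 == p$a2 & r$A2 == p$a1
  flip_same <- COMPLEMENT[r$A1] == p$a1 & COMPLEMENT[r$A2] == p$a2
  flip_swap <- COMPLEMENT[r$A1] == p$a2 & COMPLEMENT[r$A2] == p$a1
  use_same <- !ambig & (same | flip_same)
  use_swap <- !ambig & !same & !flip_same & (swapped | flip_swap)
  mismatched <- sum(!ambig & !use_same & !use_swap)

  keep <- use_same | use_swap
  sgn <- ifelse(use_swap[keep], -1, 1)
  out <- data.frame(
    snp_id = p$snp_id[keep], chrom = p$chrom[keep], pos = p$pos[keep],
    beta = r$BETA[keep] * sgn, p = r$P[keep],
    eaf = ifelse(use_swap[keep], 1 - r$EAF[keep], r$EAF[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "harmonization") <- c(
    matched = sum(use_same & same), flipped = sum(use_swap & swapped),
    strand_flipped = sum((use_same & !same) | (use_swap & !swapped)),
    ambiguous = sum(ambig), mismatched = mismatched, unmatched = unmatched
  )
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unclaimed variant as an index SNP and
#' removes all unclaimed variants within `window_kb` kilobases whose
#' squared dosage correlation with the index exceeds `r2_max`. LD is
#' computed in the target panel itself. Ties on p are broken by ascending
#' (chromosome, position). Monomorphic variants have undefined r²; it is
#' treated as 0 with a warning.
#'
#' @param effects harmonized effect table from [harmonize_alleles()]
#'   (columns `snp_id`, `chrom`, `pos`, `p` at minimum).
#' @param panel `geno_panel` providing dosages for LD.
#' @param window_kb half-window in kb around the index SNP (default 250).
#' @param r2_max r² threshold above which neighbours are removed
#'   (default 0.1).
#' @return The index-SNP subset of `effects` (original column set), sorted
#'   by position, with attribute `"n_removed"`.
#' @export
clump <- function(effects, panel, window_kb = 250, r2_max = 0.1) {
  if (window_kb <= 0) stop("'window_kb' must be positive")
  if (r2_max < 0 || r2_max > 1) stop("'r2_max' must lie in [0, 1]")
  m <- nrow(effects)
  if (m == 0L) return(effects)
  col <- match(effects$snp_id, colnames(panel$dosage))
  if (anyNA(col))
    stop("effects contain variants absent from the panel: ",
         paste(utils::head(effects$snp_id[is.na(col)], 5), collapse = ", "))
  X <- panel$dosage[, col, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning("monomorphic variant(s) in panel; treating their r² as 0",
            call. = FALSE)
  ord <- order(effects$p, effects$chrom, effects$pos)
  window <- window_kb * 1000
  claimed <- logical(m)   # removed by a previous index
  kept <- logical(m)
  for (i in ord) {
    if (claimed[i] || kept[i]) next
    kept[i] <- TRUE
    near <- which(!claimed & !kept &
                    effects$chrom == effects$chrom[i] &
                    abs(effects$pos - effects$pos[i]) <= window)
    if (length(near)) {
      if (sds[i] == 0) next  # undefined LD treated as r2 = 0
      r <- suppressWarnings(stats::cor(X[, i], X[, near, drop = FALSE]))
      r[is.na(r)] <- 0
      claimed[near[r^2 > r2_max]] <- TRUE
    }
  }
  out <- effects[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(claimed)
  out
}

#' Default p-value threshold grid
#'
#' The 15 descending p-value cutoffs at which scores are computed.
#' @return Numeric vector of thresholds.
#' @export
default_thresholds <- function() {
  c(1, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05, 0.01,
    1e-3, 1e-4, 1e-5, 1e-6, 1e-7, 5e-8, 1e-8)
}

#' Compute C+T polygenic scores at a grid of p-value thresholds
#'
#' `score(i, T) = sum over SNPs j with p_j <= T of dosage_ij * beta_j`.
#' Missing dosages are mean-imputed per variant. Columns can be z-scored
#' so downstream regressions report standardized coefficients.
#'
#' @param panel `geno_panel`.
#' @param effects clumped, harmonized effect table (`snp_id`, `beta`, `p`).
#' @param thresholds descending p-value cutoffs (default
#'   [default_thresholds()]).
#' @param standardize z-score each threshold column (default `TRUE`).
#'   Columns with zero variance (no SNPs pass) are left at zero.
#' @return A `prs_profile`: list with `ids`, `thresholds`, `scores`
#'   (individuals x thresholds), `n_snps` per threshold, `standardized`.
#' @export
prs_score <- function(panel, effects, thresholds = default_thresholds(),
                      standardize = TRUE) {
  if (length(thresholds) == 0L) stop("threshold grid is empty")
  thresholds <- sort(thresholds, decreasing = TRUE)
  col <- match(effects$snp_id, colnames(panel$dosage))
  if (anyNA(col))
    stop("effects contain variants absent from the panel")
  X <- panel$dosage[, col, drop = FALSE]
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  S <- matrix(0, nrow(X), length(thresholds),
              dimnames = list(rownames(X), format_thresholds(thresholds)))
  nsnp <- integer(length(thresholds))
  for (k in seq_along(thresholds)) {
    sel <- effects$p <= thresholds[k]
    nsnp[k] <- sum(sel)
    if (nsnp[k] > 0)
      S[, k] <- X[, sel, drop = FALSE] %*% effects$beta[sel]
  }
  if (standardize) {
    mu <- colMeans(S)
    sdv <- apply(S, 2, stats::sd)
    pos <- sdv > 0
    S[, pos] <- scale(S[, pos, drop = FALSE])
    S[, !pos] <- 0
  }
  structure(list(ids = rownames(X), thresholds = thresholds, scores = S,
                 n_snps = stats::setNames(nsnp, colnames(S)),
                 standardized = standardize),
            class = "prs_profile")
}

format_thresholds <- function(t)
  paste0("pT_", format(t, scientific = FALSE, trim = TRUE, drop0trailing = TRUE))

#' @export
print.prs_profile <- function(x, ...) {
  cat(sprintf("PRS profile: %d individuals x %d thresholds%s\n",
              length(x$ids), length(x$thresholds),
              if (x$standardized) " (standardized)" else ""))
  print(x$n_snps)
  invisible(x)
}

## ---- plain-text interchange -------------------------------------------

#' Read / write GWAS summary statistics as tab-delimited text
#'
#' Columns: `SNP, CHR, BP, A1, A2, BETA, SE, P, EAF, INFO`. Column names
#' can be remapped on read via `col_map`.
#'
#' @param records summary-statistic data frame.
#' @param file path.
#' @param col_map named character vector mapping standard names to the
#'   file's names, e.g. `c(SNP = "rsid", P = "pval")`.
#' @return `read_sumstats` returns the data frame; `write_sumstats` its
#'   file path, invisibly.
#' @export
write_sumstats <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(file, col_map = NULL) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map))
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(d))
      if (!is.na(j)) names(d)[j] <- std
    }
  d$CHR <- as.character(d$CHR)
  check_sumstats(d)
  d
}

#' Read / write a genotype panel as plain text
#'
#' Two files: `<prefix>.dosage.tsv` (variants in rows: `snp_id` then one
#' column per individual) and `<prefix>.map.tsv` (variant metadata).
#'
#' @param panel `geno_panel`.
#' @param prefix file path prefix.
#' @return `read_panel` returns a `geno_panel`; `write_panel` the prefix,
#'   invisibly.
#' @export
write_panel <- function(panel, prefix) {
  d <- data.frame(snp_id = colnames(panel$dosage), t(panel$dosage),
                  check.names = FALSE)
  utils::write.table(d, paste0(prefix, ".dosage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$map, paste0(prefix, ".map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix) {
  d <- utils::read.table(paste0(prefix, ".dosage.tsv"), header = TRUE,
                         sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  map <- utils::read.table(paste0(prefix, ".map.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  map$chrom <- as.character(map$chrom)
  X <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(X) <- d$snp_id
  structure(list(dosage = X, map = map), class = "geno_panel")
}

#' Read / write a PRS profile as tab-delimited text
#'
#' One row per individual, one column per threshold.
#' @param profile `prs_profile`.
#' @param file path.
#' @return `read_prs_profile` returns a `prs_profile` (thresholds recovered
#'   from column names); `write_prs_profile` the path, invisibly.
#' @export
write_prs_profile <- function(profile, file) {
  d <- data.frame(id = profile$ids, profile$scores, check.names = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_prs_profile
#' @export
read_prs_profile <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  S <- as.matrix(d[, -1, drop = FALSE])
  rownames(S) <- d$id
  thr <- as.numeric(sub("^pT_", "", colnames(S)))
  structure(list(ids = d$id, thresholds = thr, scores = S,
                 n_snps = rep(NA_integer_, ncol(S)),
                 standardized = NA),
            class = "prs_profile")
}
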