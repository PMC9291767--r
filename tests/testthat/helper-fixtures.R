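# Shared fixture builders and independent reference implementations.

# Assemble a geno_panel directly from a dosage matrix and positions.
make_panel <- function(X, pos, chrom = "1", a1 = NULL, a2 = NULL) {
  m <- ncol(X)
  ids <- sprintf("s%03d", seq_len(m))
  colnames(X) <- ids
  rownames(X) <- sprintf("i%04d", seq_len(nrow(X)))
  map <- data.frame(
    snp_id = ids, chrom = rep_len(as.character(chrom), m), pos = pos,
    a1 = a1 %||% rep("A", m), a2 = a2 %||% rep("G", m),
    maf = colMeans(X) / 2, block = seq_len(m), stringsAsFactors = FALSE)
  structure(list(dosage = X, map = map), class = "geno_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal well-formed summary-statistic table.
make_sumstats <- function(n = 5, beta = 0.1, p = 0.01, eaf = 0.3, info = 0.95,
                          a1 = "A", a2 = "G", pos = NULL, chrom = "1") {
  data.frame(
    SNP = sprintf("s%03d", seq_len(n)), CHR = rep_len(chrom, n),
    BP = pos %||% seq_len(n) * 1000L,
    A1 = rep_len(a1, n), A2 = rep_len(a2, n),
    BETA = rep_len(beta, n), SE = rep_len(0.01, n), P = rep_len(p, n),
    EAF = rep_len(eaf, n), INFO = rep_len(info, n),
    stringsAsFactors = FALSE)
}

# Literal step-by-step greedy clumping trace, kept deliberately naive:
# full precomputed r2 matrix, explicit while-loop over the remaining set.
oracle_clump_ids <- function(effects, panel, window_kb, r2_max) {
  idx <- match(effects$snp_id, colnames(panel$dosage))
  R2 <- suppressWarnings(stats::cor(panel$dosage[, idx, drop = FALSE]))^2
  R2[is.na(R2)] <- 0
  remaining <- seq_len(nrow(effects))
  kept <- integer(0)
  while (length(remaining)) {
    o <- remaining[order(effects$p[remaining], effects$chrom[remaining],
                         effects$pos[remaining])]
    i <- o[1]
    kept <- c(kept, i)
    remaining <- setdiff(remaining, i)
    near <- remaining[effects$chrom[remaining] == effects$chrom[i] &
                        abs(effects$pos[remaining] - effects$pos[i]) <=
                          window_kb * 1000]
    remaining <- setdiff(remaining, near[R2[i, near] > r2_max])
  }
  sort(effects$snp_id[kept])
}

# Dumb profile grid for the random-effects likelihood-ratio statistic.
oracle_re2_grid <- function(y, se, beta_grid, tau2_grid, chunk = 200L) {
  l0 <- sum(dnorm(y, 0, se, log = TRUE))
  best <- -Inf
  for (start in seq(1, length(tau2_grid), by = chunk)) {
    t2 <- tau2_grid[start:min(start + chunk - 1L, length(tau2_grid))]
    ll <- 0
    for (i in seq_along(y)) {
      v <- se[i]^2 + t2
      ll <- ll - outer(rep(1, length(beta_grid)), 0.5 * log(2 * pi * v)) -
        outer((y[i] - beta_grid)^2, 1 / (2 * v))
    }
    best <- max(best, max(ll))
  }
  S <- max(0, 2 * (best - l0))
  list(stat = S,
       p = 0.5 * pchisq(S, 1, lower.tail = FALSE) +
         0.5 * pchisq(S, 2, lower.tail = FALSE))
}

# Random small clumping instance: LD created by copying neighbour columns
# with flips, positions scattered so windows sometimes overlap.
random_clump_instance <- function(seed, n_ind = 200, m = 20) {
  set.seed(seed)
  X <- matrix(rbinom(n_ind * m, 2, runif(1, 0.2, 0.4)), n_ind, m)
  for (j in 2:m) {
    if (runif(1) < 0.4) {  # tie column j to j-1 with a few flips
      X[, j] <- X[, j - 1]
      fl <- sample(n_ind, ceiling(n_ind * 0.1))
      X[fl, j] <- rbinom(length(fl), 2, 0.3)
    }
  }
  pos <- sort(sample.int(600000L, m))
  panel <- make_panel(X, pos)
  effects <- data.frame(snp_id = panel$map$snp_id, chrom = "1", pos = pos,
                        beta = rnorm(m, 0, 0.05), p = runif(m),
                        stringsAsFactors = FALSE)
  list(panel = panel, effects = effects)
}
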