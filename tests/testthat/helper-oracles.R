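# Independent oracles used to cross-check the package's estimators.
# Each is implemented by a different route than the code under test.

# IVW via weighted regression through the origin (lm), SEs recovered from
# the lm machinery rather than the closed-form sums.
oracle_ivw <- function(bx, by, sey) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sey^2)
  s <- summary(fit)
  se_lm <- s$coefficients[1, "Std. Error"]
  sigma <- s$sigma
  beta <- unname(coef(fit)[1])
  se_fixed <- se_lm / sigma
  list(beta = beta, se_fixed = se_fixed,
       se_mre = se_fixed * max(1, sigma))
}

# MR-Egger via explicit weighted normal equations (the package uses lm).
oracle_egger <- function(bx, by, sey) {
  flip <- bx < 0
  bx <- abs(bx)
  by <- ifelse(flip, -by, by)
  w <- 1 / sey^2
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  est <- solve(XtWX, t(X) %*% (w * by))
  resid <- by - X %*% est
  df <- length(bx) - 2
  sigma2 <- sum(w * resid^2) / df
  se_raw <- sqrt(diag(solve(XtWX)) * sigma2)
  scale <- min(sqrt(sigma2), 1)
  se <- if (scale > 0) se_raw / scale else se_raw
  list(intercept = unname(est[1]), slope = unname(est[2]),
       intercept_se = unname(se[1]), slope_se = unname(se[2]))
}

# Greedy clumping by brute-force elimination: for every candidate, mark it
# removed if any stronger retained candidate clumps it; iterate in p order
# using an explicit removed-set representation (different bookkeeping than
# the package's alive-vector sweep).
oracle_clump <- function(cand, ld, config) {
  cand <- cand[order(cand$pval, cand$variant_id), , drop = FALSE]
  window_bp <- config$clump_window_kb * 1000
  retained <- character(0)
  removed <- character(0)
  for (i in seq_len(nrow(cand))) {
    id_i <- cand$variant_id[i]
    if (id_i %in% removed) next
    clumped <- FALSE
    for (id_r in retained) {
      r <- which(cand$variant_id == id_r)
      same_chrom <- cand$chrom[r] == cand$chrom[i]
      near <- abs(cand$pos[r] - cand$pos[i]) <= window_bp
      r2 <- if (id_r %in% ld$ids && id_i %in% ld$ids) ld$r2[id_r, id_i] else 0
      if (same_chrom && near && r2 >= config$clump_r2) { clumped <- TRUE; break }
    }
    if (clumped) removed <- c(removed, id_i) else retained <- c(retained, id_i)
  }
  retained
}

# Random harmonized-style data frame for estimator checks.
random_harmonized <- function(n_snps) {
  bx <- runif(n_snps, 0.05, 0.5) * sample(c(-1, 1), n_snps, replace = TRUE)
  data.frame(variant_id = sprintf("rs%04d", seq_len(n_snps)),
             effect_allele = "A", other_allele = "G",
             beta_exposure = bx,
             se_exposure = runif(n_snps, 0.005, 0.05),
             beta_outcome = rnorm(n_snps, 0, 0.05),
             se_outcome = runif(n_snps, 0.01, 0.1),
             action = "none", stringsAsFactors = FALSE)
}

# Random candidate set with LD blocks for clumping checks.
random_candidates <- function(n = 20) {
  chrom <- as.character(sample(1:3, n, replace = TRUE))
  pos <- sample.int(3e7, n)
  ids <- sprintf("rs%04d", sample.int(9999, n))
  r2 <- matrix(0, n, n)
  # random correlated pairs
  n_pairs <- sample.int(15, 1)
  for (k in seq_len(n_pairs)) {
    ij <- sample.int(n, 2)
    r2[ij[1], ij[2]] <- r2[ij[2], ij[1]] <- runif(1)
  }
  diag(r2) <- 1
  cand <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                     effect_allele = "A", other_allele = "G",
                     eaf = runif(n), beta = rnorm(n), se = runif(n, 0.01, 0.1),
                     pval = 10^runif(n, -12, -8), n = 1e5,
                     stringsAsFactors = FALSE)
  list(cand = cand, ld = ld_matrix(r2, ids))
}

# Valid random summary-statistics data frame (round-trip checks).
random_sumstats_df <- function(n = 10) {
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pick <- sample.int(4, n, replace = TRUE)
  data.frame(variant_id = sprintf("rs%06d", sample.int(1e6, n)),
             chrom = as.character(sample(1:22, n, replace = TRUE)),
             pos = sample.int(1e8, n),
             effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
             eaf = ifelse(runif(n) < 0.2, NA_real_, runif(n)),
             beta = rnorm(n), se = runif(n, 1e-4, 0.5),
             pval = runif(n), n = sample(c(NA, 1e4, 5e5), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Small fast simulation configs used across tests.
fast_cfg <- function(seed, ...) {
  args <- list(n_instruments = 50, n_null_snps = 0, ld_block_size = 1,
               frac_palindromic = 0, frac_duplicated = 0, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

null_cfg <- function(seed) {
  fast_cfg(seed, n_mediator_instruments = 0, beta_EM_true = 0,
           beta_MO_true = 0, beta_direct_true = 0)
}
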