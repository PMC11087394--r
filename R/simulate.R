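## Synthetic GWAS summary statistics with known causal structure.
##
## Structural model: exposure-causal variants carry per-allele effects
## gamma_j on the exposure; the mediator receives beta_EM * gamma_j from
## them plus delta_k from its own directly acting variants; the outcome
## receives (beta_direct + beta_EM * beta_MO) * gamma_j and
## beta_MO * delta_k. Observed effects are the truth plus independent
## normal noise with SE 1/sqrt(2 * n * eaf * (1 - eaf)) — the standard
## per-allele approximation — drawn independently per table (two-sample
## design). Each causal variant heads an LD block; its block-mates are
## non-causal tags whose marginal effect is sqrt(r2) times the causal
## effect.

#' Simulation configuration
#'
#' Defaults emulate a pQTL-scale exposure GWAS feeding UK-Biobank-scale
#' mediator and outcome GWAS, with an exposure -> mediator -> outcome
#' structure whose implied proportion mediated is 0.25.
#'
#' @param n_instruments exposure-causal variants.
#' @param n_null_snps background variants (some become LD tags).
#' @param n_mediator_instruments variants acting directly on the mediator
#'   (instruments for the mediator -> outcome leg).
#' @param instrument_effect_range interval for |per-allele effects| of
#'   causal variants; signs are random.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param beta_EM_true exposure -> mediator structural effect.
#' @param beta_MO_true mediator -> outcome structural effect (log-odds).
#' @param beta_direct_true direct exposure -> outcome effect (log-odds).
#' @param ld_block_size variants per LD block (1 = no LD).
#' @param within_block_r2 squared correlation within a block.
#' @param frac_palindromic fraction of variants given A/T or C/G alleles.
#' @param frac_duplicated fraction of variants duplicated in the outcome
#'   table (removed later at harmonization).
#' @param seed master seed; per-table sub-seeds are derived as
#'   (seed * 16807 + k) mod (2^31 - 1), so each table is independently
#'   reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_instruments = 50, n_null_snps = 200,
                       n_mediator_instruments = n_instruments,
                       instrument_effect_range = c(0.1, 0.3),
                       n_exposure = 10000, n_mediator = 300000,
                       n_outcome = 300000,
                       beta_EM_true = -0.02, beta_MO_true = 1.5,
                       beta_direct_true = -0.09,
                       ld_block_size = 5, within_block_r2 = 0.8,
                       frac_palindromic = 0.05, frac_duplicated = 0.02,
                       seed) {
  stopifnot(n_instruments >= 1, n_null_snps >= 0, n_mediator_instruments >= 0,
            length(instrument_effect_range) == 2,
            instrument_effect_range[1] > 0,
            instrument_effect_range[2] >= instrument_effect_range[1],
            n_exposure >= 100, n_mediator >= 100, n_outcome >= 100,
            ld_block_size >= 1, within_block_r2 >= 0, within_block_r2 <= 1,
            frac_palindromic >= 0, frac_palindromic <= 1,
            frac_duplicated >= 0, frac_duplicated <= 1,
            is.numeric(seed), length(seed) == 1)
  n_var <- n_instruments + n_mediator_instruments + n_null_snps
  if (ld_block_size > n_var)
    stop("infeasible config: ld_block_size exceeds variant count")
  structure(list(n_instruments = n_instruments, n_null_snps = n_null_snps,
                 n_mediator_instruments = n_mediator_instruments,
                 instrument_effect_range = instrument_effect_range,
                 n_exposure = n_exposure, n_mediator = n_mediator,
                 n_outcome = n_outcome, beta_EM_true = beta_EM_true,
                 beta_MO_true = beta_MO_true,
                 beta_direct_true = beta_direct_true,
                 ld_block_size = ld_block_size,
                 within_block_r2 = within_block_r2,
                 frac_palindromic = frac_palindromic,
                 frac_duplicated = frac_duplicated,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Documented seed-splitting rule: sub-seed k of master seed s.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 16807 + k) %% 2147483647)
}

NONPALINDROMIC_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"),
                              c("C", "T"), c("G", "A"), c("G", "T"),
                              c("T", "C"), c("T", "G"))
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

## Shared variant grid (ids, positions, alleles, eaf, LD, true effects);
## deterministic given cfg$seed.
sim_grid <- function(cfg) {
  set.seed(sub_seed(cfg$seed, 0L))
  n_caus <- cfg$n_instruments + cfg$n_mediator_instruments
  n_var <- n_caus + cfg$n_null_snps
  b <- cfg$ld_block_size

  ## blocks: each causal variant heads a block padded with null tags;
  ## leftover nulls form their own blocks.
  block_of <- integer(n_var)
  role <- c(rep("exposure_iv", cfg$n_instruments),
            rep("mediator_iv", cfg$n_mediator_instruments),
            rep("null", cfg$n_null_snps))
  null_pool <- which(role == "null")
  next_null <- 1L
  blk <- 0L
  head_of_block <- integer(0)
  for (i in seq_len(n_caus)) {
    blk <- blk + 1L
    block_of[i] <- blk
    head_of_block[blk] <- i
    n_tags <- min(b - 1L, length(null_pool) - next_null + 1L)
    if (n_tags > 0) {
      tags <- null_pool[next_null:(next_null + n_tags - 1L)]
      block_of[tags] <- blk
      next_null <- next_null + n_tags
    }
  }
  while (next_null <= length(null_pool)) {
    blk <- blk + 1L
    take <- null_pool[next_null:min(next_null + b - 1L, length(null_pool))]
    block_of[take] <- blk
    head_of_block[blk] <- take[1]
    next_null <- next_null + length(take)
  }
  n_blocks <- blk

  chrom <- as.character(((seq_len(n_blocks) - 1L) %% 22L) + 1L)[block_of]
  block_rank <- (seq_len(n_blocks) - 1L) %/% 22L
  pos <- integer(n_var)
  for (k in seq_len(n_blocks)) {
    members <- which(block_of == k)
    pos[members] <- 1000000L + block_rank[k] * 20000000L +
      (seq_along(members) - 1L) * 1000L
  }

  ids <- sprintf("rs%07d", seq_len(n_var))
  eaf <- runif(n_var, 0.05, 0.95)

  pal_n <- as.integer(round(cfg$frac_palindromic * n_var))
  pal_idx <- if (pal_n > 0) sort(sample.int(n_var, pal_n)) else integer(0)
  pick <- sample.int(nrow(NONPALINDROMIC_PAIRS), n_var, replace = TRUE)
  ea <- NONPALINDROMIC_PAIRS[pick, 1]
  oa <- NONPALINDROMIC_PAIRS[pick, 2]
  if (pal_n > 0) {
    pp <- sample.int(nrow(PALINDROMIC_PAIRS), pal_n, replace = TRUE)
    ea[pal_idx] <- PALINDROMIC_PAIRS[pp, 1]
    oa[pal_idx] <- PALINDROMIC_PAIRS[pp, 2]
  }

  rng <- cfg$instrument_effect_range
  raw_gamma <- runif(cfg$n_instruments, rng[1], rng[2]) *
    sample(c(-1, 1), cfg$n_instruments, replace = TRUE)
  raw_delta <- if (cfg$n_mediator_instruments > 0)
    runif(cfg$n_mediator_instruments, rng[1], rng[2]) *
      sample(c(-1, 1), cfg$n_mediator_instruments, replace = TRUE)
  else numeric(0)

  gamma <- numeric(n_var)
  delta <- numeric(n_var)
  gamma[seq_len(cfg$n_instruments)] <- raw_gamma
  if (cfg$n_mediator_instruments > 0)
    delta[cfg$n_instruments + seq_len(cfg$n_mediator_instruments)] <- raw_delta
  ## tags pick up sqrt(r2) of their block head's causal effect
  tag_r <- sqrt(cfg$within_block_r2)
  for (k in seq_len(n_blocks)) {
    members <- which(block_of == k)
    hd <- head_of_block[k]
    tags <- setdiff(members, hd)
    if (length(tags)) {
      gamma[tags] <- tag_r * gamma[hd]
      delta[tags] <- tag_r * delta[hd]
    }
  }

  r2 <- diag(n_var)
  if (b > 1 && cfg$within_block_r2 > 0) {
    for (k in seq_len(n_blocks)) {
      members <- which(block_of == k)
      if (length(members) > 1) {
        r2[members, members] <- cfg$within_block_r2
        r2[cbind(members, members)] <- 1
      }
    }
  }

  list(n_var = n_var, ids = ids, chrom = chrom, pos = pos,
       effect_allele = ea, other_allele = oa, eaf = eaf,
       gamma = gamma, delta = delta,
       palindromic_ids = ids[pal_idx],
       exposure_instrument_ids = ids[seq_len(cfg$n_instruments)],
       mediator_instrument_ids =
         if (cfg$n_mediator_instruments > 0)
           ids[cfg$n_instruments + seq_len(cfg$n_mediator_instruments)]
         else character(0),
       ld = ld_matrix(r2, ids, positions = pos))
}

## One observed table: truth + independent noise at sample size n.
sim_table <- function(grid, truth, n, trait_id, trait_type, table_seed) {
  set.seed(table_seed)
  se <- 1 / sqrt(2 * n * grid$eaf * (1 - grid$eaf))
  beta <- truth + rnorm(grid$n_var, 0, se)
  df <- data.frame(variant_id = grid$ids, chrom = grid$chrom, pos = grid$pos,
                   effect_allele = grid$effect_allele,
                   other_allele = grid$other_allele, eaf = grid$eaf,
                   beta = beta, se = se,
                   ## floor avoids underflow to 0 for very strong signals
                   ## (p must stay in (0,1]); GWAS tools report tiny p the
                   ## same way
                   pval = pmax(2 * pnorm(-abs(beta / se)),
                               .Machine$double.xmin),
                   n = n,
                   stringsAsFactors = FALSE)
  sumstats(df, trait_id = trait_id, trait_type = trait_type,
           sample_label = paste0("sim_", trait_id))
}

#' Simulate an exposure/mediator/outcome triplet with known causal structure
#'
#' Three summary-statistics tables from non-overlapping samples sharing
#' one variant grid, plus the LD matrix and a truth record. Palindromic
#' contamination is variant-level (consistent across tables); duplicated
#' variants are appended to the outcome table (the harmonization stage
#' removes duplicates).
#'
#' @param cfg a [sim_config].
#' @return list(exposure, mediator, outcome, ld, truth). `truth` carries
#'   the structural parameters, per-variant effects, the implied total
#'   effect `beta_direct + beta_EM*beta_MO` and proportion mediated
#'   `beta_EM*beta_MO / total`, and the injected contamination ids.
#' @export
simulate_triplet <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- sim_grid(cfg)
  total <- cfg$beta_direct_true + cfg$beta_EM_true * cfg$beta_MO_true
  truth_exp <- grid$gamma
  truth_med <- cfg$beta_EM_true * grid$gamma + grid$delta
  truth_out <- total * grid$gamma + cfg$beta_MO_true * grid$delta

  exposure <- sim_table(grid, truth_exp, cfg$n_exposure, "exposure",
                        "quantitative", sub_seed(cfg$seed, 1L))
  mediator <- sim_table(grid, truth_med, cfg$n_mediator, "mediator",
                        "quantitative", sub_seed(cfg$seed, 2L))
  outcome <- sim_table(grid, truth_out, cfg$n_outcome, "outcome",
                       "binary", sub_seed(cfg$seed, 3L))

  n_dup <- as.integer(round(cfg$frac_duplicated * grid$n_var))
  dup_ids <- character(0)
  if (n_dup > 0) {
    set.seed(sub_seed(cfg$seed, 4L))
    dup_rows <- sort(sample.int(nrow(outcome$records), n_dup))
    dup_ids <- outcome$records$variant_id[dup_rows]
    outcome$records <- rbind(outcome$records,
                             outcome$records[dup_rows, , drop = FALSE])
    rownames(outcome$records) <- NULL
    outcome$validation$duplicated_ids <- dup_ids
  }

  truth <- list(beta_EM_true = cfg$beta_EM_true,
                beta_MO_true = cfg$beta_MO_true,
                beta_direct_true = cfg$beta_direct_true,
                total_effect = total,
                indirect_effect = cfg$beta_EM_true * cfg$beta_MO_true,
                proportion_mediated =
                  if (total != 0) cfg$beta_EM_true * cfg$beta_MO_true / total
                  else NA_real_,
                gamma = setNames(grid$gamma, grid$ids),
                delta = setNames(grid$delta, grid$ids),
                exposure_instrument_ids = grid$exposure_instrument_ids,
                mediator_instrument_ids = grid$mediator_instrument_ids,
                palindromic_ids = grid$palindromic_ids,
                duplicated_ids = dup_ids,
                config = cfg)
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       ld = grid$ld, truth = truth)
}

#' Simulate a phenotype battery sharing the exposure's variant grid
#'
#' A stated fraction of phenotypes receive a true causal effect from the
#' exposure; the rest are null. Used to exercise the phenome-wide scan.
#'
#' @param cfg a [sim_config] (its exposure grid and sample sizes are
#'   reused; phenotypes are drawn at `n_outcome`).
#' @param n_phenotypes number of phenotype tables.
#' @param frac_truly_associated fraction receiving a true effect; the
#'   count is exactly `round(frac * n_phenotypes)`.
#' @param phenotype_effect causal effect of the exposure on the
#'   associated phenotypes (log-odds per unit exposure).
#' @return list(exposure, ld, phenotypes (named list of [sumstats]),
#'   truth). `truth$associated_ids` names the truly associated
#'   phenotypes.
#' @export
simulate_phenotype_battery <- function(cfg, n_phenotypes,
                                       frac_truly_associated,
                                       phenotype_effect = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), n_phenotypes >= 1,
            frac_truly_associated >= 0, frac_truly_associated <= 1)
  grid <- sim_grid(cfg)
  exposure <- sim_table(grid, grid$gamma, cfg$n_exposure, "exposure",
                        "quantitative", sub_seed(cfg$seed, 1L))
  n_assoc <- as.integer(round(frac_truly_associated * n_phenotypes))
  set.seed(sub_seed(cfg$seed, 5L))
  assoc <- sort(sample.int(n_phenotypes, n_assoc))
  ph_ids <- sprintf("phenotype_%04d", seq_len(n_phenotypes))
  phenotypes <- lapply(seq_len(n_phenotypes), function(p) {
    truth_p <- if (p %in% assoc) phenotype_effect * grid$gamma
               else numeric(grid$n_var)
    sim_table(grid, truth_p, cfg$n_outcome, ph_ids[p], "binary",
              sub_seed(cfg$seed, 100L + p))
  })
  names(phenotypes) <- ph_ids
  list(exposure = exposure, ld = grid$ld, phenotypes = phenotypes,
       truth = list(associated_ids = ph_ids[assoc],
                    phenotype_effect = phenotype_effect,
                    n_phenotypes = n_phenotypes))
}

#' Write a simulated triplet to disk
#'
#' Writes the three summary-statistics tables, the LD matrix (dense + id
#' file) and the truth record (YAML) to a directory.
#'
#' @param sim result of [simulate_triplet()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_triplet <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             mediator = file.path(dir, "mediator.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"),
             ld_ids = file.path(dir, "ld_ids.txt"),
             truth = file.path(dir, "truth.yaml"))
  write_sumstats(sim$exposure, paths["exposure"])
  write_sumstats(sim$mediator, paths["mediator"])
  write_sumstats(sim$outcome, paths["outcome"])
  write.table(sim$ld$r2, paths["ld"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(sim$ld$ids, paths["ld_ids"])
  truth <- sim$truth
  truth$gamma <- as.list(truth$gamma)
  truth$delta <- as.list(truth$delta)
  truth$config <- unclass(truth$config)
  yaml::write_yaml(truth, paths["truth"])
  invisible(paths)
}
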