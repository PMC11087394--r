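COMPLEMENT_SET <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

mk_instr <- function(df, id = "exp") {
  structure(list(exposure_id = id, variants = df,
                 config_used = instrument_config(),
                 provenance = list(candidates = nrow(df), removed_by_clumping = 0)),
            class = "instrument_set")
}

mk_row <- function(id, ea, oa, beta, se = 0.01, pos = 100L) {
  data.frame(variant_id = id, chrom = "1", pos = pos, effect_allele = ea,
             other_allele = oa, eaf = 0.3, beta = beta, se = se,
             pval = 1e-9, n = 1e5, stringsAsFactors = FALSE)
}

mk_out <- function(df, id = "out") sumstats(df, id, trait_type = "binary")

test_that("allele alignment keeps, flips, complements, and drops correctly", {
  exp <- mk_instr(rbind(mk_row("v1", "A", "G", 0.10),
                        mk_row("v2", "A", "G", 0.10, pos = 200L),
                        mk_row("v3", "A", "T", 0.10, pos = 300L),
                        mk_row("v4", "A", "G", 0.10, pos = 400L),
                        mk_row("v5", "A", "G", 0.10, pos = 500L)))
  out <- mk_out(rbind(mk_row("v1", "A", "G", -0.05),   # same -> keep
                      mk_row("v2", "G", "A", -0.05),   # swapped -> flip
                      mk_row("v3", "A", "T", 0.05),    # palindromic -> drop
                      mk_row("v4", "T", "C", 0.05),    # strand complement -> keep
                      mk_row("v5", "A", "C", 0.07)))   # irreconcilable -> drop
  h <- harmonize(exp, out)
  rows <- h$rows
  expect_equal(rows$variant_id, c("v1", "v2", "v4"))
  expect_equal(rows$action, c("none", "outcome_sign_flipped", "none"))
  expect_equal(rows$beta_outcome, c(-0.05, 0.05, 0.05))
  expect_equal(rows$effect_allele, rep("A", 3))
  expect_setequal(h$audit$variant_id[h$audit$reason == "dropped_palindromic"], "v3")
  expect_setequal(h$audit$variant_id[h$audit$reason == "dropped_incompatible"], "v5")
})

test_that("complement-swapped alleles flip the outcome effect", {
  exp <- mk_instr(mk_row("v1", "A", "G", 0.10))
  out <- mk_out(mk_row("v1", "C", "T", -0.05))  # complement of swapped G/A
  h <- harmonize(exp, out)
  expect_equal(h$rows$action, "outcome_sign_flipped")
  expect_equal(h$rows$beta_outcome, 0.05)
})

test_that("C/G palindromes and duplicates are removed; audit records drops", {
  exp <- mk_instr(rbind(mk_row("v1", "C", "G", 0.1),
                        mk_row("v2", "A", "G", 0.1, pos = 200L),
                        mk_row("v3", "A", "C", 0.1, pos = 300L)))
  out_df <- rbind(mk_row("v1", "C", "G", 0.05),
                  mk_row("v2", "A", "G", 0.05),
                  mk_row("v2", "A", "G", 0.06),  # duplicated in outcome
                  mk_row("v3", "A", "C", 0.05))
  h <- harmonize(exp, mk_out(out_df))
  expect_equal(h$rows$variant_id, "v3")
  expect_setequal(h$audit$variant_id[h$audit$reason == "dropped_duplicate"], "v2")
  expect_setequal(h$audit$variant_id[h$audit$reason == "dropped_palindromic"], "v1")
})

test_that("instruments missing from the outcome are audited", {
  exp <- mk_instr(rbind(mk_row("v1", "A", "G", 0.1),
                        mk_row("v9", "A", "G", 0.1, pos = 900L)))
  h <- harmonize(exp, mk_out(mk_row("v1", "A", "G", 0.05)))
  expect_equal(h$rows$variant_id, "v1")
  expect_equal(h$audit$reason[h$audit$variant_id == "v9"], "not_in_outcome")
})

test_that("zero harmonizable instruments signals a typed condition", {
  exp <- mk_instr(mk_row("v1", "A", "T", 0.1))  # palindromic only
  expect_error(harmonize(exp, mk_out(mk_row("v1", "A", "T", 0.05))),
               class = "mrscreen_no_harmonizable")
})

test_that("double flip is an identity on retained effects", {
  set.seed(401)
  df <- random_harmonized(12)
  exp <- mk_instr(data.frame(variant_id = df$variant_id, chrom = "1",
                             pos = seq_len(12) * 1000L,
                             effect_allele = "A", other_allele = "G",
                             eaf = 0.3, beta = df$beta_exposure,
                             se = df$se_exposure, pval = 1e-9, n = 1e5,
                             stringsAsFactors = FALSE))
  out_df <- data.frame(variant_id = df$variant_id, chrom = "1",
                       pos = seq_len(12) * 1000L, effect_allele = "A",
                       other_allele = "G", eaf = 0.3, beta = df$beta_outcome,
                       se = df$se_outcome, pval = 0.5, n = 1e5,
                       stringsAsFactors = FALSE)
  flipped <- out_df
  flipped$effect_allele <- "G"
  flipped$other_allele <- "A"
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h1 <- harmonize(exp, mk_out(out_df))
  h2 <- harmonize(exp, mk_out(flipped))
  keep <- setdiff(names(h1$rows), "action")
  expect_identical(h1$rows[keep], h2$rows[keep])
})

test_that("retained rows never contain palindromic variants (property)", {
  set.seed(402)
  for (i in 1:10) {
    sim <- simulate_triplet(fast_cfg(500 + i, n_null_snps = 50,
                                     frac_palindromic = 0.3,
                                     frac_duplicated = 0.1))
    instr <- select_instruments(sim$exposure, sim$ld)
    h <- harmonize(instr, sim$outcome)
    pal <- with(h$rows, COMPLEMENT_SET(effect_allele) == other_allele)
    expect_false(any(pal))
    expect_false(any(duplicated(h$rows$variant_id)))
  }
})
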