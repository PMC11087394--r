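test_that("Wald ratio arithmetic, sign behavior, and degenerate instruments", {
  w <- wald_ratio(0.1, 0.02, 0.02, 0.01)
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.1)
  expect_equal(w$ci_low, 0.2 - 1.959964 * 0.1)

  expect_equal(wald_ratio(0.1, 0.02, 0, 0.01)$beta, 0)
  expect_equal(wald_ratio(0.1, 0.02, 0, 0.01)$or_, 1.0)

  neg <- wald_ratio(-0.1, 0.02, 0.02, 0.01)
  expect_equal(neg$beta, -0.2)
  expect_equal(neg$se, 0.1)  # SE uses |bx|

  expect_error(wald_ratio(0, 0.02, 0.02, 0.01),
               class = "mrscreen_degenerate_instrument")
})

test_that("IVW matches the hand-computed two-SNP case and reduces to Wald at one SNP", {
  h2 <- data.frame(variant_id = c("a", "b"), beta_exposure = c(0.1, 0.2),
                   se_exposure = 0.01, beta_outcome = c(0.01, 0.04),
                   se_outcome = 0.01)
  fe <- mr_ivw(h2, mode = "fixed")
  expect_equal(fe$beta, 0.18, tolerance = 1e-12)
  expect_equal(fe$se, sqrt(1 / 500), tolerance = 1e-12)

  h1 <- h2[1, , drop = FALSE]
  ivw1 <- mr_ivw(h1)
  wd <- wald_ratio(0.1, 0.01, 0.01, 0.01)
  expect_identical(ivw1$beta, wd$beta)
  expect_identical(ivw1$se, wd$se)
  expect_identical(ivw1$method, "wald_ratio")

  expect_error(mr_ivw(h2[0, ]), class = "mrscreen_no_instruments")
})

test_that("IVW is consensus-invariant: equal Wald ratios give that ratio exactly", {
  set.seed(501)
  bx <- runif(8, 0.05, 0.4)
  h <- data.frame(variant_id = letters[1:8], beta_exposure = bx,
                  se_exposure = 0.01, beta_outcome = 0.37 * bx,
                  se_outcome = runif(8, 0.01, 0.1))
  expect_equal(mr_ivw(h, "fixed")$beta, 0.37, tolerance = 1e-13)
  # multiplicative random effects reduce to fixed exactly under homogeneity
  mre <- mr_ivw(h, "multiplicative_random")
  expect_equal(mre$se, mr_ivw(h, "fixed")$se, tolerance = 1e-12)
})

test_that("IVW agrees with the weighted-regression-through-origin oracle", {
  set.seed(502)
  for (i in 1:30) {
    h <- random_harmonized(sample(2:50, 1))
    orc <- oracle_ivw(h$beta_exposure, h$beta_outcome, h$se_outcome)
    fe <- mr_ivw(h, "fixed")
    mre <- mr_ivw(h, "multiplicative_random")
    expect_equal(fe$beta, orc$beta, tolerance = 1e-10)
    expect_equal(fe$se, orc$se_fixed, tolerance = 1e-10)
    expect_equal(mre$se, orc$se_mre, tolerance = 1e-10)
  }
})

test_that("Cochran's Q: zero under consensus, hand value at two SNPs, scales as 1/se^2", {
  bx <- c(0.1, 0.2, 0.3)
  hom <- data.frame(variant_id = letters[1:3], beta_exposure = bx,
                    se_exposure = 0.01, beta_outcome = 0.5 * bx,
                    se_outcome = 0.02)
  q0 <- cochran_q(hom)
  expect_equal(q0$q_stat, 0, tolerance = 1e-20)
  expect_equal(q0$q_pval, 1)

  h2 <- data.frame(variant_id = c("a", "b"), beta_exposure = c(0.1, 0.2),
                   se_exposure = 0.01, beta_outcome = c(0.01, 0.04),
                   se_outcome = 0.01)
  q <- cochran_q(h2, ivw_beta = 0.18)
  # w = (100, 400); Q = 100*(0.1-0.18)^2 + 400*(0.2-0.18)^2 = 0.8
  expect_equal(q$q_stat, 0.8, tolerance = 1e-12)
  expect_equal(q$q_df, 1)
  expect_equal(q$q_pval, pchisq(0.8, 1, lower.tail = FALSE))

  h2b <- h2
  h2b$se_outcome <- 2 * h2$se_outcome
  expect_equal(cochran_q(h2b)$q_stat, q$q_stat / 4, tolerance = 1e-12)

  expect_null(cochran_q(h2[1, ]))
})

test_that("Egger recovers exact fits and matches the normal-equations oracle", {
  set.seed(503)
  bx <- runif(10, 0.05, 0.5)
  sey <- runif(10, 0.01, 0.1)
  exact <- data.frame(variant_id = letters[1:10], beta_exposure = bx,
                      se_exposure = 0.01, beta_outcome = 0.5 * bx,
                      se_outcome = sey)
  eg <- mr_egger(exact)
  expect_equal(eg$intercept$estimate, 0, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-12)

  offset <- exact
  offset$beta_outcome <- 0.02 + 0.5 * bx
  eg2 <- mr_egger(offset)
  expect_equal(eg2$intercept$estimate, 0.02, tolerance = 1e-12)
  expect_equal(eg2$slope$beta, 0.5, tolerance = 1e-12)

  for (i in 1:10) {
    h <- random_harmonized(sample(3:30, 1))
    got <- mr_egger(h)
    orc <- oracle_egger(h$beta_exposure, h$beta_outcome, h$se_outcome)
    expect_equal(got$intercept$estimate, orc$intercept, tolerance = 1e-10)
    expect_equal(got$slope$beta, orc$slope, tolerance = 1e-10)
    expect_equal(got$intercept$se, orc$intercept_se, tolerance = 1e-10)
    expect_equal(got$slope$se, orc$slope_se, tolerance = 1e-10)
  }

  expect_null(mr_egger(exact[1:2, ]))
})

test_that("leave-one-out: consensus stability, outlier detection, two-SNP reduction", {
  bx <- c(0.1, 0.1, 0.1)
  hom <- data.frame(variant_id = letters[1:3], beta_exposure = bx,
                    se_exposure = 0.01, beta_outcome = 0.05 * bx,
                    se_outcome = 0.02)
  full <- mr_ivw(hom)
  loo <- leave_one_out(hom)
  expect_equal(nrow(loo), 3)
  expect_equal(loo$beta, rep(full$beta, 3), tolerance = 1e-12)

  # one outlier: the fit omitting it moves farthest from the full fit
  out <- hom
  out$beta_outcome[2] <- 0.5
  full2 <- mr_ivw(out)
  loo2 <- leave_one_out(out)
  shifts <- abs(loo2$beta - full2$beta)
  expect_equal(loo2$left_out[which.max(shifts)], "b")

  h2 <- hom[1:2, ]
  h2$beta_outcome <- c(0.004, 0.009)
  loo3 <- leave_one_out(h2)
  expect_equal(loo3$n_snps, c(1L, 1L))
  expect_equal(loo3$beta[loo3$left_out == "a"],
               wald_ratio(0.1, 0.01, 0.009, 0.02)$beta)
  expect_equal(loo3$beta[loo3$left_out == "b"],
               wald_ratio(0.1, 0.01, 0.004, 0.02)$beta)

  expect_equal(nrow(leave_one_out(hom[1, ])), 0)
})

test_that("odds-ratio transform reproduces the published eczema-asthma row", {
  expect_equal(beta_to_or(0, 0.1)$or_, 1.0)
  d <- beta_to_or(log(2), 0)
  expect_equal(d$or_, 2.0)
  expect_equal(d$ci_low, 2.0)
  expect_equal(d$ci_high, 2.0)

  # beta and SE back-solved from the printed OR 1.0861 (1.0488-1.1246)
  row <- beta_to_or(0.0829, 0.0178)
  expect_equal(row$or_, 1.0861, tolerance = 5e-4)
  expect_equal(row$ci_low, 1.0488, tolerance = 5e-4)
  expect_equal(row$ci_high, 1.1246, tolerance = 5e-4)
})

test_that("estimates are invariant to row order and allele re-orientation", {
  set.seed(504)
  h <- random_harmonized(15)
  base_fe <- mr_ivw(h, "fixed")
  base_mre <- mr_ivw(h)
  base_eg <- mr_egger(h)

  perm <- h[sample.int(nrow(h)), , drop = FALSE]
  expect_equal(mr_ivw(perm, "fixed")$beta, base_fe$beta, tolerance = 1e-12)

  flip <- h
  sel <- c(2, 5, 9)
  flip$beta_exposure[sel] <- -flip$beta_exposure[sel]
  flip$beta_outcome[sel] <- -flip$beta_outcome[sel]
  expect_identical(mr_ivw(flip, "fixed")$beta, base_fe$beta)
  expect_identical(mr_ivw(flip, "fixed")$se, base_fe$se)
  expect_identical(mr_ivw(flip)$se, base_mre$se)
  expect_identical(mr_egger(flip)$intercept$estimate, base_eg$intercept$estimate)
})

test_that("IVW estimates fall within 3 analytic SEs of the truth for strong instruments", {
  hits <- logical(400)
  for (i in 1:400) {
    sim <- simulate_triplet(fast_cfg(3000 + i))
    h <- harmonize(select_instruments(sim$exposure, sim$ld), sim$outcome)
    est <- mr_ivw(h)
    hits[i] <- abs(est$beta - sim$truth$total_effect) <= 3 * est$se
  }
  expect_gte(mean(hits), 0.99)
})

test_that("sensitivity report has consistent shape", {
  set.seed(505)
  h <- random_harmonized(6)
  s <- mr_sensitivity(h)
  expect_gte(s$q_stat, 0)
  expect_equal(s$q_df, 5)
  expect_equal(nrow(s$loo), 6)
  s1 <- mr_sensitivity(random_harmonized(1))
  expect_true(is.na(s1$q_stat))
  expect_true(is.na(s1$egger_intercept))
  expect_equal(nrow(s1$loo), 0)
})
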