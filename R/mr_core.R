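## Causal-effect estimation from harmonized summary statistics: Wald
## ratio, inverse-variance-weighted (IVW) meta-analysis of Wald ratios,
## Cochran's Q heterogeneity, the MR-Egger intercept as a probe for
## directional horizontal pleiotropy, and leave-one-out refits.

mr_estimate <- function(beta, se, n_snps, method) {
  ci_low <- beta - Z95 * se
  ci_high <- beta + Z95 * se
  structure(list(beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
                 pval = norm_pval(beta, se),
                 or_ = exp(beta), or_ci_low = exp(ci_low),
                 or_ci_high = exp(ci_high),
                 n_snps = n_snps, method = method),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNPs): beta %.4g (SE %.4g), OR %.4f [%.4f, %.4f], p %.3g\n",
              x$method, x$n_snps, x$beta, x$se, x$or_, x$or_ci_low,
              x$or_ci_high, x$pval))
  invisible(x)
}

## Accept either a harmonized_table or a plain data.frame with the
## harmonized columns (handy for tests and simulation studies).
h_rows <- function(h) {
  if (inherits(h, "harmonized_table")) h$rows else as.data.frame(h)
}

#' Wald-ratio causal estimate from a single variant
#'
#' `beta = by/bx`, first-order `se = sey/|bx|`; 95% Wald CI and two-sided
#' normal p.
#'
#' @param bx,sex variant-exposure effect and its SE.
#' @param by,sey variant-outcome effect and its SE.
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(bx, sex, by, sey) {
  if (bx == 0)
    mr_abort("degenerate instrument: variant-exposure effect is zero",
             "mrscreen_degenerate_instrument")
  mr_estimate(by / bx, sey / abs(bx), 1L, "wald_ratio")
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analysis of per-variant Wald ratios with weights `bx^2/sey^2`:
#' `beta = sum(bx*by/sey^2) / sum(bx^2/sey^2)`, fixed-effect
#' `se = sqrt(1/sum(bx^2/sey^2))`. The default multiplicative
#' random-effects mode inflates the SE by `sqrt(max(1, Q/(J-1)))` —
#' never deflating — and reduces to the fixed-effect result exactly when
#' instruments are homogeneous. With a single instrument the result is
#' the Wald ratio, exactly.
#'
#' @param h a `harmonized_table` or data.frame with columns
#'   beta_exposure, se_exposure, beta_outcome, se_outcome.
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `"ivw_mre"`, `"ivw_fe"`, or
#'   `"wald_ratio"` (single instrument).
#' @export
mr_ivw <- function(h, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  r <- h_rows(h)
  if (nrow(r) == 0)
    mr_abort("no instruments to estimate from", "mrscreen_no_instruments")
  if (any(r$beta_exposure == 0))
    mr_abort("degenerate instrument: variant-exposure effect is zero",
             "mrscreen_degenerate_instrument")
  if (nrow(r) == 1)
    return(wald_ratio(r$beta_exposure, r$se_exposure,
                      r$beta_outcome, r$se_outcome))
  bx <- r$beta_exposure; by <- r$beta_outcome; sey <- r$se_outcome
  w <- bx^2 / sey^2
  beta <- sum(bx * by / sey^2) / sum(w)
  se <- sqrt(1 / sum(w))
  if (mode == "multiplicative_random") {
    q <- cochran_q(r, beta)
    se <- se * sqrt(max(1, q$q_stat / q$q_df))
    mr_estimate(beta, se, nrow(r), "ivw_mre")
  } else {
    mr_estimate(beta, se, nrow(r), "ivw_fe")
  }
}

#' Cochran's Q heterogeneity statistic across Wald ratios
#'
#' `Q = sum(w_j * (by_j/bx_j - ivw_beta)^2)` with `w_j = bx_j^2/sey_j^2`;
#' p from chi-square on J-1 df.
#'
#' @inheritParams mr_ivw
#' @param ivw_beta the (fixed-effect) IVW estimate to measure dispersion
#'   around; computed internally when NULL.
#' @return list(q_stat, q_df, q_pval), or NULL with fewer than 2 SNPs.
#' @export
cochran_q <- function(h, ivw_beta = NULL) {
  r <- h_rows(h)
  if (nrow(r) < 2) return(NULL)
  bx <- r$beta_exposure; by <- r$beta_outcome; sey <- r$se_outcome
  w <- bx^2 / sey^2
  if (is.null(ivw_beta)) ivw_beta <- sum(bx * by / sey^2) / sum(w)
  q <- sum(w * (by / bx - ivw_beta)^2)
  df <- nrow(r) - 1L
  list(q_stat = q, q_df = df, q_pval = pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of variant-outcome on variant-exposure effects
#' with an intercept, weights `1/sey^2`, after orienting each pair so the
#' exposure effect is non-negative. A non-zero intercept indicates
#' directional horizontal pleiotropy. SEs are scaled by `1/min(sigma, 1)`
#' (multiplicative random-effects convention, never deflating below the
#' homogeneous model); p-values from a t-distribution on J-2 df.
#'
#' @inheritParams mr_ivw
#' @return list with `intercept` (list: estimate, se, pval) and `slope`
#'   (an `mr_estimate` with method `"egger"`), or NULL with fewer than
#'   3 SNPs.
#' @export
mr_egger <- function(h) {
  r <- h_rows(h)
  if (nrow(r) < 3) return(NULL)
  flip <- r$beta_exposure < 0
  bx <- abs(r$beta_exposure)
  by <- ifelse(flip, -r$beta_outcome, r$beta_outcome)
  w <- 1 / r$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  s <- summary(fit)
  est <- coef(fit)
  se_raw <- s$coefficients[, "Std. Error"]
  scale <- min(s$sigma, 1)
  se <- if (scale > 0) se_raw / scale else se_raw
  df <- nrow(r) - 2L
  pv <- ifelse(se > 0, 2 * pt(-abs(est / se), df = df), NA_real_)
  slope <- mr_estimate(unname(est[2]), unname(se[2]), nrow(r), "egger")
  slope$pval <- unname(pv[2])
  list(intercept = list(estimate = unname(est[1]), se = unname(se[1]),
                        pval = unname(pv[1])),
       slope = slope)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-fits IVW once per omitted variant. An estimate that changes
#' materially when one variant is dropped flags that variant as
#' influential.
#'
#' @inheritParams mr_ivw
#' @param mode IVW mode passed through to [mr_ivw()].
#' @return data.frame with one row per left-out variant (left_out, beta,
#'   se, ci_low, ci_high, pval, n_snps, method); empty with fewer than
#'   2 SNPs.
#' @export
leave_one_out <- function(h, mode = "multiplicative_random") {
  r <- h_rows(h)
  if (nrow(r) < 2)
    return(data.frame(left_out = character(0), beta = numeric(0),
                      se = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), pval = numeric(0),
                      n_snps = integer(0), method = character(0)))
  fits <- lapply(seq_len(nrow(r)), function(j) {
    est <- mr_ivw(r[-j, , drop = FALSE], mode = mode)
    data.frame(left_out = r$variant_id[j], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               n_snps = est$n_snps, method = est$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, fits)
}

#' Full sensitivity report: heterogeneity, pleiotropy, leave-one-out
#'
#' @inheritParams mr_ivw
#' @return list(q_stat, q_df, q_pval, egger_intercept,
#'   egger_intercept_se, egger_intercept_pval, loo). Q fields are NA with
#'   fewer than 2 SNPs; Egger fields NA with fewer than 3.
#' @export
mr_sensitivity <- function(h) {
  q <- cochran_q(h)
  eg <- mr_egger(h)
  list(q_stat = q$q_stat %||% NA_real_,
       q_df = q$q_df %||% NA_integer_,
       q_pval = q$q_pval %||% NA_real_,
       egger_intercept = eg$intercept$estimate %||% NA_real_,
       egger_intercept_se = eg$intercept$se %||% NA_real_,
       egger_intercept_pval = eg$intercept$pval %||% NA_real_,
       loo = leave_one_out(h))
}

#' Convert a log-odds effect to an odds ratio with 95% CI
#'
#' @param beta effect on the log-odds scale.
#' @param se its standard error (>= 0).
#' @return list(or_, ci_low, ci_high) = exp(beta), exp(beta +- 1.959964*se).
#' @export
beta_to_or <- function(beta, se) {
  stopifnot(se >= 0)
  list(or_ = exp(beta), ci_low = exp(beta - Z95 * se),
       ci_high = exp(beta + Z95 * se))
}
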