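## Two-step MR mediation: the total effect of an exposure on the outcome
## decomposes into an indirect path through a mediator (product of the
## exposure->mediator and mediator->outcome effects) and the direct
## remainder. The delta method gives the SE of the product; the two legs
## come from non-overlapping samples, so no covariance term is included.

#' Indirect effect by the product of coefficients with delta-method SE
#'
#' `indirect = beta_em * beta_mo`; delta-method variance
#' `beta_em^2 * se_mo^2 + beta_mo^2 * se_em^2` (no covariance term under
#' the two-sample design); 95% CI and two-sided normal p from that SE.
#' `direct = beta_eo - indirect` and
#' `proportion_mediated = indirect / beta_eo` (undefined when the total
#' effect is zero). Proportions outside \[0,1\] (inconsistent mediation)
#' are reported verbatim; when the indirect and total effects have
#' opposite signs the result is flagged, with a warning, never clamped.
#'
#' @param beta_em,se_em exposure -> mediator effect and SE.
#' @param beta_mo,se_mo mediator -> outcome effect and SE.
#' @param beta_eo,se_eo total exposure -> outcome effect and SE.
#' @return Object of class `mediation_result`: indirect_beta,
#'   indirect_se, indirect_ci_low/high, indirect_pval, direct_beta,
#'   proportion_mediated (and as percent), flags
#'   (sign_discordant, proportion_undefined).
#' @export
indirect_effect <- function(beta_em, se_em, beta_mo, se_mo,
                            beta_eo, se_eo = NA_real_) {
  stopifnot(se_em > 0, se_mo > 0)
  indirect <- beta_em * beta_mo
  se <- sqrt(beta_em^2 * se_mo^2 + beta_mo^2 * se_em^2)
  direct <- beta_eo - indirect
  undefined <- beta_eo == 0
  prop <- if (undefined) NA_real_ else indirect / beta_eo
  discordant <- !undefined && indirect != 0 && sign(indirect) != sign(beta_eo)
  if (discordant)
    warning("indirect and total effects have opposite signs; ",
            "proportion mediated reported unclamped")
  structure(list(indirect_beta = indirect, indirect_se = se,
                 indirect_ci_low = indirect - Z95 * se,
                 indirect_ci_high = indirect + Z95 * se,
                 indirect_pval = norm_pval(indirect, se),
                 direct_beta = direct,
                 proportion_mediated = prop,
                 proportion_mediated_pct = 100 * prop,
                 flags = list(sign_discordant = discordant,
                              proportion_undefined = undefined)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> indirect %.4g (SE %.4g, p %.3g), direct %.4g, proportion mediated %.2f%%%s\n",
              x$indirect_beta, x$indirect_se, x$indirect_pval, x$direct_beta,
              x$proportion_mediated_pct,
              if (isTRUE(x$flags$sign_discordant)) " [sign-discordant]" else ""))
  invisible(x)
}

#' Two-step MR mediation from summary statistics
#'
#' Runs the three univariable MR legs — exposure -> mediator (exposure
#' instruments), mediator -> outcome (mediator instruments), and total
#' exposure -> outcome (exposure instruments) — via [harmonize()] and
#' [mr_ivw()], then assembles the product-method decomposition.
#'
#' @param exposure_instruments `instrument_set` for the exposure.
#' @param mediator_sumstats [sumstats] for the mediator.
#' @param outcome_sumstats [sumstats] for the outcome.
#' @param mediator_instruments `instrument_set` for the mediator (its own
#'   directly acting variants; the exposure's instruments are invalid for
#'   this leg because they reach the mediator through the exposure).
#' @param mode IVW mode for all three legs.
#' @return list with `result` (a `mediation_result`) and `legs` (the
#'   three component `mr_estimate`s: em, mo, eo) for audit.
#' @export
mediate <- function(exposure_instruments, mediator_sumstats, outcome_sumstats,
                    mediator_instruments,
                    mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  leg <- function(instr, out, name) {
    tryCatch(mr_ivw(harmonize(instr, out), mode = mode),
             mrscreen_no_harmonizable = function(e)
               mr_abort(paste0("mediation leg '", name,
                               "' has no harmonizable instruments"),
                        "mrscreen_mediation_leg_failed"))
  }
  em <- leg(exposure_instruments, mediator_sumstats, "exposure->mediator")
  mo <- leg(mediator_instruments, outcome_sumstats, "mediator->outcome")
  eo <- leg(exposure_instruments, outcome_sumstats, "exposure->outcome")
  res <- indirect_effect(em$beta, em$se, mo$beta, mo$se, eo$beta, eo$se)
  list(result = res, legs = list(em = em, mo = mo, eo = eo))
}

#' Proportion mediated from published odds ratios
#'
#' Replay mode for desk verification: supply the three odds ratios
#' (exposure -> mediator, mediator -> outcome, total exposure -> outcome)
#' as printed, and the proportion mediated is computed from their logs by
#' the product method.
#'
#' @param or_em,or_mo,or_eo odds ratios for the three effects.
#' @return list(indirect_beta, total_beta, proportion_mediated,
#'   proportion_mediated_pct).
#' @export
proportion_from_or <- function(or_em, or_mo, or_eo) {
  indirect <- log(or_em) * log(or_mo)
  total <- log(or_eo)
  prop <- indirect / total
  list(indirect_beta = indirect, total_beta = total,
       proportion_mediated = prop, proportion_mediated_pct = 100 * prop)
}
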