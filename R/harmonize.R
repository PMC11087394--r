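## Allele harmonization: align exposure instruments and outcome summary
## statistics so the effect allele matches, dropping palindromic,
## incompatible and duplicated variants. Palindromic SNPs (A/T or C/G)
## are excluded unconditionally: their strand is ambiguous in summary
## data and no allele-frequency rescue is attempted.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize exposure instruments with an outcome table
#'
#' Inner-joins on variant_id, then per variant: identical allele pairs
#' are kept as-is; swapped pairs (effect/other exchanged) have the
#' outcome beta negated; strand-complement pairs are complemented and
#' then re-checked; palindromic variants are always dropped; allele sets
#' irreconcilable after complementing are dropped as incompatible; any
#' variant_id occurring more than once in either source is dropped as a
#' duplicate. Every drop is recorded in the audit.
#'
#' @param exposure_instruments an `instrument_set`.
#' @param outcome a [sumstats] object.
#' @return Object of class `harmonized_table`: list with `exposure_id`,
#'   `outcome_id`, `rows` (data.frame: variant_id, effect_allele,
#'   other_allele, beta_exposure, se_exposure, beta_outcome, se_outcome,
#'   action), and `audit` (data.frame: variant_id, reason).
#'   Signals a condition of class `mrscreen_no_harmonizable` when no row
#'   survives, so screens can report and continue per exposure.
#' @export
harmonize <- function(exposure_instruments, outcome) {
  stopifnot(inherits(exposure_instruments, "instrument_set"),
            inherits(outcome, "sumstats"))
  exp_df <- exposure_instruments$variants
  out_df <- outcome$records

  dup_ids <- union(exp_df$variant_id[duplicated(exp_df$variant_id)],
                   out_df$variant_id[duplicated(out_df$variant_id)])

  audit <- data.frame(variant_id = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  log_drop <- function(ids, reason) {
    if (length(ids))
      audit <<- rbind(audit, data.frame(variant_id = ids, reason = reason,
                                        stringsAsFactors = FALSE))
  }

  shared <- intersect(exp_df$variant_id, out_df$variant_id)
  log_drop(setdiff(exp_df$variant_id, shared), "not_in_outcome")

  e <- exp_df[match(shared, exp_df$variant_id), , drop = FALSE]
  o <- out_df[match(shared, out_df$variant_id), , drop = FALSE]

  n <- length(shared)
  action <- rep(NA_character_, n)
  beta_out <- o$beta

  is_dup <- shared %in% dup_ids
  pal <- is_palindromic(e$effect_allele, e$other_allele) |
         is_palindromic(o$effect_allele, o$other_allele)

  oe <- o$effect_allele
  oo <- o$other_allele
  same  <- oe == e$effect_allele & oo == e$other_allele
  swap  <- oe == e$other_allele & oo == e$effect_allele
  ce <- unname(COMPLEMENT[oe])
  co <- unname(COMPLEMENT[oo])
  csame <- ce == e$effect_allele & co == e$other_allele
  cswap <- ce == e$other_allele & co == e$effect_allele

  for (i in seq_len(n)) {
    if (is_dup[i]) { action[i] <- "dropped_duplicate"; next }
    if (pal[i])    { action[i] <- "dropped_palindromic"; next }
    if (same[i])   { action[i] <- "none"; next }
    if (swap[i])   { action[i] <- "outcome_sign_flipped"; beta_out[i] <- -beta_out[i]; next }
    if (csame[i])  { action[i] <- "none"; next }
    if (cswap[i])  { action[i] <- "outcome_sign_flipped"; beta_out[i] <- -beta_out[i]; next }
    action[i] <- "dropped_incompatible"
  }

  retained <- action %in% c("none", "outcome_sign_flipped")
  for (why in c("dropped_duplicate", "dropped_palindromic", "dropped_incompatible"))
    log_drop(shared[action == why], why)

  rows <- data.frame(variant_id = shared[retained],
                     effect_allele = e$effect_allele[retained],
                     other_allele = e$other_allele[retained],
                     beta_exposure = e$beta[retained],
                     se_exposure = e$se[retained],
                     beta_outcome = beta_out[retained],
                     se_outcome = o$se[retained],
                     action = action[retained],
                     stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  if (nrow(rows) == 0)
    mr_abort(paste0("no harmonizable instruments for ",
                    exposure_instruments$exposure_id, " vs ", outcome$trait_id),
             "mrscreen_no_harmonizable")
  structure(list(exposure_id = exposure_instruments$exposure_id,
                 outcome_id = outcome$trait_id, rows = rows, audit = audit),
            class = "harmonized_table")
}

#' Write a harmonization drop-report
#'
#' @param h a `harmonized_table`.
#' @param path output path for the tab-delimited (variant_id, reason) audit.
#' @return `path`, invisibly.
#' @export
write_harmonization_audit <- function(h, path) {
  write.table(h$audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.harmonized_table <- function(x, ...) {
  cat(sprintf("<harmonized_table> %s vs %s: %d variants retained, %d dropped\n",
              x$exposure_id, x$outcome_id, nrow(x$rows), nrow(x$audit)))
  invisible(x)
}
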