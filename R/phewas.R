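## Phenome-wide scan: one exposure's instrument set against a battery of
## phenotype summary-statistics tables, with Bonferroni and
## Benjamini-Hochberg adjusted p-values reported side by side (tiers are
## labeled, never silently filtered).

#' Scan an instrument set across many phenotypes
#'
#' For each phenotype table the instruments are harmonized and an IVW
#' estimate computed. Phenotypes with no harmonizable instruments are
#' reported as missing rows (reason recorded), never dropped silently.
#' The Bonferroni divisor is the number of phenotypes actually tested.
#'
#' @param exposure_instruments an `instrument_set`.
#' @param phenotypes named list of [sumstats] objects (names are the
#'   phenotype ids), or unnamed (trait ids are used).
#' @param alpha significance level for the tier labels.
#' @param categories optional character vector of phenotype categories,
#'   parallel to `phenotypes`.
#' @param mode IVW mode.
#' @return data.frame, one row per phenotype, sorted by raw p (missing
#'   rows last): phenotype_id, phenotype_category, n_snps, method, beta,
#'   se, ci_low, ci_high, or_, pval, p_bonferroni, p_bh, significant_at
#'   (none/nominal/bh/bonferroni), reason (NA unless missing).
#' @export
phewas_scan <- function(exposure_instruments, phenotypes, alpha = 0.05,
                        categories = NULL,
                        mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  if (length(phenotypes) == 0) stop("empty phenotype list")
  ids <- names(phenotypes)
  if (is.null(ids))
    ids <- vapply(phenotypes, function(p) p$trait_id, character(1))
  if (is.null(categories)) categories <- rep(NA_character_, length(phenotypes))

  one <- function(i) {
    ph <- phenotypes[[i]]
    fit <- tryCatch({
      est <- mr_ivw(harmonize(exposure_instruments, ph), mode = mode)
      data.frame(phenotype_id = ids[i], phenotype_category = categories[i],
                 n_snps = est$n_snps, method = est$method, beta = est$beta,
                 se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
                 or_ = est$or_, pval = est$pval, reason = NA_character_,
                 stringsAsFactors = FALSE)
    }, mrscreen_no_harmonizable = function(e)
      data.frame(phenotype_id = ids[i], phenotype_category = categories[i],
                 n_snps = 0L, method = NA_character_, beta = NA_real_,
                 se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 or_ = NA_real_, pval = NA_real_,
                 reason = "no harmonizable instruments",
                 stringsAsFactors = FALSE))
    fit
  }
  out <- do.call(rbind, lapply(seq_along(phenotypes), one))

  tested <- !is.na(out$pval)
  m <- sum(tested)
  out$p_bonferroni <- NA_real_
  out$p_bh <- NA_real_
  out$p_bonferroni[tested] <- pmin(1, out$pval[tested] * m)
  out$p_bh[tested] <- p.adjust(out$pval[tested], method = "BH")
  out$significant_at <- "none"
  out$significant_at[tested & out$pval < alpha] <- "nominal"
  out$significant_at[tested & out$p_bh < alpha] <- "bh"
  out$significant_at[tested & out$pval < alpha / m] <- "bonferroni"
  out$significant_at[!tested] <- NA_character_

  out <- out[order(!tested, out$pval), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a phenotype manifest
#'
#' Tab-delimited file with columns phenotype_id, category, path
#' (path to each phenotype's summary-statistics file).
#'
#' @param path manifest file path.
#' @return data.frame with the three columns.
#' @export
read_phenotype_manifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("phenotype_id", "category", "path")
  if (!all(need %in% names(man)))
    stop("phenotype manifest needs columns: ", paste(need, collapse = ", "))
  man
}
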