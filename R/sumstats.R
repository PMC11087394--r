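## GWAS summary-statistics tables: single source of truth for variant
## identity and allele conventions. Positions are 1-based. Alleles are
## single bases A/C/G/T (SNPs only; indels rejected). Missing values are
## encoded as "NA" on disk; only eaf and n may be missing.

SUMSTATS_FIELDS <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pval", "n")
MANDATORY_FIELDS <- setdiff(SUMSTATS_FIELDS, c("eaf", "n"))
VALID_ALLELES <- c("A", "C", "G", "T")

#' Default column-name dialect for summary-statistics files
#'
#' Maps the internal field names to the column headers expected on disk.
#' Rename the values to read files with other headers, e.g.
#' `default_dialect(variant_id = "SNP", pval = "P")`.
#'
#' @param ... named overrides, `internal_field = "file column name"`.
#' @return Named character vector mapping internal field names to headers.
#' @export
default_dialect <- function(...) {
  d <- setNames(SUMSTATS_FIELDS, SUMSTATS_FIELDS)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), SUMSTATS_FIELDS)
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(over)] <- over
  }
  d
}

#' Construct a summary-statistics table from a data frame
#'
#' Validates each row against the per-variant invariants (alleles in
#' A/C/G/T and distinct, se > 0, p in (0,1], eaf missing or in \[0,1\],
#' pos >= 1) and drops violating rows, recording the reason. Alleles are
#' normalized to uppercase. Duplicated variant_id values are *flagged*
#' in the validation report, not dropped: harmonization removes them.
#'
#' @param records data.frame with the columns named in [default_dialect()].
#' @param trait_id identifier of the trait.
#' @param trait_type `"binary"` (betas are log-odds) or `"quantitative"`.
#' @param sample_label label of the contributing GWAS sample, used for
#'   two-sample bookkeeping.
#' @return An object of class `sumstats`: list with `trait_id`,
#'   `trait_type`, `sample_label`, `records` (validated data.frame) and
#'   `validation` (a report of dropped rows by reason and duplicated ids).
#' @export
sumstats <- function(records, trait_id, trait_type = c("quantitative", "binary"),
                     sample_label = trait_id) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTATS_FIELDS, names(records))
  for (mc in missing_cols) {
    if (mc %in% MANDATORY_FIELDS)
      stop("missing mandatory column: ", mc)
    records[[mc]] <- NA_real_
  }
  records <- records[SUMSTATS_FIELDS]
  v <- validate_records(records)
  structure(list(trait_id = trait_id, trait_type = trait_type,
                 sample_label = sample_label, records = v$records,
                 validation = v$report),
            class = "sumstats")
}

## Row-level validation; returns cleaned records plus a report.
validate_records <- function(records) {
  n_input <- nrow(records)
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) records[[col]] <- as.numeric(records[[col]])
  records$n <- as.numeric(records$n)

  reason <- rep(NA_character_, n_input)
  mark <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- mark(is.na(records$variant_id) | records$variant_id == "", "missing_id")
  reason <- mark(!(records$effect_allele %in% VALID_ALLELES) |
                 !(records$other_allele %in% VALID_ALLELES), "invalid_allele")
  reason <- mark(records$effect_allele == records$other_allele, "identical_alleles")
  reason <- mark(is.na(records$pos) | records$pos < 1L, "invalid_pos")
  reason <- mark(is.na(records$beta), "missing_beta")
  reason <- mark(is.na(records$se) | records$se <= 0, "invalid_se")
  reason <- mark(is.na(records$pval) | records$pval <= 0 | records$pval > 1, "invalid_pval")
  reason <- mark(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1), "invalid_eaf")
  reason <- mark(!is.na(records$n) & records$n <= 0, "invalid_n")

  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  dup <- unique(kept$variant_id[duplicated(kept$variant_id)])
  drops <- table(reason[!is.na(reason)])
  list(records = kept,
       report = list(n_input = n_input, n_kept = nrow(kept),
                     n_dropped = n_input - nrow(kept),
                     drops = as.list(drops), duplicated_ids = dup))
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or comma-delimited file with a header (delimiter detected
#' from the header line), maps columns through `dialect`, and validates.
#'
#' @param path file path.
#' @param dialect column-name mapping from [default_dialect()].
#' @inheritParams sumstats
#' @return A [sumstats] object; `$validation` reports dropped rows.
#' @export
read_sumstats <- function(path, dialect = default_dialect(),
                          trait_id = basename(path),
                          trait_type = c("quantitative", "binary"),
                          sample_label = trait_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  ## read everything as character (an allele column of all "T" would
  ## otherwise be sniffed as logical); validation does the conversions
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE,
                    colClasses = "character")
  for (fld in MANDATORY_FIELDS) {
    if (!(dialect[[fld]] %in% names(raw)))
      stop("missing mandatory column: ", dialect[[fld]], " (field ", fld, ")")
  }
  cols <- lapply(SUMSTATS_FIELDS, function(fld) {
    col <- dialect[[fld]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_real_, nrow(raw))
  })
  names(cols) <- SUMSTATS_FIELDS
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  sumstats(df, trait_id = trait_id, trait_type = trait_type,
           sample_label = sample_label)
}

#' Write a summary-statistics table to a tab-delimited file
#'
#' Missing eaf/n are written as "NA". Floating-point columns are written
#' with 17 significant digits so that read/write round-trips are exact.
#'
#' @param table a [sumstats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  df <- table$records
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(variant_id = df$variant_id, chrom = df$chrom,
                    pos = df$pos, effect_allele = df$effect_allele,
                    other_allele = df$other_allele, eaf = fmt(df$eaf),
                    beta = fmt(df$beta), se = fmt(df$se), pval = fmt(df$pval),
                    n = ifelse(is.na(df$n), "NA", sprintf("%.17g", df$n)),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write: ", path)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s (%s, sample %s): %d variants (%d dropped at validation)\n",
              x$trait_id, x$trait_type, x$sample_label,
              nrow(x$records), x$validation$n_dropped))
  invisible(x)
}
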