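## Instrument selection: genome-wide-significant variants pruned by
## greedy LD clumping so retained instruments are approximately
## independent.

#' Instrument-selection configuration
#'
#' Defaults follow the standard pQTL-MR workflow: genome-wide
#' significance p < 5e-8, clumping at r2 < 0.001 within 10,000 kb.
#'
#' @param p_threshold significance cutoff; comparison is strict (<).
#' @param clump_r2 squared-correlation cutoff; pairs at or above it are
#'   clumped.
#' @param clump_window_kb index-to-candidate distance in kilobases within
#'   which clumping applies (same chromosome only).
#' @return Object of class `instrument_config`.
#' @export
instrument_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                              clump_window_kb = 10000) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_window_kb > 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb),
            class = "instrument_config")
}

#' Select genome-wide-significant candidate instruments
#'
#' Returns exactly the records with `pval < p_threshold`, sorted by
#' ascending p-value with lexicographic variant_id as the tie-break (so
#' the downstream greedy clump is invariant to input row order). An
#' empty result is legal and means "this exposure has no instruments";
#' screens skip such exposures.
#'
#' @param sumstats a [sumstats] object.
#' @param config an [instrument_config].
#' @return data.frame of candidate records.
#' @export
select_candidates <- function(sumstats, config = instrument_config()) {
  stopifnot(inherits(sumstats, "sumstats"))
  rec <- sumstats$records
  cand <- rec[rec$pval < config$p_threshold, , drop = FALSE]
  cand <- cand[order(cand$pval, cand$variant_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly takes the remaining candidate with the lowest p-value
#' (ties broken by variant_id) as an index variant and discards every
#' remaining candidate on the same chromosome within the clumping window
#' whose r2 with the index is >= `clump_r2`. Candidates absent from the
#' LD matrix are treated as uncorrelated with everything and a warning
#' lists them.
#'
#' @param candidates data.frame from [select_candidates()].
#' @param ld an [ld_matrix].
#' @param config an [instrument_config].
#' @param exposure_id exposure label carried into the result.
#' @return Object of class `instrument_set`: list with `exposure_id`,
#'   `variants` (retained records), `config_used`, `provenance` (counts).
#' @export
ld_clump <- function(candidates, ld, config = instrument_config(),
                     exposure_id = "exposure") {
  cand <- candidates[order(candidates$pval, candidates$variant_id), , drop = FALSE]
  if (nrow(cand) > 0) {
    absent <- setdiff(cand$variant_id, ld$ids)
    if (length(absent))
      warning(length(absent), " candidate(s) absent from LD matrix, ",
              "assumed uncorrelated: ",
              paste(head(absent, 5), collapse = ", "),
              if (length(absent) > 5) ", ..." else "")
  }
  window_bp <- config$clump_window_kb * 1000
  keep <- logical(nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    j <- which(alive)
    if (!length(j)) break
    same <- cand$chrom[j] == cand$chrom[i] &
            abs(cand$pos[j] - cand$pos[i]) <= window_bp
    if (any(same)) {
      r2 <- ld_r2(ld, cand$variant_id[i], cand$variant_id[j[same]])
      alive[j[same][r2 >= config$clump_r2]] <- FALSE
    }
  }
  retained <- cand[keep, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(exposure_id = exposure_id, variants = retained,
                 config_used = config,
                 provenance = list(candidates = nrow(cand),
                                   removed_by_clumping = nrow(cand) - nrow(retained))),
            class = "instrument_set")
}

#' Select and clump instruments in one step
#'
#' @inheritParams select_candidates
#' @inheritParams ld_clump
#' @return An `instrument_set` (possibly empty).
#' @export
select_instruments <- function(sumstats, ld, config = instrument_config(),
                               exposure_id = sumstats$trait_id) {
  ld_clump(select_candidates(sumstats, config), ld, config, exposure_id)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instruments (%d candidates, %d removed by clumping)\n",
              x$exposure_id, nrow(x$variants), x$provenance$candidates,
              x$provenance$removed_by_clumping))
  invisible(x)
}
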