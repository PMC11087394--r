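## Orchestration of the four analyses: the many-exposure screen against
## one outcome, per-triple mediation, and the phenome-wide scan; each
## returns a results table plus a machine-readable run manifest. Config
## may be an R list or a path to a YAML file with the same structure;
## row-level failures never abort a run, config/schema failures always do.

#' Screen many exposures against one outcome
#'
#' For each exposure: candidate selection, LD clumping, harmonization,
#' IVW with heterogeneity and pleiotropy sensitivity statistics.
#' Exposures with zero genome-wide-significant variants (or none
#' harmonizable) are skipped and counted, never silently dropped. The
#' screen reports raw p-values plus Bonferroni and Benjamini-Hochberg
#' adjusted columns; nothing is filtered.
#'
#' @param exposures named list of [sumstats] objects.
#' @param outcome a [sumstats] object.
#' @param ld an [ld_matrix].
#' @param config an [instrument_config].
#' @param alpha nominal significance level recorded in the manifest.
#' @param mode IVW mode.
#' @return list with `results` (data.frame: exposure, outcome, n_snps,
#'   method, beta, se, or, ci_low, ci_high, pval, p_bonferroni, p_bh,
#'   q_pval, egger_intercept_pval), `skipped` (data.frame: exposure,
#'   reason), `manifest`.
#' @export
screen_exposures <- function(exposures, outcome, ld,
                             config = instrument_config(), alpha = 0.05,
                             mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  stopifnot(length(exposures) >= 1, inherits(outcome, "sumstats"))
  ids <- names(exposures)
  if (is.null(ids)) ids <- vapply(exposures, function(e) e$trait_id, character(1))

  rows <- list(); skipped <- list()
  for (i in seq_along(exposures)) {
    ex <- exposures[[i]]
    instr <- select_instruments(ex, ld, config, exposure_id = ids[i])
    if (nrow(instr$variants) == 0) {
      skipped[[length(skipped) + 1]] <-
        data.frame(exposure = ids[i], reason = "no genome-wide-significant variants",
                   stringsAsFactors = FALSE)
      next
    }
    h <- tryCatch(harmonize(instr, outcome),
                  mrscreen_no_harmonizable = function(e) NULL)
    if (is.null(h)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(exposure = ids[i], reason = "no harmonizable instruments",
                   stringsAsFactors = FALSE)
      next
    }
    est <- mr_ivw(h, mode = mode)
    sens <- mr_sensitivity(h)
    rows[[length(rows) + 1]] <-
      data.frame(exposure = ids[i], outcome = outcome$trait_id,
                 n_snps = est$n_snps, method = est$method, beta = est$beta,
                 se = est$se, or = est$or_, ci_low = est$or_ci_low,
                 ci_high = est$or_ci_high, pval = est$pval,
                 q_pval = sens$q_pval,
                 egger_intercept_pval = sens$egger_intercept_pval,
                 stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows)
    else data.frame(exposure = character(0), outcome = character(0),
                    n_snps = integer(0), method = character(0),
                    beta = numeric(0), se = numeric(0), or = numeric(0),
                    ci_low = numeric(0), ci_high = numeric(0),
                    pval = numeric(0), q_pval = numeric(0),
                    egger_intercept_pval = numeric(0))
  m <- nrow(results)
  results$p_bonferroni <- if (m) pmin(1, results$pval * m) else numeric(0)
  results$p_bh <- if (m) p.adjust(results$pval, method = "BH") else numeric(0)
  results <- results[order(results$pval), , drop = FALSE]
  rownames(results) <- NULL
  skipped_df <- if (length(skipped)) do.call(rbind, skipped)
    else data.frame(exposure = character(0), reason = character(0))
  manifest <- build_manifest(
    config = list(instrument_config = unclass(config), alpha = alpha,
                  ivw_mode = mode),
    counts = list(exposures_attempted = length(exposures),
                  exposures_skipped = nrow(skipped_df),
                  exposures_tested = m,
                  significant_nominal = sum(results$pval < alpha)))
  list(results = results, skipped = skipped_df, manifest = manifest)
}

build_manifest <- function(config, counts, files = character(0), seed = NULL) {
  checks <- if (length(files)) as.list(tools::md5sum(files)) else list()
  list(package = "mrscreen",
       version = as.character(packageVersion("mrscreen")),
       seed = seed, config = config, input_checksums = checks,
       counts = counts)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

require_fields <- function(config, fields, where) {
  missing <- setdiff(fields, names(config))
  if (length(missing))
    stop("config error (", where, "): missing field(s): ",
         paste(missing, collapse = ", "))
}

config_instruments <- function(config) {
  instrument_config(p_threshold = config$p_threshold %||% 5e-8,
                    clump_r2 = config$clump_r2 %||% 0.001,
                    clump_window_kb = config$clump_window_kb %||% 10000)
}

load_config_ld <- function(config) {
  load_ld(config$ld$matrix, ids = config$ld$ids %||% NULL)
}

#' Run the exposure screen from a config
#'
#' Config fields: `exposures` (named list of summary-statistics paths),
#' `outcome` (path), `outcome_type`, `ld` (list: `matrix`, optional
#' `ids`), optional `p_threshold`, `clump_r2`, `clump_window_kb`,
#' `alpha`, `ivw_mode`, `out_dir`. When `out_dir` is set, `screen.tsv`,
#' `skipped.tsv` and `manifest.yaml` are written there.
#'
#' @param config list or path to a YAML file.
#' @return As [screen_exposures()], with file checksums in the manifest.
#' @export
run_screen <- function(config) {
  config <- load_config(config)
  require_fields(config, c("exposures", "outcome", "ld"), "screen")
  if (length(config$exposures) < 1) stop("config error (screen): no exposures")
  exp_paths <- unlist(config$exposures)
  if (is.null(names(exp_paths))) names(exp_paths) <- basename(exp_paths)
  exposures <- lapply(seq_along(exp_paths), function(i)
    read_sumstats(exp_paths[[i]], trait_id = names(exp_paths)[i]))
  names(exposures) <- names(exp_paths)
  outcome <- read_sumstats(config$outcome,
                           trait_id = config$outcome_id %||% basename(config$outcome),
                           trait_type = config$outcome_type %||% "binary")
  ld <- load_config_ld(config)
  out <- screen_exposures(exposures, outcome, ld,
                          config = config_instruments(config),
                          alpha = config$alpha %||% 0.05,
                          mode = config$ivw_mode %||% "multiplicative_random")
  out$manifest$input_checksums <-
    as.list(tools::md5sum(c(unname(exp_paths), config$outcome)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_17g(out$results, file.path(config$out_dir, "screen.tsv"))
    write.table(out$skipped, file.path(config$out_dir, "skipped.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(out$manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  out
}

## Tab-delimited writer with full-precision numerics (deterministic output
## checksums across runs).
write_tsv_17g <- function(df, path) {
  out <- df
  for (col in names(out))
    if (is.double(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.17g", out[[col]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run mediation analyses from a config
#'
#' Config field `triples`: a list; each element either names summary-
#' statistics files (`exposure`, `mediator`, `outcome`, with the shared
#' `ld` block used for instrument selection of both exposure and
#' mediator) or — replay mode — supplies published effect estimates
#' directly (`beta_em`, `se_em`, `beta_mo`, `se_mo`, `beta_eo`, `se_eo`,
#' or odds ratios `or_em`, `or_mo`, `or_eo`), bypassing the MR legs.
#' A failing leg produces a row-level error entry; the run continues.
#'
#' @param config list or path to a YAML file.
#' @return list with `results` (one row per triple: component betas/SEs,
#'   indirect effect with CI, direct effect, proportion mediated and as
#'   percent, flags/error) and `manifest`.
#' @export
run_mediation <- function(config) {
  config <- load_config(config)
  require_fields(config, "triples", "mediation")
  rows <- lapply(seq_along(config$triples), function(i) {
    tri <- config$triples[[i]]
    label <- tri$label %||% paste0("triple_", i)
    tryCatch({
      if (!is.null(tri$or_em)) {
        rep <- proportion_from_or(tri$or_em, tri$or_mo, tri$or_eo)
        data.frame(label = label, beta_em = log(tri$or_em), se_em = NA_real_,
                   beta_mo = log(tri$or_mo), se_mo = NA_real_,
                   beta_eo = rep$total_beta, se_eo = NA_real_,
                   indirect_beta = rep$indirect_beta, indirect_se = NA_real_,
                   indirect_ci_low = NA_real_, indirect_ci_high = NA_real_,
                   direct_beta = rep$total_beta - rep$indirect_beta,
                   proportion_mediated = rep$proportion_mediated,
                   proportion_mediated_pct = rep$proportion_mediated_pct,
                   sign_discordant = sign(rep$indirect_beta) != sign(rep$total_beta),
                   error = NA_character_, stringsAsFactors = FALSE)
      } else if (!is.null(tri$beta_em)) {
        res <- indirect_effect(tri$beta_em, tri$se_em, tri$beta_mo,
                               tri$se_mo, tri$beta_eo,
                               tri$se_eo %||% NA_real_)
        mediation_row(label, tri$beta_em, tri$se_em, tri$beta_mo, tri$se_mo,
                      tri$beta_eo, tri$se_eo %||% NA_real_, res)
      } else {
        require_fields(tri, c("exposure", "mediator", "outcome"),
                       paste0("mediation triple ", label))
        ld <- load_config_ld(if (!is.null(tri$ld)) tri else config)
        icfg <- config_instruments(config)
        exps <- read_sumstats(tri$exposure, trait_id = "exposure")
        meds <- read_sumstats(tri$mediator, trait_id = "mediator")
        outs <- read_sumstats(tri$outcome, trait_id = "outcome",
                              trait_type = config$outcome_type %||% "binary")
        med <- mediate(select_instruments(exps, ld, icfg), meds, outs,
                       select_instruments(meds, ld, icfg))
        mediation_row(label, med$legs$em$beta, med$legs$em$se,
                      med$legs$mo$beta, med$legs$mo$se,
                      med$legs$eo$beta, med$legs$eo$se, med$result)
      }
    }, error = function(e)
      data.frame(label = label, beta_em = NA_real_, se_em = NA_real_,
                 beta_mo = NA_real_, se_mo = NA_real_, beta_eo = NA_real_,
                 se_eo = NA_real_, indirect_beta = NA_real_,
                 indirect_se = NA_real_, indirect_ci_low = NA_real_,
                 indirect_ci_high = NA_real_, direct_beta = NA_real_,
                 proportion_mediated = NA_real_,
                 proportion_mediated_pct = NA_real_,
                 sign_discordant = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
  })
  results <- do.call(rbind, rows)
  manifest <- build_manifest(
    config = list(n_triples = length(config$triples)),
    counts = list(triples_attempted = nrow(results),
                  triples_failed = sum(!is.na(results$error))))
  out <- list(results = results, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_17g(results, file.path(config$out_dir, "mediation.tsv"))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  out
}

mediation_row <- function(label, bem, sem, bmo, smo, beo, seo, res) {
  data.frame(label = label, beta_em = bem, se_em = sem, beta_mo = bmo,
             se_mo = smo, beta_eo = beo, se_eo = seo,
             indirect_beta = res$indirect_beta, indirect_se = res$indirect_se,
             indirect_ci_low = res$indirect_ci_low,
             indirect_ci_high = res$indirect_ci_high,
             direct_beta = res$direct_beta,
             proportion_mediated = res$proportion_mediated,
             proportion_mediated_pct = res$proportion_mediated_pct,
             sign_discordant = res$flags$sign_discordant,
             error = NA_character_, stringsAsFactors = FALSE)
}

#' Run a phenome-wide scan from a config
#'
#' Config fields: `exposure` (path), `ld` (list: `matrix`, optional
#' `ids`), `phenotype_manifest` (path to the tab-delimited manifest with
#' columns phenotype_id, category, path), optional `alpha`, thresholds,
#' `out_dir`. Phenotype files that are missing or unreadable produce
#' row-level error entries; the run continues.
#'
#' @param config list or path to a YAML file.
#' @return list with `results` (as [phewas_scan()], plus rows for
#'   unreadable phenotypes) and `manifest` (tested/missing counts).
#' @export
run_phewas <- function(config) {
  config <- load_config(config)
  require_fields(config, c("exposure", "ld", "phenotype_manifest"), "phewas")
  man <- read_phenotype_manifest(config$phenotype_manifest)
  ld <- load_config_ld(config)
  exposure <- read_sumstats(config$exposure, trait_id = "exposure")
  instr <- select_instruments(exposure, ld, config_instruments(config))

  readable <- file.exists(man$path)
  phenos <- lapply(which(readable), function(i)
    read_sumstats(man$path[i], trait_id = man$phenotype_id[i],
                  trait_type = "binary"))
  names(phenos) <- man$phenotype_id[readable]
  results <- phewas_scan(instr, phenos, alpha = config$alpha %||% 0.05,
                         categories = man$category[readable])
  if (any(!readable)) {
    err <- results[0, , drop = FALSE]
    for (i in which(!readable)) {
      row <- as.list(rep(NA, ncol(results)))
      names(row) <- names(results)
      row$phenotype_id <- man$phenotype_id[i]
      row$phenotype_category <- man$category[i]
      row$n_snps <- 0L
      row$reason <- paste0("file not found: ", man$path[i])
      err <- rbind(err, as.data.frame(row, stringsAsFactors = FALSE))
    }
    results <- rbind(results, err)
    rownames(results) <- NULL
  }
  manifest <- build_manifest(
    config = list(alpha = config$alpha %||% 0.05,
                  n_phenotypes = nrow(man)),
    counts = list(phenotypes_listed = nrow(man),
                  phenotypes_tested = sum(!is.na(results$pval)),
                  phenotypes_missing = sum(is.na(results$pval))))
  out <- list(results = results, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_17g(results, file.path(config$out_dir, "phewas.tsv"))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  out
}

#' Write a simulated study to disk from a config
#'
#' Config fields: `seed` plus any [sim_config()] argument, and `out_dir`.
#'
#' @param config list or path to a YAML file.
#' @return Written file paths, invisibly.
#' @export
run_simulate <- function(config) {
  config <- load_config(config)
  require_fields(config, c("seed", "out_dir"), "simulate")
  args <- config[intersect(names(config), names(formals(sim_config)))]
  cfg <- do.call(sim_config, args)
  sim <- simulate_triplet(cfg)
  write_triplet(sim, config$out_dir)
}
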