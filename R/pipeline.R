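## End-to-end orchestration: simulate -> preprocess -> trend -> DMR ->
## context -> Cox -> enrichment, with a machine-readable run summary.

PKG_VERSION <- function() as.character(utils::packageVersion("methtrend"))

RUN_CONFIG_KEYS <- c(
  "seed", "n_cpgs", "chrom_count", "group_counts", "n_batches",
  "n_dmcs", "n_dmrs", "dmr_size_range", "delta_range", "sign_mix",
  "sigma_noise", "batch_shift", "adjust_batch", "use_cell_covariates",
  "n_markers", "min_cpgs", "max_gap", "site_p_threshold",
  "cox_top_n", "linked_cpg_rank", "cox_log_hr", "baseline_rate",
  "censor_rate", "gmt", "write_matrices")

#' Default pipeline configuration
#'
#' One structured list drives every stage; all randomness flows from the
#' single root `seed`.  Unknown keys are rejected by [run_pipeline()].
#'
#' @param ... overrides for any default.
#' @return named list of class `mt_run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_cpgs = 20000, chrom_count = 4,
    group_counts = c(GS6 = 82, GS7 = 162, GS8plus = 36),
    n_batches = 4,
    n_dmcs = 100, n_dmrs = 10, dmr_size_range = c(7, 12),
    delta_range = c(0.08, 0.15), sign_mix = 0.8,
    sigma_noise = 0.15, batch_shift = 0.2,
    adjust_batch = TRUE, use_cell_covariates = FALSE, n_markers = 100,
    min_cpgs = 7, max_gap = 500, site_p_threshold = 0.05,
    cox_top_n = 20, linked_cpg_rank = 1, cox_log_hr = log(3.66),
    baseline_rate = 0.008, censor_rate = 0.006,
    gmt = NULL, write_matrices = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), RUN_CONFIG_KEYS)
  if (length(unknown) > 0)
    stop_mt("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "mt_run_config")
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file of config overrides.
#' @return an `mt_run_config`.
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown) > 0)
    stop_mt("unknown config key(s) in %s: %s", path,
            paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_mt("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Score DMR calls against spiked truth
#'
#' A spiked block counts as recovered when some called DMR of the same
#' direction covers at least half of its member CpGs; a called DMR sharing
#' no CpG with any spiked block is a false DMR, rated per 100,000 null
#' (unspiked) sites.
#'
#' @param dmrs data.frame from [scan_dmrs()].
#' @param effects the `mt_effects` truth used at generation.
#' @param manifest the generating `mt_manifest`.
#' @return list: `n_blocks`, `n_recovered`, `sensitivity`, `false_dmrs`,
#'   `false_per_100k_null`.
#' @export
dmr_recovery <- function(dmrs, effects, manifest) {
  truth_ids <- unlist(lapply(effects$dmr_blocks, `[[`, "cpg_ids"))
  spiked <- unique(c(effects$dmc$cpg_id, truth_ids))
  n_null <- nrow(manifest) - length(spiked)
  recovered <- vapply(effects$dmr_blocks, function(b) {
    any(vapply(seq_len(nrow(dmrs)), function(k) {
      dmrs$direction[k] == b$sign &&
        length(intersect(dmrs$cpg_ids[[k]], b$cpg_ids)) >= length(b$cpg_ids) / 2
    }, logical(1)))
  }, logical(1))
  false_dmrs <- sum(vapply(seq_len(nrow(dmrs)), function(k) {
    length(intersect(dmrs$cpg_ids[[k]], truth_ids)) == 0
  }, logical(1)))
  list(n_blocks = length(effects$dmr_blocks),
       n_recovered = sum(recovered),
       sensitivity = if (length(recovered) > 0) mean(recovered) else NA_real_,
       false_dmrs = false_dmrs,
       false_per_100k_null = if (n_null > 0) 1e5 * false_dmrs / n_null else NA_real_)
}

#' Run the full synthetic pipeline
#'
#' Simulates a dataset per the config, optionally adjusts batch effects
#' and estimates cell-proportion covariates, runs the per-CpG trend test,
#' tabulates DMCs, scans and annotates DMRs, summarizes methylation by
#' context, fits the BCR Cox models for the top DMCs, optionally runs
#' gene-set enrichment, and writes all outputs plus `summary.json` to
#' `outdir`.  Deterministic given the config seed.
#'
#' @param config an [run_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "mt_run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  meta <- list(package = "methtrend", version = PKG_VERSION(),
               seed = config$seed, config_hash = hash)
  seeds <- config$seed + 0:9   # per-stage substreams

  sim <- run_stage("simulate", {
    manifest <- generate_manifest(config$n_cpgs, config$chrom_count,
                                  seed = seeds[1])
    spec <- cohort_spec(n_samples = sum(config$group_counts),
                        group_counts = config$group_counts,
                        n_batches = config$n_batches, seed = seeds[2])
    cohort <- generate_cohort(spec)
    effects <- spike_effects(manifest, n_dmcs = config$n_dmcs,
                             n_dmrs = config$n_dmrs,
                             dmr_size_range = config$dmr_size_range,
                             delta_range = config$delta_range,
                             sign_mix = config$sign_mix,
                             max_gap = config$max_gap, seed = seeds[3])
    shifts <- NULL
    if (config$n_batches > 1 && config$batch_shift != 0) {
      shifts <- stats::setNames(
        config$batch_shift * (seq_len(config$n_batches) - 1) /
          max(config$n_batches - 1, 1),
        sprintf("B%d", seq_len(config$n_batches)))
    }
    sigs <- NULL
    reference <- NULL
    if (config$use_cell_covariates) {
      reference <- generate_cell_reference(L = config$n_markers, seed = seeds[4])
      rownames(reference) <- manifest$cpg_id[seq_len(config$n_markers)]
      sigs <- logit(clip_beta(reference))
    }
    beta <- generate_beta(manifest, cohort, effects,
                          sigma_noise = config$sigma_noise,
                          batch_shifts = shifts, cell_signatures = sigs,
                          seed = seeds[5])
    linked <- NULL
    if (config$cox_log_hr != 0 && nrow(effects$dmc) >= config$linked_cpg_rank)
      linked <- effects$dmc$cpg_id[config$linked_cpg_rank]
    cohort <- generate_survival(cohort, beta, linked_cpg = linked,
                                log_hr = config$cox_log_hr,
                                baseline_rate = config$baseline_rate,
                                censor_rate = config$censor_rate,
                                seed = seeds[6])
    list(manifest = manifest, cohort = cohort, effects = effects,
         beta = beta, reference = reference, linked = linked)
  })

  adj <- run_stage("preprocess", {
    beta <- sim$beta
    if (config$adjust_batch && config$n_batches > 1)
      beta <- adjust_batch(beta, sim$cohort$batch)
    props <- NULL
    if (config$use_cell_covariates)
      props <- estimate_cell_proportions(beta, sim$reference)
    covs <- if (is.null(props)) NULL else
      build_covariate_matrix(sim$cohort, props)
    list(beta = beta, props = props, covariates = covs)
  })

  trend <- run_stage("trend", {
    res <- trend_test_matrix(adj$beta, sim$cohort$score, adj$covariates)
    list(results = res, tab = tabulate_dmcs(res),
         global = global_trend(adj$beta, sim$cohort))
  })

  dmr <- run_stage("dmr", {
    labels <- classify_sites(trend$results, sim$manifest,
                             scanner_config(config$min_cpgs, config$max_gap,
                                            config$site_p_threshold))
    dmrs <- scan_dmrs(sim$manifest, labels,
                      scanner_config(config$min_cpgs, config$max_gap,
                                     config$site_p_threshold))
    annotate_dmrs(dmrs, sim$manifest, trend$results)
  })

  context <- run_stage("context", {
    rbind(summarize_context(adj$beta, sim$manifest, sim$cohort,
                            "island_relation"),
          summarize_context(adj$beta, sim$manifest, sim$cohort,
                            "gene_region"))
  })

  cox <- run_stage("cox", {
    ord <- order(trend$results$p_trend)
    top <- trend$results$cpg_id[utils::head(ord, config$cox_top_n)]
    bcr_association(adj$beta, top, sim$cohort)
  })

  enrich <- NULL
  if (!is.null(config$gmt)) {
    enrich <- run_stage("enrich", {
      sets <- read_gmt(config$gmt)
      hits <- unique(toupper(unlist(dmr$genes)))
      universe <- unique(toupper(stats::na.omit(sim$manifest$gene_symbol)))
      hits <- intersect(hits, universe)
      enrichment_table(hits, sets, universe)
    })
  }

  recovery <- dmr_recovery(dmr, sim$effects, sim$manifest)
  summary <- list(
    package = "methtrend", version = PKG_VERSION(),
    seed = config$seed, config_hash = hash,
    n_cpgs = nrow(sim$manifest), n_samples = nrow(sim$cohort),
    global_trend = list(group_means = as.list(trend$global$group_means),
                        p_trend = trend$global$p_trend),
    dmc_counts = as.list(trend$tab$counts),
    fraction_increasing = trend$tab$fraction_increasing,
    n_dmrs = nrow(dmr),
    recovery = recovery,
    cox_linked_cpg = sim$linked,
    incomplete = FALSE)

  run_stage("write", {
    write_manifest(sim$manifest, file.path(outdir, "manifest.tsv"), meta)
    write_sample_sheet(sim$cohort, file.path(outdir, "samples.tsv"), meta)
    if (isTRUE(config$write_matrices)) {
      write_matrix(sim$beta, file.path(outdir, "beta.tsv"), meta)
      write_matrix(adj$beta, file.path(outdir, "adj_beta.tsv"), meta)
    }
    truth <- data.frame(cpg_id = names(effect_vector(sim$effects, sim$manifest)),
                        delta = unname(effect_vector(sim$effects, sim$manifest)))
    write_tsv_mt(truth[truth$delta != 0, ], file.path(outdir, "truth_effects.tsv"),
                 meta)
    write_tsv_mt(trend$results, file.path(outdir, "trend.tsv"), meta)
    write_dmr_table(dmr, file.path(outdir, "dmrs.tsv"), meta)
    write_dmr_bed(dmr, file.path(outdir, "dmrs.bed"))
    write_tsv_mt(context, file.path(outdir, "context.tsv"), meta)
    write_tsv_mt(cox, file.path(outdir, "cox.tsv"), meta)
    if (!is.null(enrich))
      write_tsv_mt(enrich, file.path(outdir, "enrich.tsv"), meta)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  })
  invisible(summary)
}
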