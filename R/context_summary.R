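## Mean methylation by CpG context (island relation or gene region),
## overall and per Gleason group.

#' Summarize mean beta by CpG context
#'
#' For each category on the chosen axis, reports the mean beta over all
#' (CpG-in-category, sample) cells — overall and within each Gleason
#' group.  For a complete matrix this equals the mean over samples of the
#' per-sample category means.
#'
#' @param beta CpG x sample beta matrix.
#' @param manifest an `mt_manifest` covering the beta rows.
#' @param cohort optional cohort data.frame; when supplied, per-group
#'   means are included.
#' @param axis "island_relation" or "gene_region".
#' @return data.frame (`category`, `group`, `mean_beta`, `n_cpgs`) with
#'   group "all" for the overall summary.
#' @export
summarize_context <- function(beta, manifest, cohort = NULL,
                              axis = c("island_relation", "gene_region")) {
  axis <- match.arg(axis)
  idx <- match(rownames(beta), manifest$cpg_id)
  if (anyNA(idx)) stop_mt("beta rows missing from manifest")
  cats <- manifest[[axis]][idx]
  levels <- if (axis == "island_relation") ISLAND_RELATIONS else GENE_REGIONS
  groups <- list(all = seq_len(ncol(beta)))
  if (!is.null(cohort)) {
    col_idx <- match(cohort$sample_id, colnames(beta))
    if (anyNA(col_idx)) stop_mt("beta matrix missing cohort sample(s)")
    for (g in GLEASON_GROUPS)
      groups[[g]] <- col_idx[cohort$gleason_group == g]
  }
  out <- list()
  for (gname in names(groups)) {
    cols <- groups[[gname]]
    site_means <- rowMeans(beta[, cols, drop = FALSE])
    for (cat in levels) {
      rows <- cats == cat
      out[[length(out) + 1L]] <- data.frame(
        category = cat, group = gname,
        mean_beta = if (any(rows)) mean(site_means[rows]) else NA_real_,
        n_cpgs = sum(rows), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
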