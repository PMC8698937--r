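## Differentially methylated region (DMR) calling.
##
## A DMR is a maximal run of at least `min_cpgs` consecutive manifest CpGs
## (no intervening assayed site) that all pass the per-site significance
## filter with the same trend direction, with every adjacent pair at most
## `max_gap` bp apart.  "Maximal" means the run cannot be extended on
## either side without breaking one of those conditions.  A brute-force
## window-enumeration oracle shares the definition but not the code path.

#' Scanner configuration
#'
#' @param min_cpgs minimum run length (>= 2; default 7).
#' @param max_gap largest allowed adjacent gap in bp (inclusive;
#'   default 500).
#' @param site_p_threshold per-site trend p-value filter applied before
#'   run-finding (strict inequality; default 0.05).  Without it, sign-only
#'   runs of 7 arise by chance thousands of times over an 860K-site array.
#' @return list of class `mt_scanner_config`.
#' @export
scanner_config <- function(min_cpgs = 7, max_gap = 500,
                           site_p_threshold = 0.05) {
  if (min_cpgs < 2) stop_mt("min_cpgs must be >= 2")
  if (max_gap < 1) stop_mt("max_gap must be >= 1")
  if (site_p_threshold <= 0 || site_p_threshold > 1)
    stop_mt("site_p_threshold must be in (0, 1]")
  structure(list(min_cpgs = as.integer(min_cpgs), max_gap = max_gap,
                 site_p_threshold = site_p_threshold),
            class = "mt_scanner_config")
}

#' Classify sites by trend direction
#'
#' Label = trend direction (+1/-1) where `p_trend < site_p_threshold`,
#' else 0.  Results must cover every manifest CpG.
#'
#' @param results data.frame from [trend_test_matrix()].
#' @param manifest an `mt_manifest`.
#' @param config an [scanner_config()].
#' @return integer vector of labels in manifest order, named by cpg_id.
#' @export
classify_sites <- function(results, manifest, config = scanner_config()) {
  idx <- match(manifest$cpg_id, results$cpg_id)
  if (anyNA(idx))
    stop_mt("missing trend result for manifest CpG(s): %s",
            paste(utils::head(manifest$cpg_id[is.na(idx)], 3), collapse = ", "))
  lab <- ifelse(results$p_trend[idx] < config$site_p_threshold,
                results$direction[idx], 0L)
  stats::setNames(as.integer(lab), manifest$cpg_id)
}

dmr_record <- function(manifest, idx, label) {
  data.frame(chrom = manifest$chrom[idx[1]],
             start = manifest$pos[idx[1]],
             end = manifest$pos[idx[length(idx)]],
             n_cpgs = length(idx),
             direction = as.integer(label),
             cpg_ids = I(list(manifest$cpg_id[idx])),
             stringsAsFactors = FALSE)
}

empty_dmrs <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
              n_cpgs = integer(0), direction = integer(0),
              cpg_ids = I(list()), stringsAsFactors = FALSE)
}

#' Scan for DMRs
#'
#' Single pass over the manifest: runs break at label changes, label 0
#' (non-significant sites break runs, they are not skipped), adjacent gaps
#' `> max_gap`, and chromosome boundaries.  Maximal runs of length >=
#' `min_cpgs` are reported in genomic order; a longer run is one DMR, not
#' several.
#'
#' @param manifest an `mt_manifest`.
#' @param labels integer labels (+1/-1/0) aligned to manifest order.
#' @param config an [scanner_config()].
#' @return data.frame of DMRs (`chrom`, `start`, `end`, `n_cpgs`,
#'   `direction`, list-column `cpg_ids`), possibly empty.
#' @export
scan_dmrs <- function(manifest, labels, config = scanner_config()) {
  n <- nrow(manifest)
  if (length(labels) != n) stop_mt("labels must align with the manifest")
  if (n == 0) return(empty_dmrs())
  ## break before site i when it cannot extend the run ending at i-1
  new_chrom <- c(TRUE, manifest$chrom[-1] != manifest$chrom[-n])
  gap_ok <- c(FALSE, diff(manifest$pos) <= config$max_gap)
  brk <- new_chrom | c(TRUE, labels[-1] != labels[-n]) | !gap_ok
  run_id <- cumsum(brk)
  keep <- labels != 0
  out <- list()
  for (r in unique(run_id[keep])) {
    idx <- which(run_id == r)
    if (labels[idx[1]] == 0 || length(idx) < config$min_cpgs) next
    out[[length(out) + 1L]] <- dmr_record(manifest, idx, labels[idx[1]])
  }
  if (length(out) == 0) return(empty_dmrs())
  res <- do.call(rbind, out)
  res[order(chrom_rank(res$chrom), res$start), , drop = FALSE]
}

#' Brute-force DMR oracle
#'
#' Enumerates every contiguous manifest window, keeps those satisfying all
#' three DMR conditions (length, shared nonzero label, gap bound), and
#' discards windows contained in a larger qualifying window.  Quadratic;
#' refuses instances above 10,000 sites.
#'
#' @inheritParams scan_dmrs
#' @return data.frame in the same layout as [scan_dmrs()].
#' @export
enumerate_dmrs_oracle <- function(manifest, labels, config = scanner_config()) {
  n <- nrow(manifest)
  if (n > 1e4) stop_mt("oracle restricted to <= 10,000 sites (got %d)", n)
  if (length(labels) != n) stop_mt("labels must align with the manifest")
  qualifying <- list()
  for (i in seq_len(n)) {
    if (labels[i] == 0) next
    j <- i
    while (j < n &&
           labels[j + 1] == labels[i] &&
           manifest$chrom[j + 1] == manifest$chrom[j] &&
           manifest$pos[j + 1] - manifest$pos[j] <= config$max_gap) {
      j <- j + 1
    }
    for (jj in seq(i, j)) {
      if (jj - i + 1 >= config$min_cpgs)
        qualifying[[length(qualifying) + 1L]] <- c(i, jj)
    }
  }
  if (length(qualifying) == 0) return(empty_dmrs())
  win <- do.call(rbind, qualifying)
  maximal <- vapply(seq_len(nrow(win)), function(k) {
    contained <- win[, 1] <= win[k, 1] & win[, 2] >= win[k, 2] &
      (win[, 1] < win[k, 1] | win[, 2] > win[k, 2])
    !any(contained)
  }, logical(1))
  win <- win[maximal, , drop = FALSE]
  out <- lapply(seq_len(nrow(win)), function(k) {
    idx <- win[k, 1]:win[k, 2]
    dmr_record(manifest, idx, labels[idx[1]])
  })
  res <- do.call(rbind, out)
  res <- res[!duplicated(paste(res$chrom, res$start, res$end)), , drop = FALSE]
  res[order(chrom_rank(res$chrom), res$start), , drop = FALSE]
}

#' Annotate DMRs with genes, context and trend statistics
#'
#' Genes = union of member CpGs' symbols; island relation and gene region
#' context are summarized by majority vote of members (ties broken by the
#' canonical category order).  When trend results are supplied, each DMR
#' also carries `min_p` and `mean_slope` over members.
#'
#' @param dmrs data.frame from [scan_dmrs()].
#' @param manifest an `mt_manifest` carrying gene symbols.
#' @param results optional data.frame from [trend_test_matrix()].
#' @return `dmrs` with `genes` (list-column), `island_context`,
#'   `region_context`, and optionally `min_p`, `mean_slope`.
#' @export
annotate_dmrs <- function(dmrs, manifest, results = NULL) {
  majority <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    names(tab)[which.max(tab)]
  }
  ann <- lapply(dmrs$cpg_ids, function(ids) {
    idx <- match(ids, manifest$cpg_id)
    syms <- manifest$gene_symbol[idx]
    list(genes = sort(unique(syms[!is.na(syms)])),
         island = majority(manifest$island_relation[idx], ISLAND_RELATIONS),
         region = majority(manifest$gene_region[idx], GENE_REGIONS))
  })
  dmrs$genes <- I(lapply(ann, `[[`, "genes"))
  dmrs$island_context <- vapply(ann, `[[`, character(1), "island")
  dmrs$region_context <- vapply(ann, `[[`, character(1), "region")
  if (!is.null(results)) {
    stat <- lapply(dmrs$cpg_ids, function(ids) {
      idx <- match(ids, results$cpg_id)
      c(min_p = min(results$p_trend[idx]),
        mean_slope = mean(results$slope[idx]))
    })
    dmrs$min_p <- vapply(stat, `[`, numeric(1), "min_p")
    dmrs$mean_slope <- vapply(stat, `[`, numeric(1), "mean_slope")
  }
  dmrs
}

#' Write DMRs as BED6
#'
#' Coordinates convert from 1-based inclusive CpG positions to 0-based
#' half-open BED (`start - 1`, `end`).  Name is the first annotated gene
#' (or "."), score is `-10 log10(min_p)` capped at 1000 (0 when min_p is
#' unavailable), strand ".".
#'
#' @param dmrs annotated DMR data.frame.
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  name <- vapply(seq_len(nrow(dmrs)), function(k) {
    g <- dmrs$genes[[k]] %||% character(0)
    if (length(g) > 0) g[1] else "."
  }, character(1))
  score <- if ("min_p" %in% names(dmrs))
    pmin(round(-10 * log10(pmax(dmrs$min_p, 1e-100))), 1000) else rep(0L, nrow(dmrs))
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1, end = dmrs$end,
                    name = name, score = score,
                    strand = rep(".", nrow(dmrs)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write DMRs as TSV
#'
#' @param dmrs annotated DMR data.frame.
#' @param path output path.
#' @param meta optional named list written as "#" metadata lines.
#' @export
write_dmr_table <- function(dmrs, path, meta = NULL) {
  flat <- dmrs
  flat$cpg_ids <- vapply(dmrs$cpg_ids, paste, character(1), collapse = ",")
  if ("genes" %in% names(flat))
    flat$genes <- vapply(dmrs$genes, function(g)
      if (length(g) > 0) paste(g, collapse = ",") else NA_character_, character(1))
  write_tsv_mt(flat, path, meta)
}
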