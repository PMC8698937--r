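## Readers and writers for the package's on-disk formats, plus the beta
## computation from raw methylated/unmethylated intensities.
##
## All files are tab-delimited UTF-8 with a header row.  Writers may emit
## "#"-prefixed metadata lines before the header; readers skip them.

MANIFEST_COLS <- c("cpg_id", "chrom", "pos", "island_relation",
                   "gene_region", "gene_symbol")

#' Compute beta values from methylated/unmethylated intensities
#'
#' The methylation fraction at a CpG is estimated as
#' \deqn{\beta = M / (M + U + \alpha)}
#' where M and U are the fluorescence intensities of the methylated and
#' unmethylated probe alleles and \eqn{\alpha \ge 0} is a stabilising
#' offset (100 by Illumina convention).  Values fall in \[0, 1\]: 0 means
#' unmethylated, 1 fully methylated.
#'
#' @param M,U nonnegative numeric matrices (CpG x sample) with identical
#'   dimensions and dimnames; row names are CpG ids, column names sample ids.
#' @param offset nonnegative scalar added to the denominator. With
#'   `offset = 0` an all-zero cell (M = U = 0) yields beta 0 by convention.
#' @return numeric matrix of beta values with the dimnames of `M`.
#' @examples
#' M <- matrix(c(900, 50), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
#' U <- matrix(c(100, 50), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
#' compute_beta(M, U, offset = 100)
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (!is.matrix(M) || !is.matrix(U) || !all(dim(M) == dim(U)))
    stop_mt("M and U must be matrices of identical dimensions")
  if (!identical(dimnames(M), dimnames(U)))
    stop_mt("M and U must carry identical dimnames")
  check_matrix_ids(M, "intensity matrix")
  if (length(offset) != 1L || is.na(offset) || offset < 0)
    stop_mt("offset must be a single nonnegative number")
  bad <- which(M < 0 | U < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_mt("negative intensity at CpG '%s', sample '%s'",
            rownames(M)[bad[1, 1]], colnames(M)[bad[1, 2]])
  }
  denom <- M + U + offset
  beta <- ifelse(denom == 0, 0, M / denom)
  dimnames(beta) <- dimnames(M)
  beta
}

validate_manifest <- function(df) {
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing) > 0)
    stop_mt("manifest is missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(df$cpg_id)) {
    dup <- df$cpg_id[duplicated(df$cpg_id)][1]
    stop_mt("duplicate cpg_id in manifest: '%s'", dup)
  }
  if (any(!is.finite(df$pos)) || any(df$pos < 1) || any(df$pos != floor(df$pos)))
    stop_mt("manifest positions must be integers >= 1 (1-based bp)")
  bad_rel <- setdiff(unique(df$island_relation), ISLAND_RELATIONS)
  if (length(bad_rel) > 0)
    stop_mt("unknown island_relation value(s): %s", paste(bad_rel, collapse = ", "))
  bad_reg <- setdiff(unique(df$gene_region), GENE_REGIONS)
  if (length(bad_reg) > 0)
    stop_mt("unknown gene_region value(s): %s", paste(bad_reg, collapse = ", "))
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key))
    stop_mt("duplicate (chrom, pos) pair in manifest: %s",
            key[duplicated(key)][1])
  invisible(df)
}

#' Construct a CpG manifest
#'
#' A manifest is a data.frame of CpG annotations in genomic scan order:
#' sorted by chromosome (1..22, X, Y, then others) and 1-based position.
#'
#' @param df data.frame with columns `cpg_id`, `chrom`, `pos`,
#'   `island_relation` (Island/Shore/Shelf/OpenSea), `gene_region`
#'   (TSS200/TSS1500/Exon1/UTR5/Body/UTR3/IGR), `gene_symbol` (`NA` for
#'   unannotated sites).
#' @return the validated, sorted manifest with class `mt_manifest`.
#' @export
as_manifest <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$pos <- as.numeric(df$pos)
  validate_manifest(df)
  df <- df[order(chrom_rank(df$chrom), df$pos), MANIFEST_COLS, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mt_manifest", "data.frame")
  df
}

n_comment_lines <- function(path) {
  n <- 0L
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    n <- n + 1L
  }
  n
}

read_tsv_mt <- function(path, ...) {
  if (!file.exists(path)) stop_mt("file not found: %s", path)
  skip <- n_comment_lines(path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, skip = skip,
                                  na.strings = "NA", showProgress = FALSE, ...))
}

header_lines <- function(meta) {
  if (is.null(meta)) return(character())
  paste0("# ", names(meta), ": ", unlist(meta))
}

write_tsv_mt <- function(df, path, meta = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  hl <- header_lines(meta)
  if (length(hl) > 0) writeLines(hl, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read / write a CpG manifest TSV
#'
#' The file must carry the columns listed in [as_manifest()]. Sites are
#' sorted into genomic order on read; parse failures report the offending
#' line number (counting "#" metadata lines and the header).
#'
#' @param path file path.
#' @return [read_manifest()]: an `mt_manifest`.
#' @export
read_manifest <- function(path) {
  skip <- n_comment_lines(path)
  df <- read_tsv_mt(path, colClasses = list(character = c(1, 2)))
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing) > 0)
    stop_mt("manifest %s is missing column(s): %s", path,
            paste(missing, collapse = ", "))
  pos_num <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos_num) | pos_num < 1 | pos_num != floor(pos_num))
  if (length(bad) > 0)
    stop_mt("unparseable position at line %d of %s (value '%s')",
            skip + 1L + bad[1], path, as.character(df$pos[bad[1]]))
  df$pos <- pos_num
  bad_rel <- which(!(df$island_relation %in% ISLAND_RELATIONS))
  if (length(bad_rel) > 0)
    stop_mt("unknown island_relation '%s' at line %d of %s",
            df$island_relation[bad_rel[1]], skip + 1L + bad_rel[1], path)
  bad_reg <- which(!(df$gene_region %in% GENE_REGIONS))
  if (length(bad_reg) > 0)
    stop_mt("unknown gene_region '%s' at line %d of %s",
            df$gene_region[bad_reg[1]], skip + 1L + bad_reg[1], path)
  df$gene_symbol <- as.character(df$gene_symbol)
  as_manifest(df)
}

#' @rdname read_manifest
#' @param manifest an `mt_manifest`.
#' @param meta optional named list written as "#" metadata lines.
#' @export
write_manifest <- function(manifest, path, meta = NULL) {
  validate_manifest(manifest)
  write_tsv_mt(as.data.frame(manifest), path, meta)
}

parse_matrix_df <- function(df, path) {
  if (ncol(df) < 2) stop_mt("%s: expected an id column plus sample columns", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop_mt("%s: duplicated row ids", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad_col <- names(df)[-1][which(!vapply(df[-1], is.numeric, logical(1)))[1]]
    stop_mt("%s: non-numeric cell(s) in column '%s'", path, bad_col)
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_mt("%s: missing value at row '%s', column '%s' (missing entries unsupported)",
            path, ids[idx[1]], colnames(m)[idx[2]])
  }
  rownames(m) <- ids
  m
}

#' Read / write CpG-by-sample matrices
#'
#' Rectangular TSV with the sample ids as header and the CpG id as first
#' column.  `read_beta_matrix()` additionally validates that all entries
#' lie in \[0, 1\]; `read_intensity_matrix()` that they are nonnegative.
#'
#' @param path file path.
#' @return numeric matrix with CpG row names and sample column names.
#' @export
read_beta_matrix <- function(path) {
  m <- parse_matrix_df(read_tsv_mt(path), path)
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_mt("%s: beta value %g outside [0,1] at row '%s', column '%s'",
            path, m[bad[1, 1], bad[1, 2]],
            rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  m
}

#' @rdname read_beta_matrix
#' @export
read_intensity_matrix <- function(path) {
  m <- parse_matrix_df(read_tsv_mt(path), path)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_mt("%s: negative intensity at row '%s', column '%s'", path,
            rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  m
}

#' @rdname read_beta_matrix
#' @param mat CpG x sample numeric matrix with dimnames.
#' @param meta optional named list written as "#" metadata lines.
#' @export
write_matrix <- function(mat, path, meta = NULL) {
  check_matrix_ids(mat, "matrix")
  dt <- data.table::data.table(cpg_id = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  con <- file(path, "w", encoding = "UTF-8")
  hl <- header_lines(meta)
  if (length(hl) > 0) writeLines(hl, con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = length(hl) > 0,
                     col.names = TRUE)
  invisible(path)
}

SAMPLE_SHEET_COLS <- c("sample_id", "gleason_group", "score", "age", "smoking",
                       "bmi_class", "stage", "psa_class", "treatment", "batch",
                       "bcr_time", "bcr_event")

#' Read / write the sample sheet
#'
#' One row per sample: `gleason_group` in GS6/GS7/GS8plus with its ordinal
#' `score` 0/1/2, clinical covariates, `batch`, and the biochemical
#' recurrence follow-up (`bcr_time` in months, `bcr_event` 0/1).  Cell
#' proportion columns (prefix `prop_`) are carried through when present.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_mt(path)
  missing <- setdiff(SAMPLE_SHEET_COLS, names(df))
  if (length(missing) > 0)
    stop_mt("sample sheet %s is missing column(s): %s", path,
            paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_mt("sample sheet %s has duplicated sample ids", path)
  bad <- setdiff(unique(df$gleason_group), GLEASON_GROUPS)
  if (length(bad) > 0)
    stop_mt("unknown gleason_group value(s) in %s: %s", path,
            paste(bad, collapse = ", "))
  if (!all(df$score == match(df$gleason_group, GLEASON_GROUPS) - 1L))
    stop_mt("sample sheet %s: score must be the 0-based rank of gleason_group", path)
  df
}

#' @rdname read_sample_sheet
#' @param sheet data.frame of samples.
#' @param meta optional named list written as "#" metadata lines.
#' @export
write_sample_sheet <- function(sheet, path, meta = NULL) {
  write_tsv_mt(sheet, path, meta)
}
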