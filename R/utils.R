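#' @keywords internal
"_PACKAGE"

## Canonical category sets used throughout the package.
ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")
GENE_REGIONS <- c("TSS200", "TSS1500", "Exon1", "UTR5", "Body", "UTR3", "IGR")
GLEASON_GROUPS <- c("GS6", "GS7", "GS8plus")

## Canonical chromosome order: 1..22, X, Y; anything else sorts after,
## alphabetically.
CANONICAL_CHROMS <- c(as.character(1:22), "X", "Y")

chrom_rank <- function(chrom) {
  r <- match(chrom, CANONICAL_CHROMS)
  extra <- sort(unique(chrom[is.na(r)]))
  r[is.na(r)] <- length(CANONICAL_CHROMS) + match(chrom[is.na(r)], extra)
  r
}

## beta values are clipped away from {0,1} before any logit transform;
## 1e-6 keeps logit magnitudes below ~14, far from overflow.
BETA_EPS <- 1e-6

clip_beta <- function(beta, eps = BETA_EPS) {
  pmin(pmax(beta, eps), 1 - eps)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mt <- function(...) stop(sprintf(...), call. = FALSE)

check_matrix_ids <- function(mat, what = "matrix") {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_mt("%s must carry row names (CpG ids) and column names (sample ids)", what)
  if (anyDuplicated(rownames(mat)))
    stop_mt("%s has duplicated row ids", what)
  if (anyDuplicated(colnames(mat)))
    stop_mt("%s has duplicated column ids", what)
  invisible(mat)
}

## Split an integer n into k near-equal parts (largest-remainder).
split_count <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

## Draw counts for categories so that they sum exactly to n while matching
## the target frequencies as closely as possible (largest remainder method).
## Used where downstream summaries must reproduce tabulated percentages.
exact_counts <- function(n, probs) {
  probs <- probs / sum(probs)
  raw <- n * probs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

## Dirichlet draws via normalized gammas.
rdirichlet_mt <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}
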