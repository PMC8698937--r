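## Gene-set over-representation for DMR gene lists.

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and a
#' gene set within a finite universe: with population `|universe|`,
#' `|set (intersect) universe|` successes and `|hits|` draws,
#' `p = P(X >= k)` where `k` is the observed overlap.
#'
#' @param hits character vector of hit genes (must lie in the universe).
#' @param gene_set character vector of set members (intersected with the
#'   universe before testing).
#' @param universe character vector of background genes (nonempty).
#' @return list with `overlap`, `expected`, `p`, and the effective margins
#'   `n_set`, `n_hits`, `n_universe`.
#' @export
hypergeometric_enrichment <- function(hits, gene_set, universe) {
  norm <- function(x) unique(toupper(x))
  universe <- norm(universe)
  if (length(universe) == 0) stop_mt("empty universe")
  hits <- norm(hits)
  if (!all(hits %in% universe))
    stop_mt("hit gene(s) outside the universe: %s",
            paste(utils::head(setdiff(hits, universe), 3), collapse = ", "))
  set_u <- intersect(norm(gene_set), universe)
  k <- length(intersect(hits, set_u))
  N <- length(universe); K <- length(set_u); n <- length(hits)
  p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, expected = n * K / N, p = min(p, 1),
       n_set = K, n_hits = n, n_universe = N)
}

#' Test DMR genes against a collection of gene sets
#'
#' Runs [hypergeometric_enrichment()] for each set and appends
#' Benjamini-Hochberg adjusted p-values (a convenience post-step).
#'
#' @param hits character vector of hit genes.
#' @param gene_sets named list of character vectors ([read_gmt()]).
#' @param universe background gene universe.
#' @return data.frame sorted by p: `set`, `overlap`, `n_set`, `expected`,
#'   `p`, `p_adj`.
#' @export
enrichment_table <- function(hits, gene_sets, universe) {
  rows <- lapply(names(gene_sets), function(nm) {
    r <- hypergeometric_enrichment(hits, gene_sets[[nm]], universe)
    data.frame(set = nm, overlap = r$overlap, n_set = r$n_set,
               expected = r$expected, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members.  Symbols are uppercased on read.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop_mt("malformed GMT line %d in %s (need name, description, members)",
              i, path)
    members <- unique(toupper(parts[-(1:2)]))
    if (length(members) == 0) stop_mt("empty gene set at line %d of %s", i, path)
    sets[[parts[1]]] <- members
  }
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @param descriptions optional character vector matching `gene_sets`.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], desc[i], gene_sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
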