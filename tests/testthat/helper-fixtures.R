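## Shared fixtures and independent oracles.  Everything is built in code;
## no binary fixtures.

## A small hand-written manifest (already in genomic order).
tiny_manifest <- function() {
  as_manifest(data.frame(
    cpg_id = sprintf("cg%02d", 1:10),
    chrom = c(rep("1", 6), rep("2", 4)),
    pos = c(100, 180, 260, 900, 1000, 6000, 500, 620, 740, 5000),
    island_relation = c(rep("Island", 3), "Shore", "Shore", "OpenSea",
                        "Island", "Island", "Shore", "OpenSea"),
    gene_region = c("TSS200", "TSS200", "Exon1", "TSS1500", "UTR5", "Body",
                    "TSS200", "Exon1", "Body", "IGR"),
    gene_symbol = c(rep("GENEA", 5), "GENEB", rep("GENEC", 3), NA),
    stringsAsFactors = FALSE))
}

## Manifest with n equally-labelled sites on one chromosome and chosen gaps.
run_manifest <- function(gaps, chrom = "1") {
  n <- length(gaps) + 1
  as_manifest(data.frame(
    cpg_id = sprintf("cg%03d", seq_len(n)),
    chrom = chrom, pos = 1000 + cumsum(c(0, gaps)),
    island_relation = "Island", gene_region = "TSS200",
    gene_symbol = "G1", stringsAsFactors = FALSE))
}

## Random scanner instance: labels in {-1,0,1} and gaps that straddle the
## 500 bp boundary (499/500/501 included by construction).
random_dmr_instance <- function(n, seed) {
  set.seed(seed)
  n_chrom <- sample(1:3, 1)
  chrom <- sort(sample(as.character(1:n_chrom), n, replace = TRUE))
  gaps <- sample(c(50, 120, 499, 500, 501, 700, 5000), n,
                 replace = TRUE, prob = c(.3, .25, .1, .1, .1, .1, .05))
  pos <- numeric(n)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- 1000 + cumsum(gaps[idx])
  }
  manifest <- as_manifest(data.frame(
    cpg_id = sprintf("cg%05d", seq_len(n)), chrom = chrom, pos = pos,
    island_relation = "OpenSea", gene_region = "IGR",
    gene_symbol = NA_character_, stringsAsFactors = FALSE))
  labels <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(.35, .2, .45))
  list(manifest = manifest, labels = labels)
}

## Permutation p-value oracle for the no-covariate trend slope t-test.
perm_trend_p <- function(y, scores, B = 1000, seed = 1) {
  set.seed(seed)
  tstat <- function(s) {
    r <- suppressWarnings(stats::cor(y, s))
    r * sqrt((length(y) - 2) / (1 - r^2))
  }
  t_obs <- tstat(scores)
  t_perm <- replicate(B, tstat(sample(scores)))
  mean(abs(t_perm) >= abs(t_obs))
}

## Plain-product Cox partial likelihood for a single covariate on
## tie-free data; used as a grid-search oracle.
cox_plik_1cov <- function(b, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}

## Exact QP oracle for min ||r - S w||^2 s.t. w >= 0, sum(w) <= 1, by
## enumerating every active set (small K only).
cls_enum_oracle <- function(S, r) {
  K <- ncol(S)
  best <- NULL
  best_obj <- Inf
  for (zero_mask in 0:(2^K - 1)) {
    zero <- as.logical(bitwAnd(zero_mask, 2^(0:(K - 1))))
    free <- which(!zero)
    for (sum_active in c(FALSE, TRUE)) {
      w <- rep(0, K)
      if (length(free) > 0) {
        Sf <- S[, free, drop = FALSE]
        if (sum_active) {
          nf <- length(free)
          kkt <- rbind(cbind(2 * crossprod(Sf), rep(1, nf)), c(rep(1, nf), 0))
          sol <- tryCatch(solve(kkt, c(2 * crossprod(Sf, r), 1)),
                          error = function(e) NULL)
          if (is.null(sol)) next
          w[free] <- sol[seq_len(nf)]
        } else {
          wf <- tryCatch(qr.solve(Sf, r), error = function(e) NULL)
          if (is.null(wf)) next
          w[free] <- wf
        }
      } else if (sum_active) next
      if (any(w < -1e-9) || sum(w) > 1 + 1e-9) next
      obj <- sum((r - S %*% w)^2)
      if (obj < best_obj - 1e-12) { best_obj <- obj; best <- w }
    }
  }
  best
}

## Small complete cohort with filled-in follow-up, for Cox plumbing tests.
small_cohort_with_bcr <- function(seed = 5, n_cpgs = 60) {
  spec <- cohort_spec(n_samples = 60,
                      group_counts = c(GS6 = 20, GS7 = 25, GS8plus = 15),
                      n_batches = 2, seed = seed)
  cohort <- generate_cohort(spec)
  manifest <- generate_manifest(n_cpgs, chrom_count = 1, seed = seed)
  beta <- generate_beta(manifest, cohort, seed = seed + 1)
  cohort <- generate_survival(cohort, beta, seed = seed + 2)
  list(cohort = cohort, manifest = manifest, beta = beta)
}

clip_beta_for_test <- function(b) pmin(pmax(b, 1e-6), 1 - 1e-6)
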