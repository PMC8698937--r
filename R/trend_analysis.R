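## Per-CpG ordinal trend testing across Gleason-score groups.
##
## The trend test is the least-squares slope of beta on the ordinal group
## score (0, 1, 2 for GS6, GS7, GS>=8), optionally adjusted for covariates,
## with a t test on the slope.  Analysis is on the beta scale.  A
## rank-based Jonckheere-Terpstra variant is available for sensitivity
## analysis on single rows.

DMC_P_LADDER <- c(0.05, 0.01, 1e-3, 1e-4, 1e-5)

trend_group_means <- function(beta_row, scores) {
  vapply(0:2, function(s) {
    if (any(scores == s)) mean(beta_row[scores == s]) else NA_real_
  }, numeric(1))
}

#' Ordinal trend test for one CpG
#'
#' Fits `beta ~ intercept + slope * score (+ covariates)` by least squares
#' and tests the slope with a two-sided t test on residual degrees of
#' freedom.  A constant beta row returns slope 0, p 1 and a degenerate
#' flag.  `method = "jonckheere"` instead computes the Jonckheere-Terpstra
#' rank statistic (normal approximation, no covariate adjustment).
#'
#' @param beta_row numeric vector of beta values.
#' @param scores integer ordinal scores in \{0, 1, 2\}, same length.
#' @param covariates optional numeric matrix (samples x covariates).
#' @param method "linear" (default) or "jonckheere".
#' @return list with `group_means`, `slope`, `se`, `t_stat`, `p_trend`,
#'   `direction` (sign of the slope), `degenerate`.
#' @export
trend_test <- function(beta_row, scores, covariates = NULL,
                       method = c("linear", "jonckheere")) {
  method <- match.arg(method)
  n <- length(beta_row)
  if (length(scores) != n) stop_mt("scores must match beta_row length")
  if (length(unique(scores)) < 2) stop_mt("need >= 2 distinct scores")
  if (method == "jonckheere") return(jonckheere_test(beta_row, scores))
  p_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= p_cov + 2) stop_mt("need n > number of covariates + 2")
  res <- trend_test_matrix(matrix(beta_row, nrow = 1,
                                  dimnames = list("row", names(beta_row))),
                           scores, covariates)
  list(group_means = trend_group_means(beta_row, scores),
       slope = res$slope, se = res$se, t_stat = res$t_stat,
       p_trend = res$p_trend, direction = res$direction,
       degenerate = res$degenerate)
}

#' Ordinal trend tests for every CpG of a beta matrix
#'
#' Vectorized least-squares fit of `beta ~ score (+ covariates)` across all
#' rows sharing one design matrix.
#'
#' @param beta CpG x sample beta matrix.
#' @param scores ordinal scores, one per sample column.
#' @param covariates optional numeric covariate matrix (samples x p).
#' @return data.frame with one row per CpG: `cpg_id`, per-group mean beta
#'   (`mean_GS6`, `mean_GS7`, `mean_GS8plus`), `slope`, `se`, `t_stat`,
#'   `p_trend`, `direction`, `degenerate`.
#' @export
trend_test_matrix <- function(beta, scores, covariates = NULL) {
  n <- ncol(beta)
  if (length(scores) != n) stop_mt("scores must match sample count")
  X <- cbind(intercept = 1, score = scores)
  if (!is.null(covariates)) {
    if (nrow(covariates) != n) stop_mt("covariates must have one row per sample")
    X <- cbind(X, covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop_mt("singular design matrix")
  xtx_inv <- chol2inv(qr.R(qx))
  coefs <- t(beta %*% X %*% xtx_inv)                 # p x N
  fitted <- X %*% coefs                              # n x N
  rss <- colSums((t(beta) - fitted)^2)
  df <- n - ncol(X)
  slope <- coefs[2, ]
  se <- sqrt(pmax(rss, 0) / df * xtx_inv[2, 2])
  t_stat <- slope / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- rss < 1e-20 & abs(slope) < 1e-12
  slope[degenerate] <- 0
  t_stat[degenerate] <- 0
  p[degenerate] <- 1
  p <- pmax(p, .Machine$double.xmin)                 # keep p in (0, 1]
  gm <- matrix(unlist(lapply(0:2, function(s) {
    cols <- scores == s
    if (any(cols)) rowMeans(beta[, cols, drop = FALSE]) else rep(NA_real_, nrow(beta))
  })), nrow = nrow(beta), ncol = 3)
  data.frame(cpg_id = rownames(beta),
             mean_GS6 = gm[, 1], mean_GS7 = gm[, 2], mean_GS8plus = gm[, 3],
             slope = slope, se = se, t_stat = t_stat, p_trend = p,
             direction = ifelse(slope < 0, -1L, 1L),
             degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Jonckheere-Terpstra with normal approximation (two-sided); sensitivity
## alternative to the linear slope test, no covariate adjustment.
jonckheere_test <- function(beta_row, scores) {
  groups <- sort(unique(scores))
  U <- 0
  for (a in seq_along(groups)[-length(groups)]) {
    for (b in (a + 1):length(groups)) {
      xa <- beta_row[scores == groups[a]]
      xb <- beta_row[scores == groups[b]]
      cmp <- outer(xa, xb, function(u, v) (u < v) + 0.5 * (u == v))
      U <- U + sum(cmp)
    }
  }
  ns <- table(factor(scores, levels = groups))
  n <- sum(ns)
  mean_U <- (n^2 - sum(ns^2)) / 4
  var_U <- (n^2 * (2 * n + 3) - sum(ns^2 * (2 * ns + 3))) / 72
  z <- (U - mean_U) / sqrt(var_U)
  p <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  degenerate <- stats::sd(beta_row) == 0
  if (degenerate) { z <- 0; p <- 1 }
  list(group_means = trend_group_means(beta_row, scores),
       slope = NA_real_, se = NA_real_, t_stat = z, p_trend = p,
       direction = if (z < 0) -1L else 1L, degenerate = degenerate)
}

#' Global mean-methylation trend
#'
#' Computes each sample's grand mean beta over all assayed CpGs, then runs
#' the ordinal trend test on those per-sample means (no covariates).
#'
#' @param beta CpG x sample beta matrix.
#' @param cohort cohort data.frame with `sample_id`, `gleason_group`,
#'   `score`.
#' @return list with `group_means` (mean of per-sample means per Gleason
#'   group), `slope`, `p_trend`.
#' @export
global_trend <- function(beta, cohort) {
  idx <- match(cohort$sample_id, colnames(beta))
  if (anyNA(idx)) stop_mt("beta matrix missing cohort sample(s)")
  if (!all(0:2 %in% cohort$score)) stop_mt("empty Gleason group")
  sample_means <- colMeans(beta[, idx, drop = FALSE])
  res <- trend_test(sample_means, cohort$score)
  list(group_means = stats::setNames(res$group_means, GLEASON_GROUPS),
       slope = res$slope, p_trend = res$p_trend)
}

#' Tabulate differentially methylated CpG sites
#'
#' Counts trend-test results below the fixed significance ladder
#' (0.05, 0.01, 1e-3, 1e-4, 1e-5; strict inequality) and the fraction of
#' methylation increases among sites passing the loosest rung.
#'
#' @param results data.frame from [trend_test_matrix()].
#' @return list with `counts` (named integer vector over the ladder) and
#'   `fraction_increasing`.
#' @export
tabulate_dmcs <- function(results) {
  if (nrow(results) == 0) stop_mt("no trend results to tabulate")
  counts <- vapply(DMC_P_LADDER, function(th) sum(results$p_trend < th),
                   numeric(1))
  names(counts) <- paste0("p_lt_", format(DMC_P_LADDER, scientific = FALSE,
                                          trim = TRUE, drop0trailing = TRUE))
  pass <- results$p_trend < DMC_P_LADDER[1]
  frac <- if (any(pass)) mean(results$direction[pass] == 1) else NA_real_
  list(counts = counts, fraction_increasing = frac)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate in (0, 1).
#' @return `alpha / n_tests` (e.g. 0.05 / 850000 = 5.9e-8 at two
#'   significant figures).
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1 || n_tests != floor(n_tests))
    stop_mt("n_tests must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop_mt("alpha must be in (0, 1)")
  alpha / n_tests
}
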