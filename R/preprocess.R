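## Batch-effect adjustment and reference-based cell-type deconvolution.

#' Empirical-Bayes batch adjustment
#'
#' Location/scale batch correction in the ComBat style, performed on
#' logit(beta) so the output stays in \[0, 1\] and batch effects act
#' additively.  Per CpG the data are standardized against the pooled
#' mean/variance; per-batch location and scale estimates are shrunk toward
#' their across-CpG moments under parametric priors (normal for location,
#' inverse-gamma for scale) via the usual fixed-point iteration, the
#' standardized data are adjusted and back-transformed.  Each CpG is
#' finally re-centred to its original logit-scale mean, so the grand mean
#' per CpG is preserved exactly.
#'
#' @param beta CpG x sample beta matrix.
#' @param batch character/factor of batch labels, one per column.
#' @param parametric only `TRUE` (parametric priors) is implemented.
#' @param tol fixed-point convergence tolerance.
#' @return adjusted beta matrix, same dimensions and dimnames.
#' @export
adjust_batch <- function(beta, batch, parametric = TRUE, tol = 1e-6) {
  check_matrix_ids(beta, "beta matrix")
  if (!parametric)
    stop_mt("non-parametric priors are not implemented; use parametric = TRUE")
  if (length(batch) != ncol(beta))
    stop_mt("batch must have one label per sample column")
  batch <- as.character(batch)
  counts <- table(batch)
  if (any(counts < 2))
    stop_mt("each batch needs >= 2 samples (batch '%s' has %d)",
            names(counts)[counts < 2][1], min(counts))
  if (length(counts) < 2) {
    warning("single batch: returning input unchanged")
    return(beta)
  }
  x <- logit(clip_beta(beta))
  n <- ncol(x)
  levels <- names(counts)
  nb <- as.integer(counts[levels])

  ## standardization: remove per-CpG batch means, pool residual variance
  bm <- vapply(levels, function(b) rowMeans(x[, batch == b, drop = FALSE]),
               numeric(nrow(x)))                       # CpG x batch means
  grand <- as.vector(bm %*% (nb / n))
  resid <- x - bm[, match(batch, levels)]
  var_pooled <- rowMeans(resid^2)
  sd_pooled <- sqrt(ifelse(var_pooled > 0, var_pooled, 1))
  z <- (x - grand) / sd_pooled

  row_mean_orig <- rowMeans(x)
  out <- z
  for (bi in seq_along(levels)) {
    cols <- which(batch == levels[bi])
    zb <- z[, cols, drop = FALSE]
    g_hat <- rowMeans(zb)
    d_hat <- apply(zb, 1, stats::var)
    ## hyperpriors: normal moments for location, inverse-gamma
    ## method-of-moments for scale
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    if (!is.finite(t2) || t2 < 1e-12 || !is.finite(s2) || s2 < 1e-12) {
      g_star <- g_hat                 # degenerate prior: no shrinkage
      d_star <- d_hat
    } else {
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      nbk <- length(cols)
      g_star <- g_hat; d_star <- d_hat
      for (it in 1:500) {
        g_new <- (t2 * nbk * g_hat + d_star * g_bar) / (t2 * nbk + d_star)
        sum2 <- rowSums((zb - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (nbk / 2 + a_prior - 1)
        delta <- max(abs(g_new - g_star), abs(d_new - d_star))
        g_star <- g_new; d_star <- d_new
        if (delta < tol) break
      }
    }
    out[, cols] <- (zb - g_star) / sqrt(pmax(d_star, 1e-12))
  }
  adj <- out * sd_pooled + grand
  adj <- adj + (row_mean_orig - rowMeans(adj))   # exact per-CpG re-centring
  res <- inv_logit(adj)
  dimnames(res) <- dimnames(beta)
  res
}

## ---- constrained least squares for deconvolution -------------------------

## Lawson-Hanson nonnegative least squares: min ||b - A w||^2, w >= 0.
nnls_mt <- function(A, b, tol = 1e-10) {
  k <- ncol(A)
  w <- rep(0, k)
  passive <- rep(FALSE, k)
  for (outer in 1:(10 * k + 20)) {
    g <- crossprod(A, b - A %*% w)[, 1]
    cand <- which(!passive & g > tol)
    if (length(cand) == 0) break
    passive[cand[which.max(g[cand])]] <- TRUE
    repeat {
      z <- rep(0, k)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      if (all(z[passive] > tol)) { w <- z; break }
      neg <- passive & z <= tol
      alpha <- min(w[neg] / (w[neg] - z[neg]))
      w <- w + alpha * (z - w)
      passive <- passive & (w > tol)
      w[!passive] <- 0
    }
  }
  w
}

## Active-set solver for min ||b - A w||^2 s.t. w >= 0, sum(w) = 1.
simplex_ls <- function(A, b, tol = 1e-10) {
  k <- ncol(A)
  free <- rep(TRUE, k)
  w <- rep(0, k)
  for (it in 1:(20 * k + 50)) {
    Af <- A[, free, drop = FALSE]
    nf <- ncol(Af)
    kkt <- rbind(cbind(2 * crossprod(Af), rep(1, nf)), c(rep(1, nf), 0))
    rhs <- c(2 * crossprod(Af, b), 1)
    sol <- solve(kkt, rhs)
    wf <- sol[seq_len(nf)]
    mu <- sol[nf + 1]
    if (any(wf < -tol)) {
      drop_j <- which(free)[which.min(wf)]
      if (sum(free) == 1) break                  # cannot empty the free set
      free[drop_j] <- FALSE
      next
    }
    w[] <- 0; w[free] <- pmax(wf, 0)
    grad <- 2 * crossprod(A, A %*% w - b)[, 1]
    viol <- which(!free & (grad + mu < -tol))
    if (length(viol) == 0) return(w)
    free[viol[which.min(grad[viol])]] <- TRUE
  }
  w
}

#' Estimate leukocyte cell-type proportions
#'
#' Reference-based deconvolution in the Houseman style: for each sample,
#' the marker-CpG beta profile r is projected onto the reference signature
#' S by constrained least squares
#' \deqn{\hat w = \arg\min_w \|r - S w\|^2 \quad s.t.\ w \ge 0,\ \sum_k w_k \le 1,}
#' solved exactly by an active-set method.  `1 - sum(w)` is reported as the
#' unexplained residual fraction.
#'
#' @param beta beta matrix containing all marker CpGs (rows) and the
#'   samples to deconvolve (columns).
#' @param reference marker x cell-type matrix of reference beta values
#'   (full column rank, L >= K).
#' @return matrix samples x cell types of proportions, with a `residual`
#'   attribute (vector of 1 - sum(w) per sample).
#' @export
estimate_cell_proportions <- function(beta, reference) {
  if (is.null(rownames(reference)) || is.null(colnames(reference)))
    stop_mt("reference must carry marker row names and cell-type column names")
  if (nrow(reference) < ncol(reference))
    stop_mt("reference needs at least as many markers as cell types")
  if (qr(reference)$rank < ncol(reference))
    stop_mt("reference signature is rank deficient")
  missing <- setdiff(rownames(reference), rownames(beta))
  if (length(missing) > 0)
    stop_mt("marker CpG(s) absent from beta matrix: %s",
            paste(utils::head(missing, 3), collapse = ", "))
  B <- beta[rownames(reference), , drop = FALSE]
  S <- unname(reference)
  props <- t(vapply(seq_len(ncol(B)), function(j) {
    w <- nnls_mt(S, B[, j])
    if (sum(w) > 1 + 1e-9) w <- simplex_ls(S, B[, j])
    w
  }, numeric(ncol(S))))
  dimnames(props) <- list(colnames(B), colnames(reference))
  attr(props, "residual") <- 1 - rowSums(props)
  props
}

#' Assemble the covariate matrix for trend testing
#'
#' Joins estimated cell proportions (dropping the largest-mean type to
#' avoid collinearity with the intercept) with requested clinical
#' covariates from the cohort, encoded numerically (age as-is, categorical
#' covariates as treatment-contrast indicators).  Constant columns are
#' dropped with a warning.
#'
#' @param cohort cohort data.frame with `sample_id`.
#' @param proportions samples x cell-types matrix
#'   ([estimate_cell_proportions()]), or NULL for none.
#' @param covariates clinical columns of `cohort` to include (e.g. "age",
#'   "smoking").
#' @return numeric matrix with one row per cohort sample, in cohort order;
#'   dropped constant columns recorded in attribute `dropped`.
#' @export
build_covariate_matrix <- function(cohort, proportions = NULL,
                                   covariates = character()) {
  blocks <- list()
  if (!is.null(proportions)) {
    idx <- match(cohort$sample_id, rownames(proportions))
    if (anyNA(idx))
      stop_mt("proportions missing sample(s): %s",
              paste(utils::head(cohort$sample_id[is.na(idx)], 3), collapse = ", "))
    p <- proportions[idx, , drop = FALSE]
    drop_k <- which.max(colMeans(p))
    blocks$props <- p[, -drop_k, drop = FALSE]
  }
  for (cv in covariates) {
    if (!cv %in% names(cohort)) stop_mt("cohort has no column '%s'", cv)
    v <- cohort[[cv]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, cv))
    } else {
      f <- factor(v)
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(cv, "_", levels(f)[-1])
    }
    blocks[[cv]] <- m
  }
  if (length(blocks) == 0)
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0,
                  dimnames = list(cohort$sample_id, NULL)))
  x <- do.call(cbind, blocks)
  rownames(x) <- cohort$sample_id
  const <- apply(x, 2, function(col) diff(range(col)) < 1e-12)
  if (any(const)) {
    warning(sprintf("dropping constant covariate column(s): %s",
                    paste(colnames(x)[const], collapse = ", ")))
    dropped <- colnames(x)[const]
    x <- x[, !const, drop = FALSE]
    attr(x, "dropped") <- dropped
  }
  x
}
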