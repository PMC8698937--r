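## Median-dichotomized Cox proportional-hazards association of CpG
## methylation with biochemical recurrence (BCR).
##
## The Cox engine maximizes the Efron-tie-corrected partial likelihood by
## Newton-Raphson with step halving.  Wald inference: CI = exp(coef +/-
## 1.96 se), two-sided p from the normal approximation.

#' Dichotomize a beta row at the sample median
#'
#' High-methylation group = beta strictly greater than the median; ties at
#' the median go to the low (reference) group.  A constant row is all low
#' and flagged degenerate.
#'
#' @param beta_row numeric vector (n >= 2).
#' @return list with `high` (0/1 integer vector), `median`, `degenerate`.
#' @export
dichotomize <- function(beta_row) {
  if (length(beta_row) < 2) stop_mt("need >= 2 samples to dichotomize")
  med <- stats::median(beta_row)
  high <- as.integer(beta_row > med)
  list(high = stats::setNames(high, names(beta_row)), median = med,
       degenerate = all(high == 0L) || all(high == 1L))
}

## Partial likelihood, gradient and Hessian at `coef`.  Efron tie
## correction by default; `ties = "breslow"` keeps the full risk-set sums
## for every tied death (the two coincide exactly on tie-free data).
efron_loglik <- function(coef, times, events, X, ties = "efron") {
  eta <- as.vector(X %*% coef)
  w <- exp(eta)
  ll <- 0
  grad <- rep(0, ncol(X))
  hess <- matrix(0, ncol(X), ncol(X))
  for (tk in unique(times[events == 1])) {
    risk <- which(times >= tk)
    dead <- which(times == tk & events == 1)
    d <- length(dead)
    Xr <- X[risk, , drop = FALSE]
    wr <- w[risk]
    S0r <- sum(wr)
    S1r <- colSums(Xr * wr)
    S2r <- crossprod(Xr, Xr * wr)
    Xd <- X[dead, , drop = FALSE]
    wd <- w[dead]
    S0d <- sum(wd)
    S1d <- colSums(Xd * wd)
    S2d <- crossprod(Xd, Xd * wd)
    ll <- ll + sum(eta[dead])
    grad <- grad + colSums(Xd)
    for (l in seq_len(d) - 1) {
      f <- if (ties == "efron") l / d else 0
      s0 <- S0r - f * S0d
      s1 <- S1r - f * S1d
      s2 <- S2r - f * S2d
      ll <- ll - log(s0)
      grad <- grad - s1 / s0
      hess <- hess - (s2 / s0 - tcrossprod(s1 / s0))
    }
  }
  list(loglik = ll, grad = grad, hess = hess)
}

#' Fit a Cox proportional-hazards model
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators (>= 1 event required).
#' @param X numeric covariate matrix (samples x p), no constant columns.
#' @param max_iter,tol Newton iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param ties "efron" (default) or "breslow" tie handling.
#' @return data.frame with one row per covariate: `term`, `coef`, `se`,
#'   `hr`, `ci_low`, `ci_high`, `p`, plus attributes `loglik`,
#'   `n_events`, `converged`.  The converged flag is FALSE when the
#'   gradient fails to vanish within `max_iter` iterations or the
#'   likelihood is monotone (complete separation).
#' @export
fit_cox <- function(times, events, X, max_iter = 50, tol = 1e-9,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(times)
  if (length(events) != n || nrow(X) != n)
    stop_mt("times, events and X must agree in length")
  if (any(times <= 0)) stop_mt("times must be positive")
  if (sum(events) < 1) stop_mt("need at least one event")
  const <- apply(X, 2, function(col) diff(range(col)) < 1e-12)
  if (any(const))
    stop_mt("constant covariate column(s): %s",
            paste(colnames(X)[const], collapse = ", "))
  if (qr(X)$rank < ncol(X)) stop_mt("singular design matrix")
  coef <- rep(0, ncol(X))
  ev <- efron_loglik(coef, times, events, X, ties)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(ev$hess, ev$grad), error = function(e) NULL)
    if (is.null(step)) break
    new_coef <- coef - step            # Newton ascent: hess is negative definite
    new_ev <- efron_loglik(new_coef, times, events, X, ties)
    halvings <- 0
    while ((!is.finite(new_ev$loglik) || new_ev$loglik < ev$loglik) &&
           halvings < 20) {
      new_coef <- (coef + new_coef) / 2
      new_ev <- efron_loglik(new_coef, times, events, X, ties)
      halvings <- halvings + 1
    }
    rel <- abs(new_ev$loglik - ev$loglik) / (abs(ev$loglik) + 1e-12)
    coef <- new_coef; ev <- new_ev
    if (rel < tol) { converged <- TRUE; break }
  }
  if (any(abs(coef) > 15)) converged <- FALSE   # monotone likelihood guard
  vc <- tryCatch(solve(-ev$hess), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(pmax(diag(vc), 0))
  z <- coef / se
  out <- data.frame(term = colnames(X), coef = coef, se = se,
                    hr = exp(coef),
                    ci_low = exp(coef - 1.96 * se),
                    ci_high = exp(coef + 1.96 * se),
                    p = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "loglik") <- ev$loglik
  attr(out, "n_events") <- sum(events)
  attr(out, "converged") <- converged
  out
}

## Clinical covariate encoding for the BCR models: age continuous; PSA
## class, Gleason group, stage (T3 and T4 collapsed, both sparse) and
## treatment as treatment-contrast indicators.
encode_bcr_covariates <- function(cohort) {
  stage <- ifelse(cohort$stage %in% c("T3", "T4"), "T3T4", cohort$stage)
  blocks <- list(age = matrix(cohort$age, ncol = 1,
                              dimnames = list(NULL, "age")))
  cat_vars <- list(psa = cohort$psa_class, gs = cohort$gleason_group,
                   stage = stage, treat = cohort$treatment)
  for (nm in names(cat_vars)) {
    f <- factor(cat_vars[[nm]])
    if (nlevels(f) < 2) next
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0(nm, "_", levels(f)[-1])
    blocks[[nm]] <- m
  }
  do.call(cbind, blocks)
}

#' Cox association of candidate CpGs with biochemical recurrence
#'
#' For each CpG: dichotomize at the median, assemble the adjusted design
#' (high-methylation indicator plus age, PSA class, Gleason group,
#' clinical stage, treatment), fit the Cox model and collect the
#' high-vs-low hazard ratio.  Per-CpG failures and non-convergence are
#' reported as flags, not errors.
#'
#' @param beta beta matrix containing the candidate CpGs.
#' @param dmc_ids character vector of CpG ids to test.
#' @param cohort cohort data.frame with `bcr_time`, `bcr_event` and the
#'   clinical covariates.
#' @param adjusted include clinical covariates (default TRUE).
#' @return data.frame: `cpg_id`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `n_events`, `converged`, `degenerate`.
#' @export
bcr_association <- function(beta, dmc_ids, cohort, adjusted = TRUE) {
  if (anyNA(cohort$bcr_time) || anyNA(cohort$bcr_event))
    stop_mt("cohort lacks complete bcr_time/bcr_event follow-up")
  missing <- setdiff(dmc_ids, rownames(beta))
  if (length(missing) > 0)
    stop_mt("beta matrix missing CpG(s): %s",
            paste(utils::head(missing, 3), collapse = ", "))
  covs <- if (adjusted) encode_bcr_covariates(cohort) else NULL
  rows <- lapply(dmc_ids, function(cg) {
    d <- dichotomize(beta[cg, cohort$sample_id])
    if (d$degenerate)
      return(data.frame(cpg_id = cg, hr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        n_events = sum(cohort$bcr_event),
                        converged = FALSE, degenerate = TRUE))
    X <- cbind(high_meth = d$high, covs)
    fit <- tryCatch(fit_cox(cohort$bcr_time, cohort$bcr_event, X),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(cpg_id = cg, hr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        n_events = sum(cohort$bcr_event),
                        converged = FALSE, degenerate = FALSE))
    k <- match("high_meth", fit$term)
    data.frame(cpg_id = cg, hr = fit$hr[k], ci_low = fit$ci_low[k],
               ci_high = fit$ci_high[k], p = fit$p[k],
               n_events = attr(fit, "n_events"),
               converged = attr(fit, "converged"), degenerate = FALSE)
  })
  do.call(rbind, rows)
}
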