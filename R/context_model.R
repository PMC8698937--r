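## Baseline methylation model for the synthetic generator.
##
## Each CpG's baseline logit-beta depends on its (island relation, gene
## region) pair.  Defaults are calibrated so that the *marginal* grand mean
## beta per island relation and per gene region reproduces the pattern seen
## on EPIC leukocyte data: islands nearly unmethylated (~0.19), open sea /
## gene bodies high (~0.6), and a monotone rise with distance from the core
## promoter (TSS200 lowest, 3'UTR highest).

## Marginal mean-beta targets.
CONTEXT_REL_TARGETS <- c(Island = 0.189, Shore = 0.420, Shelf = 0.645,
                         OpenSea = 0.625)
CONTEXT_REGION_TARGETS <- c(TSS200 = 0.187, TSS1500 = 0.378, Exon1 = 0.218,
                            UTR5 = 0.417, Body = 0.608, UTR3 = 0.653,
                            IGR = 0.566)

## Fraction of sites per island relation (islands enriched to ~19% as on
## the EPIC chip) and the distribution of gene regions within each.
CONTEXT_REL_PROPS <- c(Island = 0.19, Shore = 0.18, Shelf = 0.07,
                       OpenSea = 0.56)
CONTEXT_REGION_GIVEN_REL <- rbind(
  #          TSS200 TSS1500 Exon1 UTR5 Body UTR3  IGR
  Island  = c(0.30, 0.22, 0.15, 0.08, 0.09, 0.01, 0.15),
  Shore   = c(0.12, 0.20, 0.07, 0.12, 0.24, 0.03, 0.22),
  Shelf   = c(0.01, 0.05, 0.02, 0.10, 0.50, 0.07, 0.25),
  OpenSea = c(0.01, 0.04, 0.02, 0.08, 0.49, 0.06, 0.30))
colnames(CONTEXT_REGION_GIVEN_REL) <- names(CONTEXT_REGION_TARGETS)

#' Calibrate per-context baseline means
#'
#' Solves for a 4 x 7 matrix of logit-scale baselines mu(relation, region)
#' such that the implied marginal mean beta per island relation and per
#' gene region matches the supplied targets, given the joint frequency of
#' (relation, region) pairs.  Uses alternating marginal raking on the
#' logit scale; the two target sets need not be perfectly consistent with
#' the joint weights, in which case the solver converges to a compromise
#' (the final sweep matches the island-relation marginals).
#'
#' @param rel_targets,region_targets named vectors of target mean beta.
#' @param rel_props site frequencies per island relation (sums to 1).
#' @param region_given_rel row-stochastic matrix of gene-region frequencies
#'   within each island relation.
#' @param n_iter raking sweeps.
#' @return list with `mu` (logit baselines, relations x regions), the joint
#'   weight matrix `weights`, and the achieved marginals.
#' @export
calibrate_context_means <- function(rel_targets = CONTEXT_REL_TARGETS,
                                    region_targets = CONTEXT_REGION_TARGETS,
                                    rel_props = CONTEXT_REL_PROPS,
                                    region_given_rel = CONTEXT_REGION_GIVEN_REL,
                                    n_iter = 200) {
  stopifnot(abs(sum(rel_props) - 1) < 1e-8,
            all(abs(rowSums(region_given_rel) - 1) < 1e-8))
  w <- rel_props * region_given_rel        # joint weights, rows = relations
  mu <- outer(logit(rel_targets), logit(region_targets), function(a, b) (a + b) / 2)
  for (it in seq_len(n_iter)) {
    for (r in seq_along(rel_targets)) {    # match relation marginals
      m <- sum(region_given_rel[r, ] * inv_logit(mu[r, ]))
      mu[r, ] <- mu[r, ] + logit(rel_targets[r]) - logit(m)
    }
    if (it == n_iter) break                # end on a relation sweep
    for (g in seq_along(region_targets)) { # match region marginals
      wg <- w[, g] / sum(w[, g])
      m <- sum(wg * inv_logit(mu[, g]))
      mu[, g] <- mu[, g] + logit(region_targets[g]) - logit(m)
    }
  }
  achieved_rel <- rowSums(region_given_rel * inv_logit(mu))
  achieved_region <- colSums(w * inv_logit(mu)) / colSums(w)
  list(mu = mu, weights = w,
       achieved_rel = achieved_rel, achieved_region = achieved_region)
}

## Memoised default calibration (deterministic, so computed once per session).
.context_cache <- new.env(parent = emptyenv())

default_context_model <- function() {
  if (is.null(.context_cache$model))
    .context_cache$model <- calibrate_context_means()
  .context_cache$model
}

## Baseline logit for each manifest site under the default (or supplied)
## calibration.
context_baseline <- function(manifest, model = default_context_model()) {
  model$mu[cbind(match(manifest$island_relation, rownames(model$mu)),
                 match(manifest$gene_region, colnames(model$mu)))]
}
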