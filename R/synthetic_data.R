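## Synthetic EPIC-like data generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## a manifest with clustered CpG islands, a cohort with three ordered
## Gleason-score groups, spiked per-CpG trend effects and clustered DMR
## blocks, batch shifts, leukocyte cell-type mixtures, and survival times
## linked to chosen CpGs.  All randomness is controlled by explicit seeds;
## a given seed reproduces the dataset exactly.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(seed)
  }
  force(code)
}

## Mean run length (consecutive manifest sites) per island relation, and
## mean gap in bp between consecutive sites.  Island spacing is tight
## (geometric, mean 80 bp) so >=7-site windows with gaps <= 500 bp occur
## naturally; open-sea spacing (mean 5 kb) almost never qualifies, giving
## both gap-pass and gap-fail scenarios.
DEFAULT_RUN_LENGTHS <- c(Island = 8, Shore = 6, Shelf = 3, OpenSea = 20)
DEFAULT_GAP_MEANS <- c(Island = 80, Shore = 400, Shelf = 2000, OpenSea = 5000,
                       cross = 3000)

#' Generate a synthetic CpG manifest
#'
#' Island relations are laid down in runs (a renewal process whose
#' long-run site fractions equal `context_proportions`), so island CpGs
#' cluster together as on the real chip.  Gene regions are drawn
#' conditionally on the island relation; gene symbols are assigned to
#' blocks of nearby non-intergenic sites.  Positions are strictly
#' increasing within each chromosome, 1-based.
#'
#' @param n_cpgs number of CpG sites.
#' @param chrom_count chromosomes to spread sites over (named 1, 2, ...).
#' @param context_proportions named site fractions per island relation.
#' @param gap_means named mean gaps (bp) per relation plus `cross` for
#'   run boundaries; gaps are 1 + geometric.
#' @param run_lengths mean run length per relation.
#' @param region_given_rel gene-region distribution within each relation.
#' @param seed integer seed.
#' @return an `mt_manifest`.
#' @export
generate_manifest <- function(n_cpgs,
                              chrom_count = 4,
                              context_proportions = CONTEXT_REL_PROPS,
                              gap_means = DEFAULT_GAP_MEANS,
                              run_lengths = DEFAULT_RUN_LENGTHS,
                              region_given_rel = CONTEXT_REGION_GIVEN_REL,
                              seed = 1) {
  if (n_cpgs < 1) stop_mt("n_cpgs must be >= 1")
  if (abs(sum(context_proportions) - 1) > 1e-8)
    stop_mt("context_proportions must sum to 1")
  rels <- names(context_proportions)
  with_seed(seed, {
    ## Renewal sequence of relation runs: picking run type with probability
    ## proportional to pi_r / L_r makes the site-level fractions equal pi_r.
    start_w <- context_proportions / run_lengths[rels]
    mean_len <- sum(start_w / sum(start_w) * run_lengths[rels])
    rel_seq <- character(0)
    run_id <- integer(0)
    k <- 0L
    while (length(rel_seq) < n_cpgs) {
      n_runs <- max(50L, ceiling(1.5 * (n_cpgs - length(rel_seq)) / mean_len))
      types <- sample(rels, n_runs, replace = TRUE, prob = start_w)
      lens <- 1L + stats::rgeom(n_runs, prob = 1 / run_lengths[types])
      rel_seq <- c(rel_seq, rep(types, lens))
      run_id <- c(run_id, rep(k + seq_len(n_runs), lens))
      k <- k + n_runs
    }
    rel_seq <- rel_seq[seq_len(n_cpgs)]
    run_id <- run_id[seq_len(n_cpgs)]

    region <- vapply(rel_seq, function(r) {
      sample(colnames(region_given_rel), 1, prob = region_given_rel[r, ])
    }, character(1))

    chrom_sizes <- split_count(n_cpgs, chrom_count)
    chrom <- rep(as.character(seq_len(chrom_count)), chrom_sizes)

    ## Gaps: within a run use the relation's spacing; across runs (or at a
    ## chromosome start) use the cross-run spacing.
    gap_mean <- ifelse(c(TRUE, diff(run_id) != 0), gap_means[["cross"]],
                       gap_means[rel_seq])
    gaps <- 1 + stats::rgeom(n_cpgs, prob = 1 / gap_mean)
    pos <- numeric(n_cpgs)
    for (cname in unique(chrom)) {
      idx <- which(chrom == cname)
      pos[idx] <- 10000 + cumsum(gaps[idx])
    }

    ## Gene symbols: a new gene starts at each run boundary falling outside
    ## intergenic context; IGR sites stay unannotated.
    gene_id <- cumsum(c(TRUE, diff(run_id) != 0) | c(TRUE, diff(match(chrom, unique(chrom))) != 0))
    symbol <- ifelse(region == "IGR", NA_character_,
                     sprintf("GENE%s_%04d", chrom, gene_id))

    as_manifest(data.frame(
      cpg_id = sprintf("cg%07d", seq_len(n_cpgs)),
      chrom = chrom, pos = pos,
      island_relation = rel_seq, gene_region = region,
      gene_symbol = symbol, stringsAsFactors = FALSE))
  })
}

## Default covariate composition: counts per category in a 280-patient
## cohort of African American prostate-cancer patients (GS=6/7/>=8 of
## 82/162/36; mostly never smokers, stage T1/T2, PSA < 10 ng/mL).
DEFAULT_COHORT_TABLES <- list(
  gleason = c(GS6 = 82, GS7 = 162, GS8plus = 36),
  smoking = c(never = 162, former = 84, current = 34),
  bmi_class = c(normal = 33, overweight = 86, obese = 115),
  stage = c(T1 = 162, T2 = 101, T3 = 11, T4 = 6),
  psa_class = c(lt10 = 216, b10to20 = 39, ge20 = 25),
  treatment = c(surgery = 168, radiation = 84, other = 28))

DEFAULT_CELL_TYPES <- c("Gran", "CD4T", "CD8T", "Bcell", "NK", "Mono")
DEFAULT_CELL_MEANS <- c(Gran = 0.55, CD4T = 0.17, CD8T = 0.09,
                        Bcell = 0.07, NK = 0.05, Mono = 0.07)

#' Cohort specification
#'
#' @param n_samples cohort size.
#' @param group_counts samples per Gleason group (GS6, GS7, GS8plus);
#'   must sum to `n_samples`.
#' @param n_batches array processing batches (balanced assignment).
#' @param cell_types leukocyte subtype names (K >= 2).
#' @param cell_means mean mixing proportions, summing to 1.
#' @param cell_concentration Dirichlet concentration: proportions are drawn
#'   from Dirichlet(concentration * means); larger = tighter around means.
#' @param tables named list of covariate category counts (scaled to the
#'   cohort size by largest remainder, then randomly assigned).
#' @param seed integer seed.
#' @return list of class `mt_cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 280,
                        group_counts = c(GS6 = 82, GS7 = 162, GS8plus = 36),
                        n_batches = 4,
                        cell_types = DEFAULT_CELL_TYPES,
                        cell_means = DEFAULT_CELL_MEANS,
                        cell_concentration = 60,
                        tables = DEFAULT_COHORT_TABLES,
                        seed = 1) {
  if (sum(group_counts) != n_samples)
    stop_mt("group_counts must sum to n_samples (%d != %d)",
            sum(group_counts), n_samples)
  if (length(cell_types) < 2) stop_mt("need at least 2 cell types")
  structure(list(n_samples = n_samples, group_counts = group_counts,
                 n_batches = n_batches, cell_types = cell_types,
                 cell_means = cell_means / sum(cell_means),
                 cell_concentration = cell_concentration,
                 tables = tables, seed = seed),
            class = "mt_cohort_spec")
}

## Category labels matching the target frequencies exactly (largest
## remainder), in random order.
draw_exact <- function(n, counts) {
  sample(rep(names(counts), exact_counts(n, counts)))
}

#' Generate a synthetic patient cohort
#'
#' Produces exact Gleason group sizes, clinical covariates drawn in the
#' configured category proportions, balanced batch labels, and Dirichlet
#' cell-type mixing proportions.  Biochemical-recurrence follow-up is left
#' `NA` until [generate_survival()] fills it in.
#'
#' @param spec an [cohort_spec()].
#' @return data.frame with one row per sample, cell proportions in
#'   `prop_<type>` columns.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "mt_cohort_spec"))
  n <- spec$n_samples
  with_seed(spec$seed, {
    group <- rep(GLEASON_GROUPS, spec$group_counts)
    age <- pmin(pmax(round(stats::rnorm(n, 58, 8.5)), 39), 83)
    props <- rdirichlet_mt(n, spec$cell_concentration * spec$cell_means)
    colnames(props) <- paste0("prop_", spec$cell_types)
    df <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      gleason_group = group,
      score = match(group, GLEASON_GROUPS) - 1L,
      age = age,
      smoking = draw_exact(n, spec$tables$smoking),
      bmi_class = draw_exact(n, spec$tables$bmi_class),
      stage = draw_exact(n, spec$tables$stage),
      psa_class = draw_exact(n, spec$tables$psa_class),
      treatment = draw_exact(n, spec$tables$treatment),
      batch = sample(rep_len(sprintf("B%d", seq_len(spec$n_batches)), n)),
      bcr_time = NA_real_,
      bcr_event = NA_integer_,
      stringsAsFactors = FALSE)
    cbind(df, as.data.frame(props))
  })
}

#' Spike trend effects into a manifest
#'
#' Chooses isolated differentially methylated CpGs (DMCs) and clustered
#' DMR blocks, assigning each a logit-scale slope delta per unit ordinal
#' Gleason score.  Blocks are runs of consecutive manifest sites whose
#' adjacent gaps are all `<= max_gap`, sharing one sign and effect size;
#' block membership and isolated DMCs are disjoint.  About `sign_mix` of
#' effects are methylation increases.
#'
#' @param manifest an `mt_manifest`.
#' @param n_dmcs isolated spiked sites.
#' @param n_dmrs spiked blocks.
#' @param dmr_size_range inclusive range of block sizes (>= 7 by default).
#' @param delta_range inclusive range of |delta| (logit-beta per score step).
#' @param sign_mix probability an effect is positive.
#' @param max_gap largest adjacent gap (bp) allowed inside a block.
#' @param seed integer seed.
#' @return list of class `mt_effects`: `dmc` (data.frame cpg_id, delta) and
#'   `dmr_blocks` (list of chrom, cpg_ids, sign, delta).
#' @export
spike_effects <- function(manifest, n_dmcs = 100, n_dmrs = 10,
                          dmr_size_range = c(7, 12),
                          delta_range = c(0.08, 0.15),
                          sign_mix = 0.8, max_gap = 500, seed = 1) {
  n <- nrow(manifest)
  with_seed(seed, {
    taken <- rep(FALSE, n)
    blocks <- list()
    if (n_dmrs > 0) {
      gaps <- c(diff(manifest$pos), Inf)
      gaps[c(manifest$chrom[-1] != manifest$chrom[-n], TRUE)] <- Inf
      ## gaps[i] = distance to the next site on the same chromosome
      attempts <- 0L
      while (length(blocks) < n_dmrs && attempts < 200L * n_dmrs) {
        attempts <- attempts + 1L
        size <- sample(seq(dmr_size_range[1], dmr_size_range[2]), 1)
        start <- sample(n - size + 1L, 1)
        idx <- start:(start + size - 1L)
        if (any(taken[idx]) || any(gaps[idx[-length(idx)]] > max_gap)) next
        taken[idx] <- TRUE
        blocks[[length(blocks) + 1L]] <- list(
          chrom = manifest$chrom[start],
          cpg_ids = manifest$cpg_id[idx],
          sign = if (stats::runif(1) < sign_mix) 1 else -1,
          delta = stats::runif(1, delta_range[1], delta_range[2]))
      }
      if (length(blocks) < n_dmrs)
        stop_mt("could only place %d of %d DMR blocks with gaps <= %d bp; use a denser manifest",
                length(blocks), n_dmrs, max_gap)
    }
    dmc <- data.frame(cpg_id = character(0), delta = numeric(0))
    if (n_dmcs > 0) {
      free <- which(!taken)
      if (length(free) < n_dmcs)
        stop_mt("manifest too small for %d isolated DMCs", n_dmcs)
      picks <- sort(sample(free, n_dmcs))
      sign <- ifelse(stats::runif(n_dmcs) < sign_mix, 1, -1)
      dmc <- data.frame(cpg_id = manifest$cpg_id[picks],
                        delta = sign * stats::runif(n_dmcs, delta_range[1],
                                                    delta_range[2]),
                        stringsAsFactors = FALSE)
    }
    structure(list(dmc = dmc, dmr_blocks = blocks), class = "mt_effects")
  })
}

#' Per-site effect vector implied by an effect map
#'
#' @param effects an `mt_effects` (or NULL for no effects).
#' @param manifest an `mt_manifest`.
#' @return named numeric vector of logit-slope delta per manifest site
#'   (0 at null sites).
#' @export
effect_vector <- function(effects, manifest) {
  delta <- stats::setNames(rep(0, nrow(manifest)), manifest$cpg_id)
  if (is.null(effects)) return(delta)
  stopifnot(inherits(effects, "mt_effects"))
  if (nrow(effects$dmc) > 0) delta[effects$dmc$cpg_id] <- effects$dmc$delta
  for (b in effects$dmr_blocks) delta[b$cpg_ids] <- b$sign * b$delta
  delta
}

#' Generate a synthetic beta matrix
#'
#' On the logit scale each entry is
#' \deqn{logit(\beta_{ij}) = \mu_{context(i)} + b_{batch(j)} +
#'   \sum_k \gamma_{ik} p_{jk} + \delta_i s_j + \epsilon_{ij}}
#' with context baselines from [calibrate_context_means()], optional batch
#' shifts, optional cell-signature effects weighted by the sample's mixing
#' proportions, spiked Gleason-trend effects (`s_j` = ordinal score), and
#' Gaussian noise.  The inverse logit is clipped to \[1e-6, 1-1e-6\].
#'
#' @param manifest an `mt_manifest`.
#' @param cohort a cohort data.frame ([generate_cohort()]).
#' @param effects optional `mt_effects`.
#' @param sigma_noise noise SD on the logit scale (default 0.15, chosen so
#'   that spiked effects translate to group-extreme beta differences of
#'   roughly 0.01-0.05).
#' @param batch_shifts optional named vector of logit shifts per batch.
#' @param cell_signatures optional matrix (marker CpGs x cell types, row
#'   names in the manifest) of logit deviations; each sample receives the
#'   proportion-weighted, centred combination.
#' @param context_model calibration from [calibrate_context_means()].
#' @param seed integer seed.
#' @return beta matrix (CpG x sample).
#' @export
generate_beta <- function(manifest, cohort, effects = NULL,
                          sigma_noise = 0.15, batch_shifts = NULL,
                          cell_signatures = NULL,
                          context_model = default_context_model(),
                          seed = 1) {
  if (sigma_noise < 0) stop_mt("sigma_noise must be >= 0")
  n_cpg <- nrow(manifest)
  n_smp <- nrow(cohort)
  with_seed(seed, {
    x <- matrix(context_baseline(manifest, context_model), n_cpg, n_smp)
    if (!is.null(batch_shifts)) {
      shift <- batch_shifts[cohort$batch]
      if (anyNA(shift)) stop_mt("batch_shifts missing a level present in cohort$batch")
      x <- sweep(x, 2, shift, `+`)
    }
    if (!is.null(cell_signatures)) {
      idx <- match(rownames(cell_signatures), manifest$cpg_id)
      if (anyNA(idx)) stop_mt("cell_signatures rows must be manifest CpGs")
      p <- as.matrix(cohort[, paste0("prop_", colnames(cell_signatures))])
      ## centre so the population-average mixture leaves baselines intact
      eff <- cell_signatures %*% t(p)
      x[idx, ] <- x[idx, ] + eff - rowMeans(eff)
    }
    delta <- effect_vector(effects, manifest)
    x <- x + outer(delta, cohort$score)
    if (sigma_noise > 0)
      x <- x + matrix(stats::rnorm(n_cpg * n_smp, 0, sigma_noise), n_cpg, n_smp)
    beta <- clip_beta(inv_logit(x))
    dimnames(beta) <- list(manifest$cpg_id, cohort$sample_id)
    beta
  })
}

#' Generate biochemical-recurrence follow-up
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(log_hr * I(beta > median))` at the linked CpG
#' (or constant hazard when `linked_cpg` is NULL); censoring is an
#' independent exponential truncated at `max_follow` months.
#'
#' @param cohort cohort data.frame.
#' @param beta beta matrix including `linked_cpg`.
#' @param linked_cpg CpG whose high-methylation group carries the hazard
#'   multiplier; NULL for a null (no-association) cohort.
#' @param log_hr log hazard ratio, high vs low methylation.
#' @param baseline_rate events per month in the low group (> 0).
#' @param censor_rate censoring rate per month (>= 0; 0 = administrative
#'   censoring at `max_follow` only).
#' @param max_follow administrative censoring horizon, months.
#' @param seed integer seed.
#' @return the cohort with `bcr_time` (months) and `bcr_event` filled in.
#' @export
generate_survival <- function(cohort, beta, linked_cpg = NULL, log_hr = 0,
                              baseline_rate = 0.008, censor_rate = 0.006,
                              max_follow = 120, seed = 1) {
  if (baseline_rate <= 0) stop_mt("baseline_rate must be > 0")
  if (censor_rate < 0) stop_mt("censor_rate must be >= 0")
  n <- nrow(cohort)
  with_seed(seed, {
    high <- rep(0L, n)
    if (!is.null(linked_cpg)) {
      if (!linked_cpg %in% rownames(beta))
        stop_mt("linked_cpg '%s' not present in beta matrix", linked_cpg)
      high <- dichotomize(beta[linked_cpg, cohort$sample_id])$high
    }
    rate <- baseline_rate * exp(log_hr * high)
    t_event <- stats::rexp(n, rate)
    t_cens <- if (censor_rate > 0) pmin(stats::rexp(n, censor_rate), max_follow)
              else rep(max_follow, n)
    cohort$bcr_time <- pmin(t_event, t_cens)
    cohort$bcr_event <- as.integer(t_event <= t_cens)
    cohort
  })
}

#' Synthetic leukocyte reference signature
#'
#' Builds an L marker-CpG x K cell-type matrix of reference beta values:
#' each type owns a set of markers that are highly methylated in that type
#' and lowly methylated elsewhere, mimicking the discriminating probes
#' used by reference-based deconvolution.
#'
#' @param L number of marker CpGs (>= K).
#' @param cell_types type names.
#' @param high,low beta levels for owned/other markers.
#' @param jitter_sd Gaussian jitter on the logit scale.
#' @param seed integer seed.
#' @return beta matrix, rows `mk0001...`, columns cell types.
#' @export
generate_cell_reference <- function(L = 100, cell_types = DEFAULT_CELL_TYPES,
                                    high = 0.85, low = 0.10,
                                    jitter_sd = 0.3, seed = 42) {
  K <- length(cell_types)
  if (L < K) stop_mt("need at least as many markers as cell types")
  with_seed(seed, {
    owner <- rep_len(seq_len(K), L)
    x <- matrix(logit(low), L, K)
    x[cbind(seq_len(L), owner)] <- logit(high)
    x <- x + matrix(stats::rnorm(L * K, 0, jitter_sd), L, K)
    ref <- inv_logit(x)
    dimnames(ref) <- list(sprintf("mk%04d", seq_len(L)), cell_types)
    ref
  })
}
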