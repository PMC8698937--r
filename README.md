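# methtrend

An R package implementing a leukocyte epigenome-wide association study
(EWAS) pipeline for aggressive prostate cancer: per-CpG methylation
trends across ordered Gleason-score groups, differentially methylated
region (DMR) calling, and survival association with biochemical
recurrence — exercised entirely on a bundled, calibrated synthetic
EPIC-like data generator, so every stage is testable without any array
download.

## The scientific problem

Most prostate cancers detected by PSA screening are indolent, yet
clinical variables (PSA, Gleason score, stage) separate aggressive from
non-aggressive disease poorly. DNA methylation in peripheral blood
leukocytes is a candidate biomarker: subtle, genome-wide shifts in CpG
methylation may track disease severity across immune cell types. The
statistical task is to take Illumina EPIC-style methylation data for a
patient cohort with three ordered tumor-grade groups (GS = 6, GS = 7,
GS ≥ 8) and find CpG sites, and runs of sites, whose methylation moves
monotonically with grade — then ask whether those sites predict relapse.

## What the package computes

For CpG *i* and sample *j*, the methylation fraction is the **β value**

    β = M / (M + U + α),   α = 100 by default,

with M and U the methylated/unmethylated probe intensities. The
pipeline stages, each an exported function group:

| Stage | Function(s) | Model / rule |
|---|---|---|
| β computation & IO | `compute_beta`, `read_*`/`write_*` | TSV manifest, matrices, sample sheet |
| Batch adjustment | `adjust_batch` | parametric empirical-Bayes location/scale correction on logit(β) (ComBat-style) |
| Cell deconvolution | `estimate_cell_proportions` | per sample solve min ‖r − Sw‖², w ≥ 0, Σw ≤ 1 (active-set least squares against a reference signature) |
| Trend test | `trend_test`, `trend_test_matrix` | least-squares slope of β on the ordinal score s ∈ {0,1,2} (+ covariates); two-sided t test on the slope |
| DMC tabulation | `tabulate_dmcs` | counts below p < .05/.01/10⁻³/10⁻⁴/10⁻⁵ and fraction of increases |
| DMR scan | `classify_sites`, `scan_dmrs`, `enumerate_dmrs_oracle` | maximal runs of ≥ 7 consecutive CpGs, same direction, each significant at p < 0.05, adjacent gaps ≤ 500 bp; plus a brute-force oracle |
| Context summary | `summarize_context` | mean β by island relation / gene region, per Gleason group |
| Survival | `dichotomize`, `fit_cox`, `bcr_association` | median-dichotomized multivariable Cox PH (Efron ties, Newton–Raphson), HR for high- vs low-methylation against biochemical recurrence |
| Enrichment | `hypergeometric_enrichment`, `enrichment_table` | upper-tail hypergeometric over-representation of DMR genes in user-supplied GMT sets |
| Synthetic data | `generate_manifest`, `generate_cohort`, `spike_effects`, `generate_beta`, `generate_survival` | logit-scale model: `logit β = μ_context + b_batch + Σ γ·p + δ·s + ε`, calibrated so context grand means match published leukocyte values |
| Orchestration | `run_config`, `run_pipeline`, `methtrend_cli` | JSON config, deterministic run directory with `summary.json` |

## Worked example

```r
library(methtrend)

man    <- generate_manifest(5000, seed = 1)
cohort <- generate_cohort(cohort_spec(seed = 2))   # 280 patients, 82/162/36
beta   <- generate_beta(man, cohort, seed = 3)
cohort <- generate_survival(cohort, beta, linked_cpg = "cg0000123",
                            log_hr = log(3.66), seed = 4)
bcr_association(beta, c("cg0000123", "cg0000200"), cohort)
#>      cpg_id   hr ci_low ci_high        p n_events converged degenerate
#> 1 cg0000123 3.70  2.642    5.18 2.46e-14      181      TRUE      FALSE
#> 2 cg0000200 1.03  0.768    1.39 8.28e-01      181      TRUE      FALSE
```

The CpG whose high-methylation group was generated with a hazard ratio
of 3.66 is recovered at HR 3.70 (95% CI 2.64–5.18, Wald p 2.5e-14,
181 relapse events); an unlinked CpG sits at HR 1.03. The full
pipeline, driven by one config:

```r
cfg <- run_config(seed = 11, n_cpgs = 20000, n_dmcs = 50, n_dmrs = 5,
                  delta_range = c(0.10, 0.15), write_matrices = FALSE)
s <- run_pipeline(cfg, "demo_run")
unlist(s$dmc_counts)
#> p_lt_0.05  p_lt_0.01 p_lt_0.001 p_lt_1e-04 p_lt_1e-05
#>      1068        274        121         98         97
c(n_dmrs = s$n_dmrs, sensitivity = s$recovery$sensitivity,
  false = s$recovery$false_dmrs)
#> n_dmrs sensitivity  false
#>      5           1      0
```

All 5 spiked DMR blocks are recovered with zero false regions on the
~20k null sites; the DMC ladder shows the 50 spiked single sites plus
the expected ~5% of nulls at the loosest rung. `demo_run/` contains
`trend.tsv`, `dmrs.tsv`/`dmrs.bed`, `cox.tsv`, `context.tsv` and a
deterministic `summary.json`.

A command-line front end mirrors the stages
(`Rscript inst/cli/methtrend.R run --config cfg.json --outdir out/`;
subcommands `beta`, `simulate`, `trend`, `dmr`, `context`, `cox`,
`enrich`).

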