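---
title: "methtrend: models, calibration, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methtrend: models, calibration, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistics: what each
stage assumes, why each tunable default has the value it has, what the
synthetic generator does and does not emulate, and where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The analysis model

### β values

Methylation at a CpG is summarized as β = M/(M + U + α) ∈ [0, 1]. The
offset default α = 100 is the array-convention stabilizer for
low-intensity probes; it is exposed because no single value is canonical.
All downstream analysis operates on β directly (not M-values): the trend
statistic is then interpretable as a methylation-fraction difference per
grade step, at the cost of mild variance heterogeneity near the β
boundaries. Missing entries are rejected rather than imputed — the run
scanner and the vectorized trend fit both assume complete rows, and
silent imputation would change the run semantics.

### Batch adjustment

`adjust_batch` is a parametric empirical-Bayes location/scale correction
in the ComBat style, re-implemented here (no external dependency): per
CpG the data are standardized against batch-mean-removed pooled variance,
per-batch location/scale estimates are shrunk toward their across-CpG
moments under normal / inverse-gamma priors via the usual fixed-point
iteration, and the standardized data are adjusted and back-transformed.
Two deliberate choices:

* **Logit scale.** The adjustment runs on logit(β) (β clipped to
  [1e-6, 1 − 1e-6]) so that output stays in [0, 1] and batch effects act
  additively, matching the generator's additive logit model. The source
  method's scale is unspecified in this context; the logit is the only
  choice that keeps the range closed under location/scale edits.
* **Exact re-centring.** After adjustment each CpG is re-centred to its
  original logit-scale mean. Any location/scale adjustment followed by a
  nonlinear back-transform cannot preserve the β-scale mean exactly, so
  the "grand mean preserved" invariant is enforced — exactly — on the
  logit scale instead.

Non-parametric priors are not implemented; requesting them is an error,
not a silent fallback.

### Cell-type deconvolution

`estimate_cell_proportions` solves, per sample,
min‖r − Sw‖² s.t. w ≥ 0, Σw ≤ 1 against a marker-CpG × cell-type
reference signature S — the reference-based (Houseman-style) projection
with the inequality constraint set, reporting 1 − Σw as unexplained
residual. The solver is exact: Lawson–Hanson NNLS first, and an
active-set solver on the probability simplex when the sum constraint
binds. Tests validate it against exhaustive active-set enumeration. The
shipped reference (`inst/extdata/cell_reference_synthetic.tsv`) is a
synthetic 6-type fixture (granulocyte, CD4 T, CD8 T, B, NK, monocyte
names; seed-42 generator output); real reference panels are out of
scope. Estimated proportions enter the trend test as linear covariates
(dropping the largest-mean type against collinearity) — the most common
reading of "controlling for cell proportions".

### The trend test

The per-CpG statistic is the least-squares slope of β on the ordinal
group score s ∈ {0, 1, 2} for GS = 6 / GS = 7 / GS ≥ 8, optionally with
covariates, tested two-sided against t on residual degrees of freedom.
Equal score spacing is the simplest reading of a three-group "trend
test" on a continuous outcome; a rank-based Jonckheere–Terpstra variant
sits behind `method = "jonckheere"` for sensitivity analysis (normal
approximation, no covariates). Whether the original analysis adjusted
its trend p-values for covariates is unknowable from the text; the
default is crude-plus-cell-proportions, and `run_pipeline` records the
choice in its outputs. No multiple-testing adjustment is applied per
CpG; the DMC tabulation mirrors the fixed nominal ladder
(0.05 … 1e-5, strict inequalities), and `bonferroni_threshold` computes
the genome-wide bound separately.

### DMR calling

A DMR is a **maximal** run of at least `min_cpgs = 7` consecutive
manifest CpGs, all individually significant (p < `site_p_threshold`,
default 0.05) with the same trend direction, every adjacent pair at most
`max_gap = 500` bp apart. Resolved ambiguities, all exposed in
`scanner_config` and shared by the brute-force oracle:

* *Consecutive* means adjacent in the manifest, not in the genome — an
  intervening assayed CpG that fails the filter breaks the run (label-0
  sites are not skipped). Without the per-site significance filter,
  sign-only runs of seven would occur by chance thousands of times over
  860k sites, which is incompatible with a genome-wide count of order
  10²; with it, the chance rate is ~(0.025)⁷ per window and the null
  false-call rate is below 1 per 100k sites (measured in the acceptance
  suite).
* The gap bound is inclusive (≤ 500 passes, 501 fails); boundaries are
  exercised explicitly in tests.
* Coordinates are 1-based inclusive member positions; BED export shifts
  to 0-based half-open and caps the −10·log₁₀(min p) score at 1000.

`enumerate_dmrs_oracle` enumerates all windows and filters — provably
maximal, quadratic, capped at 10⁴ sites — and the acceptance suite
checks scanner ≡ oracle on 200 randomized instances.

### Survival analysis

Each candidate CpG is dichotomized at the sample median (strictly
greater = high; ties and constants fall to the reference low group, with
a degenerate flag), then a multivariable Cox proportional-hazards model
is fit against biochemical recurrence adjusting for age (continuous) and
PSA class, Gleason group, stage, treatment (categorical; T3/T4 collapsed
because both are sparse). The engine is an own Newton–Raphson maximizer
of the Efron-tie-corrected partial likelihood with step halving;
inference is Wald (CI = exp(coef ± 1.96·se)) to match the HR (95% CI)
reporting convention. Convergence: relative log-likelihood change
< 1e-9 within 50 iterations; monotone likelihoods (|coef| > 15) are
flagged non-converged, and per-CpG failures surface as flags, never as
errors, so a screen over many CpGs cannot be aborted by one separation.
A Breslow option exists mainly to make the "Efron ≡ Breslow on tie-free
data" identity testable.

### Enrichment

`hypergeometric_enrichment` is the standard upper-tail test
P(X ≥ k) with population |universe|, successes |set ∩ universe|, draws
|hits|, with Benjamini–Hochberg across sets as a convenience. The
original GO analysis is unreproducible (no tool, background, or p-values
stated), so the package demonstrates the qualitative claim — strong
over-representation of homeobox and zinc-finger transcription-factor
genes among DMR genes — against shipped demo GMT sets built from the
published gene lists, inside a synthetic background universe.

## 2. The synthetic generator: a stated world

`generate_beta` draws, per CpG i and sample j,

logit(β_ij) = μ_context(i) + b_batch(j) + Σ_k γ_ik p_jk + δ_i s_j + ε_ij,
ε ~ N(0, σ²),

then inverse-logits and clips to [1e-6, 1 − 1e-6]. Effects act on the
logit scale so β stays in (0, 1) regardless of effect size; the analysis
still consumes β, as it must.

**Context calibration.** μ_context depends on the (island relation,
gene region) pair. `calibrate_context_means` solves for the 4 × 7 logit
baseline matrix by alternating marginal raking so that the implied grand
mean β per island relation hits (0.189, 0.420, 0.645, 0.625) for
Island/Shore/Shelf/OpenSea and per gene region hits
(0.187, 0.218, 0.378, 0.417, 0.566, 0.608, 0.653) for
TSS200/Exon1/TSS1500/5′UTR/IGR/Body/3′UTR — the published leukocyte
pattern of near-unmethylated islands and promoters rising with distance
from the TSS. The two marginal target sets are not perfectly consistent
with any joint table; the solver converges to a compromise whose final
sweep matches the island-relation marginals, leaving residuals well
inside the ±0.02 acceptance band (the noise-induced mean bias at
σ = 0.15 is ≤ ~0.001 and is ignored). The joint frequency table puts
19% of sites in islands (the chip's enrichment) and skews island sites
toward promoter regions.

**Manifest structure.** Island relations are laid down as a renewal
process of runs (mean lengths 8/6/3/20 sites for
Island/Shore/Shelf/OpenSea), with run-type probabilities chosen so the
long-run site fractions equal the configured proportions — islands
cluster, as on the chip. Spacing is geometric per relation: mean 80 bp
inside islands (so ≥ 7-site windows with gaps ≤ 500 bp arise
naturally), 400 bp in shores (both gap-pass and gap-fail cases occur),
5 kb in open sea (windows essentially never qualify).

**Cohort defaults.** 280 samples in Gleason groups 82/162/36; smoking
162/84/34, BMI 33/86/115, stage 162/101/11/6, PSA 216/39/25 — the
published cohort composition. Treatment (not tabulated anywhere) is
60/30/10 surgery/radiation/other. Categorical covariates are drawn as an
exact largest-remainder composition randomly assigned to samples rather
than iid multinomial: the cohort then reproduces the configured
percentages exactly, which the percentage-recomputation acceptance
targets require, at no cost to downstream analyses (assignment remains
random). Cell proportions are Dirichlet(concentration × means) with
leukocyte-like means (granulocytes 0.55, CD4 0.17, …) and concentration
60 — realistic inter-individual spread without degenerate mixtures.

**Effect sizes.** The original report says only that per-CpG β
differences between extreme grades are generally < 0.05. Defaults take
|δ| ∈ [0.08, 0.15] on the logit scale per grade step: near β = 0.5 that
is a β-slope of 0.02–0.037, i.e. group-extreme differences of 0.04–0.075,
and proportionally smaller near the boundaries — spanning the stated
0.01–0.05 range. This is an assumption, flagged as such. 80% of spiked
effects are increases (`sign_mix = 0.8`), matching the reported
preponderance of grade-associated hypermethylation. Noise σ = 0.15
(logit) makes the per-site slope t for the default δ range about
5.6–10.5 at n = 280 — comfortably past the ≥ 0.9 per-site power the
end-to-end recovery criterion presumes.

**Survival linkage.** Event times are exponential with hazard
`baseline_rate · exp(log_hr · I(β > median))` at one linked CpG, with
independent exponential censoring truncated at 120 months. Defaults
(baseline 0.008/month, censoring 0.006/month) give ~65% observed events
over a 10-year horizon — a realistic biochemical-recurrence follow-up.
The demonstration effect log(3.66) is used as a realistic magnitude for
a detectable association at n = 280.

**What the generator does not emulate**, hence what a green test does
not establish: Type I/II probe chemistry differences and probe-level
quality artifacts; SNP-affected probes; sex chromosomes; spatially
correlated noise beyond the block effects; non-Gaussian logit noise;
informative censoring. Recovery results on this world say the pipeline's
logic is correct, not that real-data sensitivity will match.

## 3. Numerical choices

* β clipping at 1e-6 bounds |logit| ≈ 13.8, far from overflow, and is
  invisible at data scale.
* The trend fit is one QR decomposition shared across all CpGs; rows
  with RSS < 1e-20 and |slope| < 1e-12 are flagged degenerate (slope 0,
  p 1) instead of producing 0/0; p-values are floored at the smallest
  positive double so p ∈ (0, 1] holds.
* The EB fixed point iterates to 1e-6 with a 500-iteration cap;
  degenerate hyperpriors (zero across-CpG variance, e.g. constant
  matrices) fall back to no shrinkage, and scale denominators are
  floored at 1e-12.
* The Cox Newton step halves up to 20 times on any likelihood decrease;
  ties are handled by Efron's correction within each death time.
* Chromosome order is the canonical 1..22, X, Y with unknown names
  sorted after, so scan output order is reproducible across inputs.
* `run_pipeline` derives all stage seeds from the single root seed, and
  `summary.json` is byte-identical across reruns of one config.

## 4. Known limitations

* The pipeline starts at intensity/β tables; idat parsing and
  upstream normalization are the caller's responsibility, and
  normalization choices there will move downstream numbers.
* Runs cannot tolerate interruptions: one noisy non-significant CpG
  splits an otherwise consistent region. This matches a strict reading
  of the region definition; kernel/bump-hunting methods are
  deliberately out of scope.
* Only parametric EB priors for batch adjustment are implemented.
* The cohort-dependent headline numbers of the motivating study (its
  DMC ladder, 77 DMRs, specific HRs) are not reproducible without the
  unreleased cohort; the package's claims are therefore property-based
  (oracle agreement, calibration, type-I error, power, recovery) plus
  the worked-example targets recomputed from printed tables.
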