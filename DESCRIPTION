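Package: methtrend
Title: Leukocyte EWAS Toolkit for Gleason-Ordinal Methylation Trends
Version: 0.1.0
Authors@R:
    person("methtrend", "developers", email = "methtrend@example.org",
           role = c("aut", "cre"))
Description: An epigenome-wide association study (EWAS) pipeline for
    Illumina EPIC-style leukocyte DNA methylation against an ordered
    clinical grade (Gleason score groups GS=6, GS=7, GS>=8). Computes
    beta values from methylated/unmethylated intensities, adjusts batch
    effects with an empirical-Bayes location/scale model on the logit
    scale, estimates leukocyte cell-type proportions by constrained
    least squares against a reference signature, runs per-CpG ordinal
    trend tests, tabulates differentially methylated CpG sites (DMCs),
    scans for differentially methylated regions (DMRs) as maximal runs
    of direction-consistent CpGs, summarises methylation by CpG context,
    fits median-dichotomized Cox proportional-hazards models against
    biochemical recurrence, and tests DMR gene lists for gene-set
    over-representation. Ships a calibrated synthetic-data generator so
    the whole pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
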