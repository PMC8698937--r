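test_that("generate_manifest is deterministic and genomically ordered", {
  m1 <- generate_manifest(100, seed = 7)
  m2 <- generate_manifest(100, seed = 7)
  expect_identical(m1, m2)
  m3 <- generate_manifest(100, seed = 8)
  expect_false(identical(m1$pos, m3$pos))

  one <- generate_manifest(200, chrom_count = 1, seed = 3)
  expect_equal(unique(one$chrom), "1")
  expect_true(all(diff(one$pos) > 0))
  for (cc in unique(m1$chrom))
    expect_true(all(diff(m1$pos[m1$chrom == cc]) > 0))
  expect_error(generate_manifest(0), "n_cpgs")
})

test_that("island fraction tracks the configured 19% enrichment", {
  man <- generate_manifest(20000, seed = 11)
  frac <- mean(man$island_relation == "Island")
  ## runs of mean length ~8 inflate binomial noise by sqrt(8):
  ## 5 * sqrt(.19 * .81 * 8 / 20000) ~ 0.039
  expect_lt(abs(frac - 0.19), 0.04)
  ## island spacing much tighter than open sea
  gap_by_rel <- function(m, rel) {
    idx <- which(m$island_relation == rel)
    idx <- idx[idx > 1 & m$island_relation[idx - 1] == rel &
                 m$chrom[idx] == m$chrom[idx - 1]]
    median(m$pos[idx] - m$pos[idx - 1])
  }
  expect_lt(gap_by_rel(man, "Island"), gap_by_rel(man, "OpenSea") / 10)
})

test_that("generate_cohort reproduces the configured composition exactly", {
  spec <- cohort_spec(seed = 2)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort), 280)
  expect_equal(unname(table(cohort$gleason_group)[c("GS6", "GS7", "GS8plus")]),
               c(82, 162, 36), ignore_attr = TRUE)
  expect_equal(sort(unname(table(cohort$smoking))), sort(c(162, 84, 34)),
               ignore_attr = TRUE)
  expect_equal(cohort$score, match(cohort$gleason_group,
                                   c("GS6", "GS7", "GS8plus")) - 1L)
  expect_identical(cohort, generate_cohort(spec))
  props <- as.matrix(cohort[, grep("^prop_", names(cohort))])
  expect_true(all(props >= 0))
  expect_equal(unname(rowSums(props)), rep(1, 280), tolerance = 1e-12)
  expect_error(cohort_spec(n_samples = 10, group_counts = c(1, 2, 3)),
               "sum to n_samples")
})

test_that("high Dirichlet concentration pins proportions at their means", {
  spec <- cohort_spec(n_samples = 40, group_counts = c(10, 20, 10),
                      cell_types = c("A", "B"), cell_means = c(A = .7, B = .3),
                      cell_concentration = 1e6, seed = 4)
  cohort <- generate_cohort(spec)
  expect_equal(mean(cohort$prop_A), 0.7, tolerance = 1e-2)
  expect_lt(sd(cohort$prop_A), 1e-3)
})

test_that("spike_effects places valid, disjoint blocks and DMCs", {
  man <- generate_manifest(5000, seed = 9)
  eff <- spike_effects(man, n_dmcs = 200, n_dmrs = 6,
                       dmr_size_range = c(7, 10), max_gap = 500, seed = 5)
  expect_length(eff$dmr_blocks, 6)
  block_ids <- unlist(lapply(eff$dmr_blocks, `[[`, "cpg_ids"))
  for (b in eff$dmr_blocks) {
    idx <- match(b$cpg_ids, man$cpg_id)
    expect_true(all(diff(idx) == 1))                     # consecutive in manifest
    expect_gte(length(idx), 7)
    expect_true(all(diff(man$pos[idx]) <= 500))
    expect_equal(unique(man$chrom[idx]), b$chrom)
    expect_true(b$sign %in% c(-1, 1))
  }
  expect_length(intersect(eff$dmc$cpg_id, block_ids), 0)
  expect_equal(nrow(eff$dmc), 200)

  empty <- spike_effects(man, n_dmcs = 0, n_dmrs = 0, seed = 1)
  expect_equal(nrow(empty$dmc), 0)
  expect_length(empty$dmr_blocks, 0)
  expect_equal(unname(effect_vector(empty, man)), rep(0, 5000))
})

test_that("sign_mix controls the fraction of methylation increases", {
  man <- generate_manifest(20000, seed = 13)
  eff <- spike_effects(man, n_dmcs = 1000, n_dmrs = 0, sign_mix = 0.8, seed = 6)
  expect_equal(mean(eff$dmc$delta > 0), 0.8, tolerance = 0.05)
})

test_that("spike_effects errors when blocks cannot be placed", {
  sparse <- as_manifest(data.frame(
    cpg_id = sprintf("cg%03d", 1:50), chrom = "1",
    pos = seq(1000, by = 5000, length.out = 50),
    island_relation = "OpenSea", gene_region = "IGR",
    gene_symbol = NA_character_))
  expect_error(spike_effects(sparse, n_dmcs = 0, n_dmrs = 2, max_gap = 500,
                             seed = 1),
               "could only place")
})

test_that("generate_beta noiseless limit equals the context baseline", {
  man <- generate_manifest(300, seed = 21)
  cohort <- generate_cohort(cohort_spec(n_samples = 12,
                                        group_counts = c(4, 4, 4), seed = 3))
  b <- generate_beta(man, cohort, sigma_noise = 0, seed = 1)
  expect_equal(unname(apply(b, 1, sd)), rep(0, 300), tolerance = 1e-12)
  model <- calibrate_context_means()
  i <- which(man$island_relation == "Island" & man$gene_region == "TSS200")[1]
  expect_equal(unname(b[i, 1]),
               plogis(model$mu["Island", "TSS200"]), tolerance = 1e-9)
  expect_error(generate_beta(man, cohort, sigma_noise = -1), "sigma_noise")
})

test_that("spiked positive effects raise group means monotonically", {
  man <- generate_manifest(300, seed = 22)
  cohort <- generate_cohort(cohort_spec(n_samples = 30,
                                        group_counts = c(10, 10, 10), seed = 4))
  eff <- spike_effects(man, n_dmcs = 5, n_dmrs = 0,
                       delta_range = c(0.2, 0.3), sign_mix = 1, seed = 7)
  b <- generate_beta(man, cohort, eff, sigma_noise = 0, seed = 2)
  for (cg in eff$dmc$cpg_id) {
    gm <- tapply(b[cg, ], cohort$score, mean)
    expect_true(all(diff(gm) > 0))
  }
})

test_that("generate_beta is seed-deterministic and seed-sensitive", {
  man <- generate_manifest(100, seed = 2)
  cohort <- generate_cohort(cohort_spec(n_samples = 9,
                                        group_counts = c(3, 3, 3), seed = 5))
  expect_identical(generate_beta(man, cohort, seed = 10),
                   generate_beta(man, cohort, seed = 10))
  expect_false(identical(generate_beta(man, cohort, seed = 10),
                         generate_beta(man, cohort, seed = 11)))
})

test_that("null generator gives uniform trend p-values (KS at alpha 0.01)", {
  man <- generate_manifest(10000, seed = 31)
  cohort <- generate_cohort(cohort_spec(seed = 32))
  b <- generate_beta(man, cohort, seed = 33)
  res <- trend_test_matrix(b, cohort$score)
  ks <- suppressWarnings(stats::ks.test(res$p_trend, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("generate_survival honours its contracts", {
  sc <- small_cohort_with_bcr()
  expect_true(all(sc$cohort$bcr_time > 0))
  expect_true(all(sc$cohort$bcr_event %in% 0:1))

  ## censor_rate = 0 with unlimited follow-up: every event observed
  cohort <- generate_survival(sc$cohort, sc$beta, censor_rate = 0,
                              max_follow = Inf, seed = 9)
  expect_true(all(cohort$bcr_event == 1))
  expect_error(generate_survival(sc$cohort, sc$beta, baseline_rate = 0),
               "baseline_rate")
  expect_error(generate_survival(sc$cohort, sc$beta, linked_cpg = "nope"),
               "not present")
})
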