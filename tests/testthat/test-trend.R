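test_that("trend_test handles degenerate and perfect-trend rows", {
  scores <- rep(0:2, each = 10)
  flat <- rep(0.4, 30)
  res <- trend_test(flat, scores)
  expect_equal(res$slope, 0)
  expect_equal(res$p_trend, 1)
  expect_true(res$degenerate)

  set.seed(1)
  y <- 0.1 + 0.1 * scores + rnorm(30, 0, 1e-6)   # tiny jitter breaks zero RSS
  res <- trend_test(y, scores)
  expect_equal(res$slope, 0.1, tolerance = 1e-4)
  expect_equal(res$direction, 1L)
  expect_equal(res$group_means, c(0.1, 0.2, 0.3), tolerance = 1e-5)
  expect_lt(res$p_trend, 1e-10)

  expect_error(trend_test(y, rep(1, 30)), "distinct scores")
  expect_error(trend_test(y[1:4], c(0, 1, 2, 2),
                          covariates = matrix(rnorm(8), 4, 2)), "covariates")
})

test_that("trend_test matches lm() with and without covariates", {
  set.seed(2)
  n <- 60
  scores <- sample(rep(0:2, each = 20))
  covs <- cbind(a = rnorm(n), b = runif(n))
  y <- plogis(rnorm(n, 0, 0.5) + 0.1 * scores + 0.3 * covs[, "a"])
  res <- trend_test(y, scores, covariates = covs)
  ref <- summary(lm(y ~ scores + covs))$coefficients["scores", ]
  expect_equal(res$slope, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(res$se, unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(res$p_trend, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)

  ## matrix version agrees with row-wise lm
  Y <- matrix(plogis(rnorm(5 * n, 0, .4)), 5, n,
              dimnames = list(paste0("cg", 1:5), paste0("s", 1:n)))
  out <- trend_test_matrix(Y, scores, covs)
  for (i in 1:5) {
    ref_i <- summary(lm(Y[i, ] ~ scores + covs))$coefficients["scores", ]
    expect_equal(out$slope[i], unname(ref_i["Estimate"]), tolerance = 1e-10)
    expect_equal(out$p_trend[i], unname(ref_i["Pr(>|t|)"]), tolerance = 1e-10)
  }
  expect_error(trend_test_matrix(Y, scores, cbind(covs, covs[, 1])), "singular")
})

test_that("reversing the ordinal coding flips the slope, not the p-value", {
  set.seed(3)
  scores <- rep(0:2, c(8, 16, 6))
  for (rep in 1:15) {
    y <- plogis(rnorm(30, 0, .4) + runif(1, -.2, .2) * scores)
    a <- trend_test(y, scores)
    b <- trend_test(y, 2 - scores)
    expect_equal(a$slope, -b$slope, tolerance = 1e-12)
    expect_equal(a$p_trend, b$p_trend, tolerance = 1e-12)
    expect_equal(a$direction, -b$direction)
  }
})

test_that("analytic p agrees with a permutation oracle", {
  set.seed(4)
  scores <- rep(0:2, c(8, 16, 6))
  diffs <- replicate(10, {
    y <- plogis(rnorm(30, 0, .4))
    p_perm <- perm_trend_p(y, scores, B = 1000, seed = sample.int(1e6, 1))
    p_an <- trend_test(y, scores)$p_trend
    abs(p_perm - p_an)
  })
  expect_lt(max(diffs), 0.08)   # 1000-permutation Monte-Carlo error
  expect_lt(median(diffs), 0.03)
})

test_that("detection rate is monotone in effect size", {
  set.seed(5)
  scores <- rep(0:2, c(82, 162, 36))
  rate <- vapply(c(0, 0.05, 0.1, 0.2), function(delta) {
    hits <- replicate(60, {
      y <- plogis(rnorm(280, 0, 0.15) + delta * scores)
      trend_test(y, scores)$p_trend < 0.05
    })
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rate) >= -0.05))  # non-decreasing up to MC noise
  expect_lt(rate[1], 0.15)
  expect_gt(rate[4], 0.9)
})

test_that("jonckheere alternative behaves sensibly", {
  set.seed(6)
  scores <- rep(0:2, each = 15)
  y_up <- scores + rnorm(45, 0, 0.3)
  res <- trend_test(y_up, scores, method = "jonckheere")
  expect_equal(res$direction, 1L)
  expect_lt(res$p_trend, 1e-4)
  res0 <- trend_test(rep(0.5, 45), scores, method = "jonckheere")
  expect_equal(res0$p_trend, 1)
  expect_true(res0$degenerate)
})

test_that("global_trend summarizes per-sample means", {
  sc <- small_cohort_with_bcr()
  ## duplicate one sample's values everywhere: all per-sample means equal
  b_const <- sc$beta
  b_const[] <- sc$beta[, 1]
  g <- global_trend(b_const, sc$cohort)
  expect_equal(unname(diff(g$group_means)), c(0, 0), tolerance = 1e-12)
  expect_equal(g$p_trend, 1)

  ## injected global logit shifts are detected
  shift <- plogis(qlogis(sc$beta) +
                  matrix(0.02 * sc$cohort$score, nrow(sc$beta),
                         ncol(sc$beta), byrow = TRUE))
  man <- generate_manifest(5000, seed = 41)
  cohort <- generate_cohort(cohort_spec(seed = 42))
  bb <- generate_beta(man, cohort, seed = 43)
  bb <- plogis(qlogis(bb) + matrix(0.004 * cohort$score, nrow(bb),
                                   ncol(bb), byrow = TRUE))
  g2 <- global_trend(bb, cohort)
  expect_true(all(diff(g2$group_means) > 0))
  expect_lt(g2$p_trend, 0.05)
})

test_that("tabulate_dmcs counts the fixed ladder correctly", {
  res <- data.frame(cpg_id = paste0("cg", 1:8),
                    p_trend = c(0.5, 0.04, 0.009, 0.0009, 9e-5, 9e-6, 0.2, 0.03),
                    direction = c(1, 1, -1, 1, 1, 1, -1, -1),
                    slope = 0, se = 0, t_stat = 0, degenerate = FALSE)
  tab <- tabulate_dmcs(res)
  ## manual tally: {.04, .009, .0009, 9e-5, 9e-6, .03} < .05 -> 6;
  ## < .01 -> 4; < .001 -> 3; < 1e-4 -> 2; < 1e-5 -> 1
  expect_equal(unname(tab$counts), c(6, 4, 3, 2, 1))
  expect_true(all(diff(tab$counts) <= 0))
  ## increasing among the six passers: .04, .0009, 9e-5, 9e-6 -> 4/6
  expect_equal(tab$fraction_increasing, 4 / 6)

  res$p_trend <- rep(0.5, 8)
  expect_equal(unname(tabulate_dmcs(res)$counts), rep(0, 5))
})

test_that("bonferroni_threshold is alpha over n", {
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(10, 0.5), 0.05)
  expect_equal(signif(bonferroni_threshold(850000, 0.05), 2), 5.9e-8)
  expect_error(bonferroni_threshold(0, 0.05), "positive integer")
  expect_error(bonferroni_threshold(10, 1.5), "alpha")
})
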