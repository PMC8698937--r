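test_that("adjust_batch validates its inputs", {
  b <- matrix(runif(20, .3, .7), 4, 5,
              dimnames = list(paste0("cg", 1:4), paste0("s", 1:5)))
  expect_error(adjust_batch(b, c("A", "A", "B", "B")), "one label per sample")
  expect_error(adjust_batch(b, c("A", "A", "A", "A", "B")), ">= 2 samples")
  expect_warning(out <- adjust_batch(b, rep("A", 5)), "single batch")
  expect_identical(out, b)
  expect_error(adjust_batch(b, rep(c("A", "B"), c(2, 3)), parametric = FALSE),
               "not implemented")
})

test_that("adjust_batch is the identity on a noiseless constant matrix", {
  b <- matrix(0.42, 6, 8,
              dimnames = list(paste0("cg", 1:6), paste0("s", 1:8)))
  out <- adjust_batch(b, rep(c("A", "B"), each = 4))
  expect_equal(out, b, tolerance = 1e-6)
})

test_that("adjust_batch matches a step-by-step worked EB computation", {
  ## two CpGs, two batches of three; worked independently below with
  ## scalar arithmetic following the parametric EB recipe
  x_beta <- matrix(c(0.30, 0.35, 0.32, 0.55, 0.52, 0.58,
                     0.70, 0.68, 0.74, 0.60, 0.66, 0.63),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("cgA", "cgB"), paste0("s", 1:6)))
  batch <- rep(c("b1", "b2"), each = 3)
  out <- adjust_batch(x_beta, batch)

  ## --- independent hand computation -------------------------------------
  x <- log(x_beta / (1 - x_beta))
  grand <- numeric(2); sd_pooled <- numeric(2)
  z <- x
  for (i in 1:2) {
    m1 <- mean(x[i, 1:3]); m2 <- mean(x[i, 4:6])
    grand[i] <- (3 * m1 + 3 * m2) / 6
    resid <- c(x[i, 1:3] - m1, x[i, 4:6] - m2)
    sd_pooled[i] <- sqrt(mean(resid^2))
    z[i, ] <- (x[i, ] - grand[i]) / sd_pooled[i]
  }
  adj <- z
  for (cols in list(1:3, 4:6)) {
    g_hat <- rowMeans(z[, cols]); d_hat <- apply(z[, cols], 1, var)
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    m <- mean(d_hat); s2 <- var(d_hat)
    a <- (2 * s2 + m^2) / s2; bpr <- (m * s2 + m^3) / s2
    g_star <- g_hat; d_star <- d_hat
    for (it in 1:500) {
      g_new <- (t2 * 3 * g_hat + d_star * g_bar) / (t2 * 3 + d_star)
      sum2 <- rowSums((z[, cols] - g_new)^2)
      d_new <- (0.5 * sum2 + bpr) / (3 / 2 + a - 1)
      if (max(abs(g_new - g_star), abs(d_new - d_star)) < 1e-6) {
        g_star <- g_new; d_star <- d_new; break
      }
      g_star <- g_new; d_star <- d_new
    }
    adj[, cols] <- (z[, cols] - g_star) / sqrt(d_star)
  }
  expected <- adj * sd_pooled + grand
  expected <- expected + (rowMeans(x) - rowMeans(expected))
  expected <- 1 / (1 + exp(-expected))
  ## ----------------------------------------------------------------------
  expect_equal(out, expected, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("adjust_batch reduces an injected logit shift and preserves range", {
  set.seed(14)
  n <- 40
  b0 <- matrix(plogis(rnorm(500 * n, 0, 1)), 500, n,
               dimnames = list(sprintf("cg%03d", 1:500), sprintf("s%02d", 1:n)))
  batch <- rep(c("A", "B"), each = n / 2)
  b <- b0
  b[, batch == "B"] <- plogis(qlogis(b0[, batch == "B"]) + 0.5)
  out <- adjust_batch(b, batch)
  pre <- rowMeans(qlogis(b[, batch == "B"])) - rowMeans(qlogis(b[, batch == "A"]))
  post <- rowMeans(qlogis(out[, batch == "B"])) - rowMeans(qlogis(out[, batch == "A"]))
  expect_lt(abs(median(post)), 0.1 * abs(median(pre)))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(dim(out), dim(b))
  ## per-CpG grand mean preserved on the logit scale
  expect_equal(rowMeans(qlogis(out)), rowMeans(qlogis(clip_beta_for_test(b))),
               tolerance = 1e-8)
})

test_that("cell proportions recover known mixtures", {
  ref <- generate_cell_reference(L = 100, seed = 42)
  set.seed(8)
  W <- rbind(diag(6),                                  # pure types
             t(replicate(20, { w <- rgamma(6, 2); w / sum(w) })),
             t(replicate(10, { w <- rgamma(6, 2); 0.8 * w / sum(w) })))
  R <- ref %*% t(W)
  colnames(R) <- sprintf("s%02d", seq_len(ncol(R)))
  est <- estimate_cell_proportions(R, ref)
  expect_lt(max(abs(est - W)), 1e-6)
  ## identity mixture -> unit vector
  expect_equal(unname(est[3, ]), c(0, 0, 1, 0, 0, 0), tolerance = 1e-8)
  ## residual reported for sub-simplex mixtures
  expect_equal(unname(attr(est, "residual")[27:36]), rep(0.2, 10),
               tolerance = 1e-6)
})

test_that("constrained solver agrees with exhaustive active-set oracle", {
  set.seed(19)
  for (rep in 1:40) {
    K <- sample(2:4, 1); L <- 12
    S <- matrix(runif(L * K), L, K,
                dimnames = list(sprintf("m%02d", 1:L), paste0("t", 1:K)))
    ## random targets, some far outside the feasible set to force both
    ## the sum constraint and nonnegativity to activate
    r <- as.vector(S %*% runif(K, -0.5, 1.5)) + rnorm(L, 0, 0.1)
    est <- estimate_cell_proportions(
      matrix(pmin(pmax(r, 0), 1), ncol = 1, dimnames = list(rownames(S), "s1")), S)
    oracle <- cls_enum_oracle(S, pmin(pmax(r, 0), 1))
    expect_equal(unname(est[1, ]), oracle, tolerance = 1e-6)
  }
})

test_that("estimate_cell_proportions input contracts hold", {
  ref <- generate_cell_reference(L = 20, seed = 1)
  bad <- ref; bad[, 2] <- bad[, 1]
  b <- matrix(0.5, 20, 2, dimnames = list(rownames(ref), c("s1", "s2")))
  expect_error(estimate_cell_proportions(b, bad), "rank deficient")
  expect_error(estimate_cell_proportions(b[1:10, ], ref), "absent")
  ## sample-order invariance
  est <- estimate_cell_proportions(b, ref)
  est_rev <- estimate_cell_proportions(b[, 2:1], ref)
  expect_equal(est["s1", ], est_rev["s1", ])
})

test_that("build_covariate_matrix encodes and aligns correctly", {
  cohort <- generate_cohort(cohort_spec(n_samples = 30,
                                        group_counts = c(10, 12, 8), seed = 6))
  props <- matrix(runif(30 * 6), 30, 6,
                  dimnames = list(cohort$sample_id, paste0("t", 1:6)))
  props <- props / rowSums(props)
  X <- build_covariate_matrix(cohort, props, covariates = c("age", "smoking"))
  expect_equal(nrow(X), 30)
  expect_equal(sum(grepl("^t", colnames(X))), 5)    # K - 1 proportion columns
  expect_true("age" %in% colnames(X))
  expect_equal(sum(grepl("^smoking_", colnames(X))), 2)

  ## shuffled proportion rows give the same matrix
  X2 <- build_covariate_matrix(cohort, props[sample(30), ],
                               covariates = c("age", "smoking"))
  expect_equal(X, X2)

  ## constant proportions are dropped with a warning
  const_props <- matrix(1 / 6, 30, 6,
                        dimnames = list(cohort$sample_id, paste0("t", 1:6)))
  expect_warning(Xc <- build_covariate_matrix(cohort, const_props), "constant")
  expect_false(any(grepl("^t", colnames(Xc))))
  expect_error(build_covariate_matrix(cohort, props[1:10, ]), "missing sample")
  expect_error(build_covariate_matrix(cohort, NULL, "nope"), "no column")
})
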