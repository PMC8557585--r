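test_that("group_summary reports n-1 SDs, ranges and flags degenerate groups", {
  gs <- group_summary(c(1, 2, 3), rep("a", 3))
  expect_equal(gs$mean, 2)
  expect_equal(gs$median, 2)
  expect_equal(gs$sd, 1)
  expect_equal(c(gs$min, gs$max), c(1, 3))

  gs <- group_summary(c(5, 1, 2), c("a", "b", "b"))
  expect_true(is.na(gs$sd[gs$label == "a"]))
  expect_equal(gs$n[gs$label == "a"], 1)

  gs <- group_summary(c(NA, 1), factor(c("a", "b"), levels = c("a", "b")))
  expect_equal(gs$n[gs$label == "a"], 0)
  expect_true(is.na(gs$mean[gs$label == "a"]))
})

test_that("exact Wilcoxon matches hand and brute-force enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(wilcoxon_rank_sum(rep(7, 3), rep(7, 3))$p_value, 1)

  set.seed(2)
  for (k in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:(10 - n1), 1)
    x <- round(rnorm(n1, 0, 2), 1)
    y <- round(rnorm(n2, 0.5, 2), 1)   # rounding induces occasional ties
    res <- wilcoxon_rank_sum(x, y, mode = "exact")
    expect_equal(res$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon p is invariant under common monotone transforms", {
  set.seed(8)
  x <- rnorm(8); y <- rnorm(8, 1)
  p0 <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
  trans <- list(function(v) exp(v), function(v) v^3, function(v) rank(v))
  for (f in trans) {
    pooled <- f(c(x, y))
    expect_equal(wilcoxon_rank_sum(pooled[1:8], pooled[9:16],
                                   mode = "exact")$p_value, p0)
  }
})

test_that("normal-approximation Wilcoxon agrees with the reference implementation", {
  set.seed(12)
  x <- round(rnorm(30, 0, 2), 1)
  y <- round(rnorm(25, 0.7, 2), 1)
  res <- wilcoxon_rank_sum(x, y, mode = "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Spearman r and exact permutation p match brute-force enumeration", {
  expect_equal(spearman_cor(1:6, (1:6)^3)$estimate, 1)
  expect_equal(spearman_cor(1:6, -(1:6))$estimate, -1)

  res <- spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3), mode = "exact")
  expect_equal(res$estimate, 0.6)
  expect_equal(res$p_value,
               oracle_spearman_p(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               tolerance = 1e-12)

  set.seed(6)
  for (n in 4:7) {
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n), 1)
    res <- spearman_cor(x, y, mode = "exact")
    expect_equal(res$p_value, oracle_spearman_p(x, y), tolerance = 1e-12)
  }
})

test_that("Spearman r is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- rnorm(12); y <- 0.5 * x + rnorm(12)
  r0 <- spearman_cor(x, y, mode = "t_approx")$estimate
  expect_equal(spearman_cor(exp(x), y, mode = "t_approx")$estimate, r0)
  expect_equal(spearman_cor(x, y^3, mode = "t_approx")$estimate, r0)
  expect_true(abs(r0) <= 1)
})

test_that("Spearman flags degenerate inputs and drops incomplete pairs", {
  res <- spearman_cor(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(res$estimate))
  expect_match(res$method, "undefined")

  res <- spearman_cor(c(1, 2, NA, 4, 5), c(2, NA, 3, 5, 6))
  expect_equal(res$n_used, 3)
  expect_equal(res$missing_excluded, 2)
})

test_that("Monte-Carlo Spearman p is reproducible and near the t answer", {
  set.seed(10)
  x <- rnorm(12); y <- 0.6 * x + rnorm(12)
  r1 <- spearman_cor(x, y, mode = "mc")
  r2 <- spearman_cor(x, y, mode = "mc")
  expect_identical(r1$p_value, r2$p_value)
  rt <- spearman_cor(x, y, mode = "t_approx")
  expect_lt(abs(r1$p_value - rt$p_value), 0.02)
})

test_that("partial Spearman removes covariate contributions on ranks", {
  # independent covariate: partial approx equals marginal
  set.seed(11)
  n <- 1000
  x <- rnorm(n); y <- 0.6 * x + rnorm(n); z <- rnorm(n)
  pr <- partial_spearman(x, y, z)$estimate
  mr <- spearman_cor(x, y, mode = "t_approx")$estimate
  expect_lt(abs(pr - mr), 0.05)

  # x = y: partial r is 1 for any non-collinear covariate
  expect_equal(partial_spearman(x[1:50], x[1:50], z[1:50])$estimate, 1)
  # covariate identical to y: flagged undefined
  res <- partial_spearman(x[1:50], y[1:50], y[1:50])
  expect_true(is.na(res$estimate))
  expect_match(res$method, "undefined")
})

test_that("partial Spearman shrinks a covariate-induced correlation", {
  set.seed(13)
  n <- 600
  z <- rnorm(n)
  x <- z + rnorm(n, 0, 0.5)
  y <- z + rnorm(n, 0, 0.5)
  marg <- spearman_cor(x, y, mode = "t_approx")$estimate
  part <- partial_spearman(x, y, z)$estimate
  expect_gt(marg, 0.5)
  expect_lt(abs(part), 0.2)
})

test_that("correlation_table runs pairwise with per-cell flags", {
  co <- generate_cohort(cohort_spec(n_benign = 40, n_malignant = 0,
                                    latent_spearman_rho = 1, seed = 21))
  df <- data.frame(q = co$quotient, cd34_100_fold = co$cd34_fraction,
                   cd34_25_fold = co$cd34_fraction,
                   cd34_all = co$cd34_fraction)
  ct <- correlation_table(df, smi_params = "q", mode = "t_approx")
  expect_equal(unname(ct$r["q", ]), c(1, 1, 1))

  tiny <- df[1:2, ]
  ct <- correlation_table(tiny, smi_params = "q", mode = "t_approx")
  expect_true(all(is.na(ct$r)))
  expect_error(correlation_table(df[0, ], smi_params = "q"),
               class = "vq_input_error")
})
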