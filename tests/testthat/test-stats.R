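test_that("Fisher ratio: hand values, symmetry, invariances", {
  expect_equal(fisher_ratio(c(0, 1, 2), c(4, 5, 6)), 8)
  expect_equal(fisher_ratio(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(0.2, 1.4, -0.3, 0.9); b <- c(2.2, 3.1, 2.8)
  expect_equal(fisher_ratio(a, b), fisher_ratio(b, a))
  expect_equal(fisher_ratio(a + 10, b + 10), fisher_ratio(a, b))
  expect_equal(fisher_ratio(3 * a, 3 * b), fisher_ratio(a, b))
  expect_error(fisher_ratio(c(1, 1), c(1, 1)), "constant")
})

test_that("KS test: hand-built ECDF cases and monotone invariance", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D, 1 / 3)
  withr::with_seed(3, { a <- rnorm(40); b <- rnorm(40, 0.7) })
  k1 <- ks_two_sample(a, b)
  k2 <- ks_two_sample(exp(a), exp(b))   # strictly monotone transform
  expect_equal(k1$D, k2$D)
  expect_equal(k1$p, k2$p)
  # permutation mode is seeded and agrees roughly with the asymptotic p
  kp1 <- ks_two_sample(a, b, method = "permutation", n_perm = 200, seed = 5)
  kp2 <- ks_two_sample(a, b, method = "permutation", n_perm = 200, seed = 5)
  expect_identical(kp1, kp2)
  expect_lt(kp1$p, 0.05)
})

test_that("Pearson correlation: exact lines and a hand computation", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1), 1)
  expect_equal(pearson_cor(x, -x), -1)
  expect_equal(pearson_cor(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_cor(x, rep(2, 4)), "variance")
})

test_that("Gaussian histogram fit recovers parameters and flags misfits", {
  withr::with_seed(10, v <- rnorm(10000, mean = 3, sd = 0.5))
  fit <- gaussian_fit_histogram(v, n_bins = 30)
  expect_equal(fit$mu, 3, tolerance = 0.05)
  expect_equal(fit$sigma, 0.5, tolerance = 0.05)
  expect_false(fit$misfit)

  withr::with_seed(11, bim <- c(rnorm(5000, -2, 0.3), rnorm(5000, 2, 0.3)))
  fitb <- gaussian_fit_histogram(bim, n_bins = 40)
  expect_true(fitb$misfit)

  expect_error(gaussian_fit_histogram(rep(1, 100)), "bins")
  expect_error(gaussian_fit_histogram(rnorm(10)), "20")
})

test_that("control-normalized means scale as stated", {
  g <- normalized_group_means(c(1, 2, 3), rep("ctl", 3), "ctl")
  expect_equal(g$normalized_mean, 1)
  expect_equal(g$normalized_sem, (sd(c(1, 2, 3)) / sqrt(3)) / 2)
  v <- c(1, 2, 3, 2, 4, 6)
  lab <- rep(c("ctl", "hi"), each = 3)
  g2 <- normalized_group_means(v, lab, "ctl")
  expect_equal(g2$normalized_mean[g2$group == "hi"], 2)
  expect_error(normalized_group_means(c(0, 0, 1), c("a", "a", "b"), "a"),
               "zero")
})

test_that("population_stats composes the group-level report", {
  withr::with_seed(20, {
    sc <- data.frame(
      sample = rep(c("control", "mid", "eotaxin_5h"), each = 60),
      activation_index = c(rnorm(60, 0), rnorm(60, 1), rnorm(60, 2)),
      integrated_sidescatter = c(rnorm(60, 100, 10), rnorm(60, 104, 10),
                                 rnorm(60, 110, 10)))
  })
  ps <- population_stats(sc)
  expect_s3_class(ps, "population_stats")
  expect_gt(ps$fisher_index, ps$fisher_sidescatter)
  expect_true(all(vapply(ps$ks_vs_control, function(k) k$D, 1) > 0))
  expect_equal(ps$sidescatter_means$normalized_mean[
    ps$sidescatter_means$group == "control"], 1)
  td <- withr::local_tempdir()
  paths <- write_stats_report(ps, td)
  expect_true(all(file.exists(paths)))
  rep <- utils::read.csv(paths["csv"])
  expect_true("fisher_ratio_index" %in% rep$statistic)
})
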