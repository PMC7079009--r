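test_that("a cell with no granules and no noise is pure cell body", {
  p <- cell_sim_params(granule_count_mean = 0, noise_sd = 0)
  cell <- simulate_cell(p, activation = 0, seed = 4)
  expect_equal(cell$darkfield, p$body_intensity * cell$mask + 0)
  expect_equal(sum(cell$autofluor), 0)
  expect_equal(cell$meta$granule_count, 0L)
})

test_that("simulation is a pure function of its seed", {
  p <- cell_sim_params()
  a <- simulate_cell(p, 0.5, seed = 11)
  b <- simulate_cell(p, 0.5, seed = 11)
  expect_identical(a, b)

  cfg <- cohort_config(samples = data.frame(label = c("s1", "s2"),
                                            activation = c(0, 1),
                                            n_cells = c(5L, 5L)),
                       n_distractors = 3L, seed = 9L)
  c1 <- simulate_cohort(cfg, p)
  c2 <- simulate_cohort(cfg, p)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$cells[[7]]$darkfield, c2$cells[[7]]$darkfield)
})

test_that("activation outside [0,1] and empty sample lists are rejected", {
  p <- cell_sim_params()
  expect_error(simulate_cell(p, -0.1), "activation")
  expect_error(simulate_cell(p, 1.5), "activation")
  expect_error(cohort_config(samples = data.frame()), "non-empty")
  expect_error(cell_sim_params(dispersion_base = 0.8, dispersion_gain = 0.5),
               "dispersion")
})

test_that("cohort bookkeeping: one ground-truth row per eosinophil", {
  p <- cell_sim_params()
  cfg <- cohort_config(samples = data.frame(label = c("a", "b", "c"),
                                            activation = c(0, .5, 1),
                                            n_cells = c(10L, 12L, 8L)),
                       n_distractors = 7L, seed = 2L)
  coh <- simulate_cohort(cfg, p)
  expect_equal(nrow(coh$truth), 30L)
  expect_equal(length(coh$cells), 37L)
  expect_false(anyDuplicated(coh$truth$cell_id) > 0)
  cls <- vapply(coh$cells, function(x) x$meta$class, "")
  expect_equal(sum(cls == "distractor"), 7L)
  # activation constant within a sample
  expect_true(all(tapply(coh$truth$activation_level, coh$truth$sample,
                         function(x) length(unique(x))) == 1L))
})

test_that("granule centres stay inside the dispersion radius and spread monotonically", {
  p <- cell_sim_params(noise_sd = 0)
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  mean_d <- numeric(length(levels))
  for (k in seq_along(levels)) {
    a <- levels[k]
    ds <- c()
    for (i in 1:40) {
      cell <- simulate_cell(p, a, seed = 1000 * k + i)
      g <- cell$meta$granules
      ctr <- cell$meta$center
      r <- cell$meta$radius
      d <- sqrt((g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2)
      expect_true(all(d <= (p$dispersion_base + p$dispersion_gain * a) * r + 1e-9))
      ds <- c(ds, d / r)
    }
    mean_d[k] <- mean(ds)
  }
  expect_true(all(diff(mean_d) > 0))
})

test_that("integrated dark-field is non-decreasing in activation and channels correlate", {
  p <- cell_sim_params()
  int_df <- function(a, seeds) vapply(seeds, function(s) {
    cell <- simulate_cell(p, a, seed = s)
    sum(cell$darkfield[cell$mask])
  }, numeric(1))
  seeds <- 1:500
  m <- vapply(c(0, 0.5, 1), function(a) mean(int_df(a, seeds)), numeric(1))
  expect_true(all(diff(m) > 0))

  vals <- t(vapply(1:300, function(s) {
    cell <- simulate_cell(p, (s %% 11) / 10, seed = 50000 + s)
    c(sum(cell$darkfield[cell$mask]), sum(cell$autofluor[cell$mask]))
  }, numeric(2)))
  expect_gt(stats::cor(vals[, 1], vals[, 2]), 0.8)
})
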