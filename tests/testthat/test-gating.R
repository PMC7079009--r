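test_that("degenerate dark-field images give empty masks, not errors", {
  expect_equal(sum(segment_cell(matrix(0, 16, 16))), 0)
  expect_equal(sum(segment_cell(matrix(3.7, 16, 16))), 0)
  expect_error(segment_cell(matrix(-1, 4, 4)), "non-negative")
})

test_that("segmentation recovers a single component containing the granules", {
  p <- cell_sim_params(noise_sd = 0)
  cell <- simulate_cell(p, 0.5, seed = 21)
  m <- segment_cell(cell$darkfield)
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  expect_equal(max(lab), 1)
  g <- round(cell$meta$granules)
  for (k in seq_len(nrow(g)))
    expect_true(m[g[k, "y"], g[k, "x"]])
})

test_that("segmentation is invariant to global intensity scaling", {
  p <- cell_sim_params(noise_sd = 0)
  cell <- simulate_cell(p, 0.3, seed = 5)
  m1 <- segment_cell(cell$darkfield)
  m2 <- segment_cell(cell$darkfield * 137.5)
  expect_identical(m1, m2)
})

test_that("mask area tracks the true disk area on seeded cells", {
  p <- cell_sim_params()
  ratios <- vapply(1:200, function(s) {
    cell <- simulate_cell(p, (s %% 5) / 4, seed = 300 + s)
    sum(segment_cell(cell$darkfield)) / sum(cell$mask)
  }, numeric(1))
  expect_gte(mean(ratios >= 0.5 & ratios <= 1.5), 0.95)
})

test_that("integrate_channel matches brute-force summation and is additive", {
  img <- matrix(2, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:2, 1:5] <- TRUE
  expect_equal(integrate_channel(img, mask), 20)
  expect_equal(integrate_channel(img, matrix(TRUE, 10, 10)), sum(img))
  expect_error(integrate_channel(img, matrix(FALSE, 10, 10)), "empty")

  withr::with_seed(8, {
    rimg <- matrix(runif(64), 8, 8)
    rmask <- matrix(runif(64) > 0.5, 8, 8)
  })
  brute <- 0
  for (i in 1:8) for (j in 1:8) if (rmask[i, j]) brute <- brute + rimg[i, j]
  expect_equal(integrate_channel(rimg, rmask), brute)
  # additivity over disjoint masks
  m1 <- rmask; m1[5:8, ] <- FALSE
  m2 <- rmask & !m1
  if (any(m1) && any(m2))
    expect_equal(integrate_channel(rimg, m1) + integrate_channel(rimg, m2),
                 integrate_channel(rimg, rmask))
})

test_that("quadrant gate applies strict thresholds, area window, idempotence", {
  ev <- data.frame(cell_id = c("a", "b", "c", "d"),
                   sample = "s",
                   integrated_sidescatter = c(10, 100, 100, 100),
                   integrated_autofluorescence = c(50, 5, 50, 50),
                   mask_area = c(500, 500, 500, 10),
                   gated = FALSE, stringsAsFactors = FALSE)
  g <- quadrant_gate(ev, gate_config(autofluor_threshold = 15,
                                     sidescatter_threshold = 80,
                                     min_mask_area = 250, max_mask_area = 1600))
  expect_equal(g$cell_id, "c")
  expect_true(all(g$gated))
  # permissive gate retains everything with areas in range
  g0 <- quadrant_gate(ev[ev$mask_area >= 250, ],
                      gate_config(0, 0, 1, 1e6))
  expect_equal(nrow(g0), 3L)
  # boundary: exactly at the threshold is excluded
  ev2 <- ev[3, ]; ev2$integrated_sidescatter <- 80
  expect_equal(nrow(quadrant_gate(ev2, gate_config(15, 80, 250, 1600))), 0L)
  # idempotence
  expect_equal(quadrant_gate(g, gate_config(15, 80, 250, 1600))$cell_id,
               g$cell_id)
})

test_that("the default gate separates eosinophils from distractors", {
  p <- cell_sim_params()
  cfg <- cohort_config(samples = data.frame(label = c("lo", "hi"),
                                            activation = c(0, 1),
                                            n_cells = c(60L, 60L)),
                       n_distractors = 60L, seed = 31L)
  coh <- simulate_cohort(cfg, p)
  wce <- whole_cell_events(coh$cells)
  g <- quadrant_gate(wce$events)
  cls <- vapply(coh$cells, function(x) x$meta$class, "")
  ids <- vapply(coh$cells, function(x) x$meta$cell_id, "")
  eos_ids <- ids[cls == "eosinophil"]
  dis_ids <- ids[cls == "distractor"]
  expect_gte(mean(eos_ids %in% g$cell_id), 0.95)
  expect_gte(mean(!dis_ids %in% g$cell_id), 0.95)
})
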