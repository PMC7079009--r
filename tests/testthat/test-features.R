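test_that("intensity statistics on constructed inputs", {
  mask <- disk_mask(12, 4)
  img <- matrix(0, 12, 12); img[mask] <- 3
  f <- intensity_features(img, mask)
  expect_equal(unname(f["Int_Integrated"]), 3 * sum(mask))
  expect_equal(unname(f[c("Int_Mean", "Int_Median", "Int_Min", "Int_Max")]),
               rep(3, 4))
  expect_equal(unname(f[c("Int_StdDev", "Int_MAD", "Int_MassDisplacement")]),
               rep(0, 3))
  expect_equal(unname(f["Int_EdgeMean"]), 3)

  # point mass off-centre: displacement is the centroid-to-pixel distance
  img2 <- matrix(0, 12, 12); img2[4, 5] <- 1
  f2 <- intensity_features(img2, mask)
  ctr <- c(mean(row(mask)[mask]), mean(col(mask)[mask]))
  expect_equal(unname(f2["Int_MassDisplacement"]),
               sqrt(sum((ctr - c(4, 5))^2)))
  expect_error(intensity_features(img, matrix(FALSE, 12, 12)), "empty")
})

test_that("radial distribution on uniform and concentrated inputs", {
  mask <- disk_mask(15, 6)
  img <- matrix(0, 15, 15); img[mask] <- 2
  f <- radial_distribution(img, mask)
  expect_equal(unname(f["Rad_FracAtD_b1"] + f["Rad_FracAtD_b2"]), 1)
  expect_equal(unname(f[c("Rad_MeanFrac_b1", "Rad_MeanFrac_b2")]), c(1, 1))

  # all intensity well inside the inner annulus
  img2 <- matrix(0, 15, 15); img2[8, 8] <- 5; img2[8, 9] <- 5
  f2 <- radial_distribution(img2, mask)
  expect_equal(unname(f2["Rad_FracAtD_b1"]), 1)
  expect_equal(unname(f2["Rad_FracAtD_b2"]), 0)
})

test_that("granularity spectrum: zeros, disk fixture, positivity", {
  mask <- disk_mask(20, 8)
  expect_equal(unname(granularity_spectrum(matrix(0, 20, 20), mask)),
               rep(0, 16))
  # flat disk of radius 3: mass concentrated at sieving steps <= 4
  img <- matrix(0, 20, 20); img[disk_mask(20, 3)] <- 1
  g <- granularity_spectrum(img, matrix(TRUE, 20, 20))
  expect_gte(sum(g[1:4]) / sum(g), 0.95)
  expect_true(all(g >= 0))
  expect_lte(sum(g), 100 + 1e-9)
})

test_that("Haralick values on a constant image and a checkerboard", {
  mask <- disk_mask(10, 4)
  img <- matrix(1, 10, 10)
  f <- haralick_texture(img, mask)
  for (d in c(1, 2, 3, 5)) {
    expect_equal(unname(f[paste0("Tex_ASM_d", d)]), 1)
    expect_equal(unname(f[paste0("Tex_Contrast_d", d)]), 0)
    expect_equal(unname(f[paste0("Tex_Entropy_d", d)]), 0)
    expect_equal(unname(f[paste0("Tex_Correlation_d", d)]), 0)
  }

  # 4x4 two-level checkerboard, full mask, offset 1: horizontal and
  # vertical neighbours always differ, diagonal neighbours always agree.
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  fcb <- haralick_texture(cb, matrix(TRUE, 4, 4), offsets = 1L, n_levels = 8L)
  # by hand: 24 symmetric pairs per axial direction all with |i-j| = 7
  # (levels 1 and 8); 18 pairs per diagonal direction all equal.
  # direction-averaged contrast = mean(c(49, 49, 0, 0))
  expect_equal(unname(fcb["Tex_Contrast_d1"]), mean(c(49, 49, 0, 0)))
  # the direction-averaged GLCM puts mass 0.25 on each of (1,8), (8,1),
  # (1,1), (8,8) (axial pairs all unequal, diagonal pairs all equal with
  # 10/18 + 8/18 summing across the two diagonals), so ASM = 4 * 0.25^2
  expect_equal(unname(fcb["Tex_ASM_d1"]), 0.25)
  expect_equal(unname(fcb), oracle_haralick(cb, matrix(TRUE, 4, 4), 1L),
               tolerance = 1e-12)
})

test_that("every family matches brute-force recomputation on random fixtures", {
  for (s in 1:10) {
    fx <- random_cell_fixture(s)
    expect_equal(unname(intensity_features(fx$image, fx$mask)),
                 oracle_intensity(fx$image, fx$mask), tolerance = 1e-10)
    expect_equal(unname(radial_distribution(fx$image, fx$mask)),
                 oracle_radial(fx$image, fx$mask), tolerance = 1e-10)
    expect_equal(unname(granularity_spectrum(fx$image, fx$mask)),
                 oracle_granularity(fx$image, fx$mask), tolerance = 1e-10)
    expect_equal(unname(haralick_texture(fx$image, fx$mask)),
                 oracle_haralick(fx$image, fx$mask), tolerance = 1e-10)
  }
})

test_that("extract_features returns 85 stably named finite values", {
  expect_length(feature_names(), 85L)
  p <- cell_sim_params()
  cell <- simulate_cell(p, 0.4, seed = 77)
  f <- extract_features(cell)
  expect_length(f, 85L)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  expect_identical(f, extract_features(cell))
})

test_that("intensity scaling moves intensity features and leaves the rest", {
  fx <- random_cell_fixture(3)
  f1 <- extract_features(fx$image, fx$mask)
  f2 <- extract_features(fx$image * 7.5, fx$mask)
  int_scaled <- c("Int_Integrated", "Int_Mean", "Int_Median", "Int_StdDev",
                  "Int_MAD", "Int_Min", "Int_Max", "Int_LowerQuartile",
                  "Int_UpperQuartile", "Int_EdgeMean")
  expect_equal(f2[int_scaled], 7.5 * f1[int_scaled])
  rest <- setdiff(names(f1), int_scaled)
  expect_equal(f2[rest], f1[rest], tolerance = 1e-10)
})

test_that("rotation by 90 degrees preserves rotation-blind families", {
  p <- cell_sim_params(noise_sd = 0)
  cell <- simulate_cell(p, 0.6, seed = 13)
  img <- cell$darkfield; mask <- cell$mask
  rot <- function(m) t(m)[, nrow(m):1] # 90-degree rotation
  f1 <- extract_features(img, mask)
  f2 <- extract_features(rot(img), rot(mask))
  fam <- function(prefix) grep(prefix, names(f1), value = TRUE)
  expect_equal(f1[fam("^Int_")], f2[fam("^Int_")], tolerance = 1e-8)
  expect_equal(f1[fam("^Gran_")], f2[fam("^Gran_")], tolerance = 1e-8)
  expect_equal(f1[fam("^Tex_")], f2[fam("^Tex_")], tolerance = 1e-8)
})

test_that("failing cells are dropped with a reason, not imputed", {
  p <- cell_sim_params()
  cells <- list(simulate_cell(p, 0.5, seed = 1), simulate_cell(p, 0.5, seed = 2))
  cells[[1]]$meta$cell_id <- "ok"; cells[[1]]$meta$sample <- "s"
  cells[[2]]$meta$cell_id <- "bad"; cells[[2]]$meta$sample <- "s"
  gated <- data.frame(cell_id = c("ok", "bad"), sample = "s",
                      stringsAsFactors = FALSE)
  masks <- list(ok = cells[[1]]$mask,
                bad = matrix(FALSE, 64, 64)) # empty mask: extraction fails
  masks$bad[1, 1] <- TRUE                    # 1 px: no co-occurring pairs
  res <- extract_feature_table(cells, gated, masks)
  expect_equal(res$table$cell_id, "ok")
  expect_equal(res$dropped$cell_id, "bad")
  expect_match(res$dropped$reason, "pairs|annulus|intensity")
})
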