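test_that("edge-detect config validates thresholds", {
  expect_error(edge_detect_config(detector = "sobel", threshold = c(1, 2)),
               "single")
  expect_error(edge_detect_config(detector = "canny", threshold = 0.5),
               "low, high")
  expect_error(edge_detect_config(detector = "canny",
                                  threshold = c(0.8, 0.2)), "low <= high")
})

test_that("digital edge masks behave on flat and step images", {
  flat <- matrix(5, 40, 40)
  expect_false(any(digital_edge_mask(flat)))
  step <- cbind(matrix(0, 40, 20), matrix(100, 40, 20))
  for (det in c("sobel", "canny")) {
    thr <- if (det == "sobel") 0.3 else c(0.1, 0.3)
    m0 <- digital_edge_mask(step, edge_detect_config(detector = det,
                                                     threshold = thr,
                                                     dilation_radius_px = 0))
    expect_true(any(m0[, 19:22]))
    # the band contains the step and grows with dilation
    m3 <- digital_edge_mask(step, edge_detect_config(detector = det,
                                                     threshold = thr,
                                                     dilation_radius_px = 3))
    expect_true(all(m0[m0] <= m3[m0]))
    expect_gt(sum(m3), sum(m0))
  }
})

test_that("sobel masking matches a small-crop reimplementation oracle", {
  r <- render_quadrants(bead_scene(g = 0.9, canvas = 64, radius = 14))
  df <- compute_darkfield(r$stack)
  cfg <- edge_detect_config(detector = "sobel", threshold = 0.4,
                            dilation_radius_px = 0)
  got <- digital_edge_mask(df, cfg)
  # oracle: separable gaussian blur + explicit 3x3 sobel conv + threshold,
  # checked away from the border to avoid padding-convention differences
  blur <- EBImage::gblur(df, sigma = 2)
  H <- nrow(df); W <- ncol(df)
  mag <- matrix(0, H, W)
  for (i in 2:(H - 1)) for (j in 2:(W - 1)) {
    gx <- (blur[i - 1, j + 1] + 2 * blur[i, j + 1] + blur[i + 1, j + 1]) -
      (blur[i - 1, j - 1] + 2 * blur[i, j - 1] + blur[i + 1, j - 1])
    gy <- (blur[i + 1, j - 1] + 2 * blur[i + 1, j] + blur[i + 1, j + 1]) -
      (blur[i - 1, j - 1] + 2 * blur[i - 1, j] + blur[i - 1, j + 1])
    mag[i, j] <- sqrt(gx^2 + gy^2)
  }
  inner <- matrix(FALSE, H, W); inner[3:(H - 2), 3:(W - 2)] <- TRUE
  ref <- stats::quantile(mag[inner], 0.99, names = FALSE)
  oracle <- mag > 0.4 * ref
  agree <- mean(got[inner] == oracle[inner])
  expect_gt(agree, 0.97)
})

test_that("mask area is monotone in threshold and dilation", {
  r <- render_quadrants(cell_scene(seed = 3))
  df <- compute_darkfield(r$stack)
  areas_thr <- vapply(c(0.1, 0.3, 0.5, 0.8), function(t) {
    sum(digital_edge_mask(df, edge_detect_config(threshold = t,
                                                 dilation_radius_px = 1)))
  }, numeric(1))
  expect_true(all(diff(areas_thr) <= 0))
  areas_dil <- vapply(c(0, 1, 3, 5), function(d) {
    sum(digital_edge_mask(df, edge_detect_config(threshold = 0.3,
                                                 dilation_radius_px = d)))
  }, numeric(1))
  expect_true(all(diff(areas_dil) >= 0))
})

test_that("edge-suppression scores hit their analytic endpoints", {
  r <- render_quadrants(imperfect_bead_scene(), quantize = FALSE)
  df <- compute_darkfield(r$stack)
  em <- r$truth$edge_mask; pm <- r$truth$puncta_mask
  sc1 <- edge_suppression_score(df, df, em, pm, c = 1)
  expect_equal(sc1$edge_residual_fraction, 1, tolerance = 1e-12)
  expect_equal(sc1$puncta_retention_fraction, 1, tolerance = 1e-12)
  z <- matrix(0, nrow(df), ncol(df))
  sc0 <- edge_suppression_score(z, df, em, pm)
  expect_equal(sc0$edge_residual_fraction, 0)
  expect_equal(sc0$puncta_retention_fraction, 0)
  expect_error(edge_suppression_score(df, df, z > 0, pm), "nonempty")
  # ideal QDF on the g=0.9 / g=0 phantom: strong suppression, high retention
  c_hat <- as.numeric(calibrate_c(r$stack, em))
  rec <- compute_qdf(r$stack, c = c_hat)
  sq <- edge_suppression_score(pmax(rec$qdf, 0), rec$df, em, pm, c = c_hat)
  expect_lte(sq$edge_residual_fraction, 0.1)
  expect_gte(sq$puncta_retention_fraction, 0.8)
})

test_that("the baseline sweep reports the grid and flags the best row", {
  r <- render_quadrants(imperfect_bead_scene())
  df <- compute_darkfield(r$stack)
  em <- r$truth$edge_mask; pm <- r$truth$puncta_mask
  one <- sweep_baseline(df, em, pm, threshold_grid = 0.3, dilation_grid = 2,
                        target_edge_residual = 1)
  expect_equal(nrow(one), 1)
  # an impossible threshold gives an empty mask and edge residual 1
  hi <- sweep_baseline(df, em, pm, threshold_grid = 1e6, dilation_grid = 0,
                       target_edge_residual = 1)
  expect_equal(hi$mask_area, 0)
  expect_equal(hi$edge_residual_fraction, 1, tolerance = 1e-12)
  grid <- sweep_baseline(df, em, pm,
                         threshold_grid = c(0.1, 0.3, 0.6),
                         dilation_grid = c(0, 2),
                         target_edge_residual = 1)
  expect_equal(nrow(grid), 6)
  expect_equal(sum(grid$best), 1)
  best <- grid[grid$best, ]
  expect_equal(best$puncta_retention_fraction,
               max(grid$puncta_retention_fraction))
  # zeroing masked pixels never increases the edge residual
  expect_true(all(grid$edge_residual_fraction <= 1 + 1e-12))
})
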