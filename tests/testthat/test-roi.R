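# ROI volumetry, tissue masking, trend fitting, table export.

make_label_img <- function() {
  d <- c(20, 20, 20)
  lab <- array(0L, d)
  lab[1:10, 1:10, 1:10] <- 1L    # 1000 voxels
  lab[11:20, 1:10, 1:10] <- 2L   # 1000 voxels
  lab[1:5, 11:20, 1:10] <- 3L    # 500 voxels
  image_grid(lab)
}

test_that("ROI volumes are additive and overlap-safe", {
  labs <- make_label_img()
  v <- measure_volumes(labs, list(a = 1L, b = 2L, ab = c(1L, 2L)))
  expect_equal(v$volume_mm3[v$roi == "a"], 1000)
  expect_equal(v$volume_mm3[v$roi == "ab"],
               v$volume_mm3[v$roi == "a"] + v$volume_mm3[v$roi == "b"])
  # overlapping definitions count shared voxels once (inclusion-exclusion)
  v2 <- measure_volumes(labs, list(u = c(1L, 2L), a = 1L, b = 2L))
  expect_equal(v2$volume_mm3[v2$roi == "u"], 2000)
  expect_error(measure_volumes(labs, list(bad = 99L)), "unknown")
  expect_s3_class(v, "tbl_df")
})

test_that("tissue masking intersects ROI and segmentation", {
  labs <- make_label_img()
  seg_all_gm <- with_voxels(labs, array(2L, grid_dim(labs)))
  m <- mask_roi_with_tissue(labs, seg_all_gm, 1L, 2L)
  expect_equal(sum(m$voxels), 1000)
  seg_none <- with_voxels(labs, array(3L, grid_dim(labs)))
  expect_equal(sum(mask_roi_with_tissue(labs, seg_none, 1L, 2L)$voxels), 0)
  # known GM fraction inside the ROI
  seg <- with_voxels(labs, array(3L, grid_dim(labs)))
  seg$voxels[1:10, 1:6, 1:10] <- 2L   # 60% of ROI 1 is GM
  frac <- sum(mask_roi_with_tissue(labs, seg, 1L, 2L)$voxels) / 1000
  expect_equal(frac, 0.6, tolerance = 0.02)
  small <- image_grid(array(0L, c(5, 5, 5)))
  expect_error(mask_roi_with_tissue(labs, small, 1L, 2L), "mismatch")
})

test_that("normalization and OLS trend reproduce closed-form values", {
  # constant series
  ct <- normalize_and_trend(c(50, 50, 50), c(0, 6, 12))
  expect_equal(ct$normalized, rep(1, 3))
  expect_equal(ct$slope, 0, tolerance = 1e-12)
  # the canonical normalized hippocampal trajectory
  tr <- normalize_and_trend(c(1, 0.995, 0.99, 0.981), c(0, 6, 12, 24))
  expect_equal(tr$slope, -0.249 / 315, tolerance = 1e-9)
  expect_lt(abs(tr$slope - (-7.90e-4)), 1e-6)
  # permutation invariance
  p <- c(3, 1, 4, 2)
  tr2 <- normalize_and_trend(c(1, 0.995, 0.99, 0.981)[p], c(0, 6, 12, 24)[p])
  expect_equal(tr2$slope, tr$slope, tolerance = 1e-12)
  # scale invariance of the normalized series
  tr3 <- normalize_and_trend(7 * c(1, 0.995, 0.99, 0.981), c(0, 6, 12, 24))
  expect_equal(tr3$normalized, tr$normalized)
  expect_error(normalize_and_trend(c(0, 1), c(0, 6)), "baseline")
  # tidy/glance surfaces
  td <- tidy(tr)
  expect_equal(td$term, c("intercept", "slope_per_month"))
  expect_equal(td$estimate[2], tr$slope)
  gl <- glance(tr)
  expect_equal(gl$n_timepoints, 4)
})

test_that("ROI tables round-trip through CSV at full precision", {
  labs <- make_label_img()
  series <- list(labs, labs, labs, labs)
  tab <- roi_table(series, c(0, 6, 12, 24), list(a = 1L, b = 2L))
  expect_true(all(tab$normalized_volume[tab$time_months == 0] == 1))
  f <- tempfile(fileext = ".csv")
  export_table(tab, f)
  back <- read_roi_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  # slope recomputed from the file matches to 1e-9
  a0 <- tab[tab$roi == "a", ]
  b0 <- back[back$roi == "a", ]
  s1 <- normalize_and_trend(a0$volume_mm3, a0$time_months)$slope
  s2 <- normalize_and_trend(b0$volume_mm3, b0$time_months)$slope
  expect_equal(s1, s2, tolerance = 1e-9)
  # empty table writes a header-only file
  empty <- tab[0, ]
  f2 <- tempfile(fileext = ".csv")
  export_table(empty, f2)
  expect_equal(nrow(read_roi_table(f2)), 0)
  expect_equal(names(read_roi_table(f2)), names(tab))
})

test_that("plots build without error", {
  labs <- make_label_img()
  tab <- roi_table(list(labs, labs), c(0, 12), list(a = 1L))
  p <- plot_roi_trends(tab)
  expect_s3_class(p, "ggplot")
  tr <- normalize_and_trend(c(1, 0.99), c(0, 12))
  expect_s3_class(autoplot(tr), "ggplot")
})
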