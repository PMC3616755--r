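# Bias-field correction and histogram matching.

test_that("a spatially uniform image needs no correction", {
  img <- image_grid(array(100, c(24, 24, 24)))
  mask <- array(TRUE, c(24, 24, 24))
  cb <- correct_bias(img, mask, iters = 10)
  expect_lt(max(abs(exp(cb$bias$log_field) - 1)), 1e-3)
  expect_lt(max(abs(cb$corrected$voxels - 100)), 0.2)
})

test_that("a known sinusoidal gain field is recovered and contrast restored", {
  set.seed(7)
  d <- c(48, 48, 48)
  geom <- image_grid(array(0, d), origin = -(d - 1) / 2)
  pts <- grid_world_coords(geom)
  rho <- array(sqrt(rowSums(pts^2)), d)
  obj <- ifelse(rho < 15, 120, ifelse(rho < 20, 60, 0))
  x <- array(pts[, 1], d)
  field <- 1 + 0.3 * sin(2 * pi * (x + 24) / 48)
  img <- with_voxels(geom, pmax(0, obj * field + rnorm(prod(d), 0, 2)))
  mask <- obj > 0
  cb <- correct_bias(img, mask, iters = 80, control_spacing = 25)
  expect_gt(cor(exp(cb$bias$log_field[mask]), field[mask]), 0.95)
  # 20%-class coefficient of variation strictly decreases
  bright <- obj == 120
  cv <- function(v) sd(v) / mean(v)
  expect_lt(cv(cb$corrected$voxels[bright]), cv(img$voxels[bright]))
  # gain-normalized: masked mean preserved within 1%
  expect_lt(abs(mean(cb$corrected$voxels[mask]) / mean(img$voxels[mask]) - 1),
            0.01)
  # empty mask errors
  expect_error(correct_bias(img, array(FALSE, d)), "empty")
})

test_that("histogram matching maps quantiles monotonically onto the reference", {
  ph <- small_phantom()
  ref <- ph$series[[1]]
  # moving = reference is a fixed point (to relative machine-interpolation
  # precision)
  hm0 <- match_histogram(ref, ref)
  expect_lt(max(abs(hm0$voxels - ref$voxels)), 1e-6 * diff(range(ref$voxels)))
  # moving = 2 * reference maps back onto the reference
  mov <- with_voxels(ref, ref$voxels * 2)
  hm <- match_histogram(mov, ref)
  sup <- ref$voxels > 0
  expect_lt(quantile(abs(hm$voxels - ref$voxels)[sup], 0.95),
            diff(range(ref$voxels)) / 100)
  # KS statistic after matching is small
  mov2 <- ph$series[[2]]
  hm2 <- match_histogram(mov2, ref, mov2$voxels > 10, ref$voxels > 10)
  ks <- longbrain:::ks_statistic(hm2$voxels[mov2$voxels > 10],
                                 ref$voxels[ref$voxels > 10])
  expect_lt(ks, 0.05)
  # monotone map preserves within-mask rank order
  m <- mov2$voxels > 10
  r_before <- rank(mov2$voxels[m], ties.method = "first")
  r_after <- rank(hm2$voxels[m], ties.method = "first")
  expect_gt(cor(r_before, r_after, method = "spearman"), 0.9999)
  # degenerate: constant moving with non-constant reference
  cm <- with_voxels(ref, array(5, grid_dim(ref)))
  expect_error(match_histogram(cm, ref, array(TRUE, grid_dim(ref)),
                               ref$voxels > 0), "degenerate")
})

test_that("preprocessing is deterministic", {
  ph <- small_phantom()
  a <- preprocess_series(ph$series[1:2], bias_iters = 5)
  b <- preprocess_series(ph$series[1:2], bias_iters = 5)
  expect_identical(a$series[[2]]$voxels, b$series[[2]]$voxels)
})
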