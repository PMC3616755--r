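# Keypoints, matching, trajectory smoothing, TPS, composition, propagation.

test_that("keypoints avoid flat regions and respect the separation radius", {
  ph <- small_phantom()
  # constant image has no distinctive points
  flat <- with_voxels(ph$series[[1]], array(7, c(48, 48, 48)))
  expect_equal(nrow(select_keypoints(flat)$points), 0)
  kps <- select_keypoints(ph$atlas$template, c(60, 60), 2, r_min = 5)
  expect_gt(nrow(kps$points), 20)
  d <- as.matrix(dist(kps$points)); diag(d) <- Inf
  expect_gte(min(d), 5)
  # a single Gaussian blob: the best keypoint sits on its edge ring
  dd <- c(40, 40, 40)
  geom <- image_grid(array(0, dd), origin = -(dd - 1) / 2)
  pts <- grid_world_coords(geom)
  blob <- with_voxels(geom, array(100 * exp(-rowSums(pts^2) / (2 * 16)), dd))
  kb <- select_keypoints(blob, c(10, 10), 2, r_min = 3)
  top <- kb$points[which.max(kb$saliency), ]
  r_top <- sqrt(sum((top - (dd - 1) / 2)^2))
  expect_lt(abs(r_top - 4), 2.5)   # max gradient of a sigma-4 blob is at r = 4
})

test_that("matching recovers shifts and rejects uncorrelated targets", {
  ph <- small_phantom()
  tpl <- ph$atlas$template
  kps <- select_keypoints(tpl, c(60, 60), 2, r_min = 4)
  m0 <- match_keypoints(tpl, tpl, kps)
  expect_true(all(m0$mx == m0$x & m0$my == m0$y & m0$mz == m0$z))
  expect_true(all(m0$ncc > 0.999))
  # 3-voxel shift in y
  sh <- warp_affine(tpl, longbrain:::rigid_pull(c(0, -3, 0), c(0, 0, 0),
                                                c(0, 0, 0)), tpl)
  m3 <- match_keypoints(tpl, sh, kps)
  off <- as.matrix(m3[, c("mx", "my", "mz")]) - as.matrix(m3[, c("x", "y", "z")])
  expect_lte(max(abs(apply(off, 2, median) - c(0, 3, 0))), 1)
  # pure noise: nearly everything rejected
  set.seed(4)
  noise <- with_voxels(tpl, array(rnorm(48^3, 50, 20), c(48, 48, 48)))
  mN <- tryCatch(match_keypoints(tpl, noise, kps), error = function(e) NULL)
  kept <- if (is.null(mN)) 0 else nrow(mN)
  expect_lt(kept / nrow(kps$points), 0.1)
})

test_that("trajectory smoothing is a contraction that preserves linear trends", {
  tb <- array(0, c(2, 5, 3))
  tb[1, , 1] <- c(3, 3, 3, 3, 3)            # constant
  tb[2, , 1] <- c(0, 1, 2, 3, 4)            # linear
  out <- smooth_trajectories(tb, bandwidth = 1)
  expect_equal(out[1, , 1], rep(3, 5))
  expect_equal(out[2, 3, 1], 2, tolerance = 1e-9)  # symmetric interior point
  # an outlier spike contracts
  tb2 <- array(0, c(1, 5, 3))
  tb2[1, , 2] <- c(0, 0, 5, 0, 0)
  sm <- smooth_trajectories(tb2, bandwidth = 1)
  expect_lt(max(abs(sm[1, , 2])), 5)
  expect_lte(var(sm[1, , 2]), var(tb2[1, , 2]))
  # single timepoint: unchanged
  tb3 <- array(rnorm(6), c(2, 1, 3))
  expect_identical(smooth_trajectories(tb3, 1), tb3)
})

test_that("TPS interpolates exactly and reproduces affine maps", {
  set.seed(5)
  src <- matrix(runif(36, -20, 20), 12, 3)
  # zero displacement gives the zero field
  f0 <- longbrain:::tps_fit(src, src, 0)
  probe <- matrix(runif(15, -15, 15), 5, 3)
  expect_lt(max(abs(longbrain:::tps_eval_points(f0, probe))), 1e-9)
  # exact interpolation at the control points
  dst <- src + matrix(rnorm(36, 0, 2), 12, 3)
  fit <- longbrain:::tps_fit(src, dst, 0)
  expect_lt(max(abs(longbrain:::tps_eval_points(fit, src) - (dst - src))), 1e-6)
  # an exact affine map is reproduced everywhere
  A <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  b <- c(2, -1, 0.5)
  dstA <- src %*% t(A) + matrix(b, 12, 3, byrow = TRUE)
  fitA <- longbrain:::tps_fit(src, dstA, 0)
  pred <- probe + longbrain:::tps_eval_points(fitA, probe)
  expect_lt(max(abs(pred - (probe %*% t(A) + matrix(b, 5, 3, byrow = TRUE)))),
            1e-6)
})

test_that("field composition behaves algebraically", {
  d <- c(24, 24, 24)
  geom <- image_grid(array(0, d), origin = -(d - 1) / 2)
  zero <- longbrain:::zero_field(geom)
  tr <- function(v) def_field(array(v[1], d), array(v[2], d), array(v[3], d),
                              geom)
  f <- tr(c(1.5, -2, 0.5))
  # compose(zero, f) = f
  cf <- compose_fields(zero, f)
  expect_equal(cf$ux, f$ux, tolerance = 1e-9)
  # translations add (inside the field of view)
  g <- tr(c(1, 1, -0.5))
  fg <- compose_fields(f, g)
  core <- 6:18
  expect_lt(max(abs(fg$ux[core, core, core] - 2.5)), 1e-6)
  expect_lt(max(abs(fg$uy[core, core, core] + 1)), 1e-6)
  # a smooth field composed with its numerical inverse is near zero
  set.seed(6)
  u <- lapply(1:3, function(k) gauss_smooth(array(rnorm(prod(d)), d), 5) * 6)
  fs <- def_field(u[[1]], u[[2]], u[[3]], geom)
  inv <- invert_field(fs)
  res <- compose_fields(fs, inv)
  mag <- sqrt(res$ux^2 + res$uy^2 + res$uz^2)
  expect_lt(mean(mag[core, core, core]), 0.5)
  # associativity within tolerance on smooth fields
  h <- tr(c(0.5, 0.5, 0.5))
  lhs <- compose_fields(compose_fields(fs, f), h)
  rhs <- compose_fields(fs, compose_fields(f, h))
  expect_lt(max(abs(lhs$ux - rhs$ux)[core, core, core]), 0.1)
})

test_that("label propagation is exact for lattice translations and never invents labels", {
  ph <- small_phantom()
  labs <- with_voxels(ph$series[[1]], ph$truth[[1]]$roi_labels)
  d <- grid_dim(labs)
  zero <- longbrain:::zero_field(labs)
  p0 <- propagate_labels(labs, zero)
  expect_identical(p0$voxels, labs$voxels)
  # integer translation: index arithmetic oracle
  f2 <- def_field(array(2, d), array(0, d), array(0, d), labs)
  p2 <- propagate_labels(labs, f2)
  expect_identical(p2$voxels[1:(d[1] - 2), , ], labs$voxels[3:d[1], , ])
  expect_true(all(p2$voxels %in% labs$voxels))
})

test_that("groupwise registration of identical timepoints stays near zero", {
  ph <- small_phantom()
  tpl <- ph$atlas$template
  series <- list(tpl, tpl, tpl)
  gw <- groupwise_register(series, rounds = 2, n_per_level = c(60, 60))
  for (f in gw$fields_m2t) {
    mag <- sqrt(f$ux^2 + f$uy^2 + f$uz^2)
    expect_lt(mean(mag), 0.2)
  }
  expect_lt(max(abs(gw$mean$voxels - tpl$voxels)), 1)
  # mean-image sharpness does not degrade over rounds
  expect_true(all(diff(gw$diagnostics$sharpness) > -0.05 *
                    gw$diagnostics$sharpness[1]))
})
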