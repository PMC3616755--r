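# Coupled level-set segmentation: initialization, local statistics,
# thickness, evolution, tissue-map registration.

test_that("noiseless shells with exact priors initialize to the truth labels", {
  ph <- clean_phantom()
  b <- with_voxels(ph$series[[1]],
                   ph$series[[1]]$voxels * ph$truth[[1]]$brain_mask)
  tr <- ph$truth[[1]]$tissue
  exact_priors <- list(
    csf = with_voxels(b, array(as.numeric(tr == 1L), grid_dim(b))),
    gm = with_voxels(b, array(as.numeric(tr == 2L), grid_dim(b))),
    wm = with_voxels(b, array(as.numeric(tr == 3L), grid_dim(b))))
  st <- init_levelsets(b, exact_priors, mask = ph$truth[[1]]$brain_mask)
  lab <- state_labels(st)
  expect_gt(mean(lab == tr), 0.999)
  # truth-WM voxels away from the interface are inside the WM level set
  core_wm <- longbrain:::signed_distance(tr == 3L, c(1, 1, 1)) < -1
  expect_true(all(st$phi_wm[core_wm] < 0))
  # nesting by construction
  expect_true(all(st$phi_gm <= st$phi_wm + 1e-9))
  expect_true(all(st$phi_csf <= st$phi_gm + 1e-9))
})

test_that("flat priors reduce initialization to global EM thresholding", {
  ph <- clean_phantom()
  b <- with_voxels(ph$series[[1]],
                   ph$series[[1]]$voxels * ph$truth[[1]]$brain_mask)
  m <- ph$truth[[1]]$brain_mask
  flat <- lapply(ph$atlas$priors, function(p)
    with_voxels(p, array(1 / 3, grid_dim(p))))
  st <- init_levelsets(b, flat, mask = m)
  lab <- state_labels(st)
  # oracle: EM class of each intensity, ordered by mean
  em <- longbrain:::em_gauss3(b$voxels[m])
  o <- order(em$mean)
  lik <- vapply(1:3, function(k)
    dnorm(b$voxels[m], em$mean[o[k]], em$sd[o[k]]), numeric(sum(m)))
  oracle <- max.col(lik)
  expect_gt(mean(lab[m] == oracle), 0.98)
})

test_that("local statistics adapt to spatial intensity structure", {
  d <- c(32, 32, 32)
  geom <- image_grid(array(0, d), origin = -(d - 1) / 2)
  v <- array(100, d); v[17:32, , ] <- 120
  img <- with_voxels(geom, v)
  # one class covering everything, phi constructed by hand
  mask <- array(TRUE, d)
  st <- list(phi_wm = array(-5, d), phi_gm = array(-8, d),
             phi_csf = array(-10, d), mask = mask)
  class(st) <- "levelset_state"
  stats <- fit_local_stats(img, st, window_fwhm = 8)
  # constant region: local mean equals the constant away from the boundary
  expect_lt(max(abs(stats$wm$mean[4:8, , ] - 100)), 0.5)
  expect_lt(max(abs(stats$wm$mean[26:30, , ] - 120)), 0.5)
  # variance floored, strictly positive
  expect_true(all(stats$wm$var > 0))
  # very wide window approaches the global class mean
  stats_g <- fit_local_stats(img, st, window_fwhm = 500)
  expect_lt(max(abs(stats_g$wm$mean - mean(v))), 0.5)
})

test_that("thickness of concentric shells matches the analytic value", {
  ph <- clean_phantom()   # 3 mm GM shell (radii 14.5 / 11.5)
  st <- truth_state(ph)
  th <- estimate_thickness(st, ph$series[[1]]$spacing)
  expect_lt(abs(mean(th$thickness, na.rm = TRUE) - 3), 0.2)
  # rigid rotation changes the estimate by less than the interpolation budget
  tr <- ph$truth[[1]]
  pull <- longbrain:::rigid_pull(c(0, 0, 0), c(15, 0, 0), c(0, 0, 0))
  rot <- function(a) {
    w <- warp_affine(with_voxels(ph$series[[1]], a), pull, ph$series[[1]],
                     interp = "nearest")
    w$voxels > 0.5
  }
  st2 <- list(phi_wm = longbrain:::signed_distance(rot(tr$tissue == 3L), c(1, 1, 1)),
              phi_gm = longbrain:::signed_distance(rot(tr$tissue >= 2L), c(1, 1, 1)),
              phi_csf = longbrain:::signed_distance(rot(tr$tissue >= 1L), c(1, 1, 1)),
              mask = rot(tr$tissue > 0L))
  class(st2) <- "levelset_state"
  th2 <- estimate_thickness(st2, c(1, 1, 1))
  expect_lt(abs(mean(th2$thickness, na.rm = TRUE) -
                mean(th$thickness, na.rm = TRUE)), 0.2)
  # thin shell limit
  d <- c(32, 32, 32)
  geom <- image_grid(array(0, d), origin = -(d - 1) / 2)
  rho <- array(sqrt(rowSums(grid_world_coords(geom)^2)), d)
  stt <- list(phi_wm = longbrain:::signed_distance(rho < 10, c(1, 1, 1)),
              phi_gm = longbrain:::signed_distance(rho < 11, c(1, 1, 1)),
              phi_csf = longbrain:::signed_distance(rho < 13, c(1, 1, 1)),
              mask = rho < 13)
  class(stt) <- "levelset_state"
  tht <- estimate_thickness(stt, c(1, 1, 1))
  expect_lt(abs(mean(tht$thickness, na.rm = TRUE) - 1), 0.35)
})

test_that("constraint-free evolution matches the voxelwise likelihood oracle", {
  ph <- clean_phantom()
  b <- with_voxels(ph$series[[1]],
                   ph$series[[1]]$voxels * ph$truth[[1]]$brain_mask)
  w <- seg_weights(lambda_spatial_thick = 0, lambda_temporal_thick = 0,
                   mu_smooth = 0)
  sg <- segment_series_4d(list(b), ph$atlas$priors, w = w, init_iters = 30)
  lab <- sg$labels[[1]]$voxels
  # oracle: class of the nearest local mean (noiseless classes are exact)
  m <- ph$truth[[1]]$brain_mask
  expect_gt(mean(lab[m] == ph$truth[[1]]$tissue[m]), 0.995)
})

test_that("the temporal clamp contributes nothing when neighbours agree with the state", {
  ph <- clean_phantom()
  b <- with_voxels(ph$series[[1]],
                   ph$series[[1]]$voxels * ph$truth[[1]]$brain_mask)
  st <- truth_state(ph)
  th <- estimate_thickness(st, c(1, 1, 1))$full
  w <- seg_weights(lambda_data = 0, mu_smooth = 0, lambda_spatial_thick = 0)
  st1 <- evolve_segmentation(b, st, neighbor_thickness = list(th, th),
                             w = w, iters = 1)
  # excess = T - clamp(T, T, T) = 0 everywhere: no update beyond reinit
  expect_equal(state_labels(st1), state_labels(st))
})

test_that("an artificially thin gap is pushed back above the lower thickness bound", {
  # anatomy with a polar cap where the GM shell is only 0.4 mm thick
  d <- c(48, 48, 48)
  geom <- image_grid(array(0, d), origin = -(d - 1) / 2)
  pts <- grid_world_coords(geom)
  rho <- array(sqrt(rowSums(pts^2)), d)
  polar <- array(pts[, 3] / pmax(rho, 1e-9), d) > 0.8   # cap around +z
  gm_outer <- ifelse(polar, 11.9, 14.5)
  tissue <- array(0L, d)
  tissue[rho < 17] <- 1L
  tissue[rho < gm_outer] <- 2L
  tissue[rho < 11.5] <- 3L
  ints <- c(0, 40, 80, 120)
  img <- with_voxels(geom, gauss_smooth(array(ints[tissue + 1L], d), 0.8))
  img <- with_voxels(img, img$voxels * (tissue > 0L))
  priors <- lapply(1:3, function(cl) {
    p <- gauss_smooth(ifelse(tissue == cl, 1, 0), 1.5)
    with_voxels(geom, pmin(1, pmax(0, p)))
  })
  names(priors) <- c("csf", "gm", "wm")
  sg <- segment_series_4d(list(img), priors, init_iters = 60)
  th <- sg$thickness[[1]]
  cap_th <- th[polar & !is.na(th)]
  # thickness in the cap is lifted towards the biological lower bound
  expect_gt(mean(cap_th), 0.8)
  expect_gt(mean(cap_th), 0.4 + 0.2)
})

test_that("tissue-map registration recovers translations and inverts consistently", {
  ph <- small_phantom()
  seg <- with_voxels(ph$series[[1]], ph$truth[[1]]$tissue)
  # identical inputs: negligible field
  f0 <- register_tissue_maps(seg, seg)
  expect_lt(mean(sqrt(f0$ux^2 + f0$uy^2 + f0$uz^2)), 0.1)
  # known 3-voxel shift: the pull field carries the content back
  sh <- warp_affine(seg, longbrain:::rigid_pull(c(3, 0, 0), c(0, 0, 0),
                                                c(0, 0, 0)), seg,
                    interp = "nearest")
  f <- register_tissue_maps(seg, sh)
  inb <- ph$truth[[1]]$brain_mask
  expect_lt(abs(abs(mean(f$ux[inb])) - 3), 0.5)
  # inverse consistency
  fb <- register_tissue_maps(sh, seg)
  comp <- compose_fields(f, fb)
  expect_lt(mean(sqrt(comp$ux^2 + comp$uy^2 + comp$uz^2)[inb]), 0.5)
})

test_that("labels partition the mask, nest, and the energy trace decreases", {
  ph <- small_phantom()
  b <- with_voxels(ph$series[[1]],
                   ph$series[[1]]$voxels * ph$truth[[1]]$brain_mask)
  sg <- segment_series_4d(list(b), ph$atlas$priors, init_iters = 40)
  expect_equal(sum(sg$labels[[1]]$voxels > 0), sum(ph$truth[[1]]$brain_mask))
  st <- sg$states[[1]]
  expect_true(all(st$phi_gm <= st$phi_wm + 1e-9))
  expect_true(all(st$phi_csf <= st$phi_gm + 1e-9))
  e <- sg$energy[[1]]
  # non-increasing up to 1% jitter, except where the local statistics are
  # refreshed (every 10 iterations), which re-baselines the energy
  jumps <- diff(e) / max(abs(e))
  refresh <- seq_along(jumps) %% 10 == 0
  expect_true(all(jumps[!refresh] <= 0.01))
  # within the first fixed-statistics segment the flow strictly descends
  expect_lt(e[9], e[1])
})
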