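# Deformable-surface skull stripping: meshes, sphere estimates, evolution,
# cerebellum removal.

test_that("icosphere tessellation has the expected counts and radius", {
  m0 <- tessellate_sphere(list(cog = c(0, 0, 0), radius = 10), 0)
  expect_equal(nrow(m0$vertices), 12)
  expect_equal(nrow(m0$triangles), 20)
  m4 <- tessellate_sphere(list(cog = c(1, 2, 3), radius = 10), 4)
  expect_equal(nrow(m4$vertices), 10 * 4^4 + 2)
  r <- sqrt(rowSums(sweep(m4$vertices, 2, c(1, 2, 3))^2))
  expect_lt(max(abs(r - 10)), 1e-9)
  # Euler characteristic V - E + F = 2 (closed genus-0 surface)
  e <- unique(t(apply(rbind(m4$triangles[, 1:2], m4$triangles[, 2:3],
                            m4$triangles[, c(3, 1)]), 1, sort)))
  expect_equal(nrow(m4$vertices) - nrow(e) + nrow(m4$triangles), 2)
  expect_true(longbrain:::mesh_is_closed(m4))
})

test_that("mesh_to_mask matches analytic sphere volumes and nests", {
  geom <- image_grid(array(0, c(40, 40, 40)), origin = rep(-19.5, 3))
  m10 <- mesh_to_mask(tessellate_sphere(list(cog = c(0, 0, 0), radius = 10), 3),
                      geom)
  expect_lt(abs(sum(m10$voxels) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.02)
  m12 <- mesh_to_mask(tessellate_sphere(list(cog = c(0, 0, 0), radius = 12), 3),
                      geom)
  expect_true(all(m10$voxels <= m12$voxels))
  # mesh entirely outside the grid rasterizes to nothing
  far <- mesh_to_mask(tessellate_sphere(list(cog = c(500, 0, 0), radius = 5), 2),
                      geom)
  expect_equal(sum(far$voxels), 0)
})

test_that("sphere estimation recovers an analytic ball", {
  d <- c(48, 48, 48)
  geom <- image_grid(array(0, d), origin = -(d - 1) / 2)
  pts <- grid_world_coords(geom)
  ball <- array(sqrt(rowSums(sweep(pts, 2, c(2, -1, 3))^2)) < 20, d)
  img <- with_voxels(geom, array(100 * ball, d))
  # grid only covers +-23.5 so use a radius that fits
  ball <- array(sqrt(rowSums(sweep(pts, 2, c(2, -1, 3))^2)) < 18, d)
  img <- with_voxels(geom, array(100 * ball, d))
  s <- estimate_sphere(img, ball)
  expect_lt(max(abs(s$cog - c(2, -1, 3))), 0.5)
  expect_lt(abs(s$radius - 18), 0.5)
  # intensity scale invariance
  s2 <- estimate_sphere(with_voxels(img, img$voxels * 2), ball)
  expect_equal(s$cog, s2$cog)
  expect_equal(s$radius, s2$radius)
  # single-voxel mask: closed-form equivalent radius
  one <- array(FALSE, d); one[24, 24, 24] <- TRUE
  s1 <- estimate_sphere(img, one)
  expect_equal(s1$radius, (3 / (4 * pi))^(1 / 3), tolerance = 1e-9)
  expect_error(estimate_sphere(img, array(FALSE, d)), "empty")
})

test_that("common sphere averages estimates symmetrically", {
  a <- list(cog = c(0, 0, 0), radius = 18)
  b <- list(cog = c(2, 2, 2), radius = 22)
  expect_equal(common_sphere(list(a))$radius, 18)
  cs <- common_sphere(list(a, b))
  expect_equal(cs$radius, 20)
  expect_equal(cs$cog, c(1, 1, 1))
  expect_equal(common_sphere(list(b, a)), cs)
})

test_that("4D evolution with zero temporal weight reduces to independent 3D runs", {
  ph <- small_phantom()
  probs <- replicate(4, ph$atlas$brain_prob, simplify = FALSE)
  init <- replicate(4, tessellate_sphere(list(cog = c(0, 0, 0), radius = 15), 3),
                    simplify = FALSE)
  w0 <- force_weights(w_temporal = 0, iters = 20)
  m4 <- evolve_surfaces_4d(ph$series, probs, init, w0)
  m3 <- lapply(1:4, function(t)
    evolve_surface_3d(ph$series[[t]], probs[[t]], init[[t]], w0))
  for (t in 1:4)
    expect_identical(m4[[t]]$vertices, m3[[t]]$vertices)
  # topology is preserved
  expect_identical(m4[[1]]$triangles, init[[1]]$triangles)
})

test_that("identical timepoints give identical surfaces under any temporal weight", {
  ph <- clean_phantom()
  probs <- replicate(3, ph$atlas$brain_prob, simplify = FALSE)
  init <- replicate(3, tessellate_sphere(list(cog = c(0, 0, 0), radius = 15), 3),
                    simplify = FALSE)
  m <- evolve_surfaces_4d(ph$series[1:3], probs, init,
                          force_weights(w_temporal = 0.7, iters = 15))
  expect_identical(m[[1]]$vertices, m[[2]]$vertices)
  expect_identical(m[[1]]$vertices, m[[3]]$vertices)
})

test_that("pure smoothing shrinks a sphere monotonically", {
  ph <- small_phantom()
  prob <- ph$atlas$brain_prob
  mesh <- tessellate_sphere(list(cog = c(0, 0, 0), radius = 15), 3)
  w <- force_weights(w_smooth = 1, w_intensity = 0, w_prob = 0,
                     w_temporal = 0, iters = 25, step_size = 0.5)
  radii <- numeric(4)
  cur <- mesh
  for (k in 1:4) {
    cur <- evolve_surface_3d(ph$series[[1]], prob, cur, w)
    radii[k] <- mean(sqrt(rowSums(cur$vertices^2)))
  }
  expect_true(all(diff(c(15, radii)) < 0))
})

test_that("surfaces land on the phantom brain boundary", {
  ph <- small_phantom()
  probs <- lapply(ph$series, function(im)
    warp_probability_map(ph$atlas$brain_prob, im,
                         template = ph$atlas$template, iters = c(20, 10)))
  sph <- lapply(seq_along(ph$series), function(i)
    estimate_sphere(ph$series[[i]], probs[[i]]$voxels >= 0.5))
  cs <- common_sphere(sph)
  init <- replicate(4, tessellate_sphere(cs, 3), simplify = FALSE)
  meshes <- evolve_surfaces_4d(ph$series, probs, init,
                               force_weights(iters = 150))
  jac <- vapply(1:4, function(t) {
    m <- mesh_to_mask(meshes[[t]], ph$series[[t]])$voxels > 0.5
    sum(m & ph$truth[[t]]$brain_mask) / sum(m | ph$truth[[t]]$brain_mask)
  }, numeric(1))
  # the compressed 48^3 head (17 mm brain, 2 mm skull) is a smoke-level
  # check; accuracy at the standard geometry is asserted in the acceptance
  # suite
  expect_true(all(jac >= 0.80))
  expect_lt(max(jac) - min(jac), 0.02)
})

test_that("warped probability maps stay in [0,1] and track aligned targets", {
  ph <- small_phantom()
  wp <- warp_probability_map(ph$atlas$brain_prob, ph$series[[1]],
                             template = ph$atlas$template, iters = c(20, 10))
  expect_true(all(wp$voxels >= 0 & wp$voxels <= 1))
  # phantom timepoint is already aligned with the atlas: near-identity warp
  expect_lt(mean(abs(wp$voxels - ph$atlas$brain_prob$voxels)), 0.05)
})

test_that("cerebellum removal subtracts the warped mask and nothing else", {
  # a larger blob than the shared fixture so mask quantization does not
  # dominate the overlap
  ph <- generate_phantom(phantom_spec(
    shape = c(48, 48, 48),
    radii = c(scalp = 21, skull = 19, csf = 17, gm_outer = 14.5, wm = 11.5),
    gm_thinning_rate = 0, jitter_mm = 0, jitter_deg = 0,
    cereb_center = c(0, -8, -6), cereb_radius = 5, seed = 7))
  masks <- lapply(ph$truth, function(tr)
    with_voxels(ph$series[[1]], tr$brain_mask))
  brains <- lapply(seq_along(ph$series), function(t)
    with_voxels(ph$series[[t]], ph$series[[t]]$voxels * ph$truth[[t]]$brain_mask))
  # empty mask: unchanged
  empty <- with_voxels(ph$atlas$cereb_mask,
                       array(0, grid_dim(ph$atlas$cereb_mask)))
  same <- remove_cerebellum(brains[1:2], masks[1:2], ph$atlas$template, empty)
  expect_identical(same[[1]]$voxels, masks[[1]]$voxels)
  out <- remove_cerebellum(brains[1:2], masks[1:2], ph$atlas$template,
                           ph$atlas$cereb_mask)
  for (t in 1:2) {
    expect_true(all(out[[t]]$voxels <= masks[[t]]$voxels))
    removed <- masks[[t]]$voxels > 0.5 & out[[t]]$voxels < 0.5
    expect_gte(dice_of(removed, ph$truth[[t]]$cereb_mask), 0.85)
  }
})

test_that("groupwise affine recovers a known translation symmetrically", {
  ph <- small_phantom()
  tpl <- ph$atlas$template
  shifted <- warp_affine(tpl, longbrain:::rigid_pull(c(-4, 0, 0), c(0, 0, 0),
                                                     c(0, 0, 0)), tpl)
  ga <- groupwise_affine(list(tpl, shifted), iters = 2)
  t1 <- ga$affines[[1]][1, 4]
  t2 <- ga$affines[[2]][1, 4]
  # unbiased midpoint: the two recovered x-translations are -2/+2 mm
  expect_lt(abs(t1 + t2), 0.5)
  expect_lt(abs(abs(t1) - 2), 0.5)
  expect_lt(abs(abs(t2) - 2), 0.5)
  # identical inputs give identity transforms
  ga0 <- groupwise_affine(list(tpl, tpl), iters = 1)
  expect_lt(max(abs(ga0$affines[[1]] - diag(4))), 1e-3)
  # group mean beats the naive average against the truth anatomy placed at
  # the unbiased midpoint of the two poses
  naive <- (tpl$voxels + shifted$voxels) / 2
  truth_mid <- warp_affine(tpl, longbrain:::rigid_pull(c(-2, 0, 0), c(0, 0, 0),
                                                       c(0, 0, 0)), tpl)
  expect_gt(cor(as.vector(ga$mean$voxels), as.vector(truth_mid$voxels)),
            cor(as.vector(naive), as.vector(truth_mid$voxels)))
  expect_error(groupwise_affine(list(tpl)), "at least 2")
})
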