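# Synthetic phantom generator: determinism, analytic truth, invariants.

test_that("phantoms are bit-reproducible from the seed", {
  sp <- phantom_spec(shape = c(32, 32, 32),
                     radii = c(scalp = 14, skull = 12.5, csf = 11,
                               gm_outer = 9, wm = 7),
                     cereb_center = c(0, -5, -4), cereb_radius = 2, seed = 9)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$series[[3]]$voxels, b$series[[3]]$voxels)
  expect_identical(a$truth[[2]]$tissue, b$truth[[2]]$tissue)
})

test_that("a fully static specification yields identical anatomy, differing noise", {
  sp <- phantom_spec(shape = c(32, 32, 32),
                     radii = c(scalp = 14, skull = 12.5, csf = 11,
                               gm_outer = 9, wm = 7),
                     gm_thinning_rate = 0, jitter_mm = 0, jitter_deg = 0,
                     cereb_center = c(0, -5, -4), cereb_radius = 2, seed = 9)
  ph <- generate_phantom(sp)
  expect_identical(ph$truth[[1]]$tissue, ph$truth[[4]]$tissue)
  expect_false(identical(ph$series[[1]]$voxels, ph$series[[2]]$voxels))
  # with zero noise as well, the volumes are identical
  sp0 <- sp; sp0$noise_sd <- 0
  ph0 <- generate_phantom(sp0)
  expect_identical(ph0$series[[1]]$voxels, ph0$series[[3]]$voxels)
})

test_that("truth volumes and thickness match the analytic geometry", {
  ph <- small_phantom()   # wm radius 11.5 mm at 1 mm spacing
  v_wm <- sum(ph$truth[[1]]$tissue == 3L)
  expect_lt(abs(v_wm - 4 / 3 * pi * 11.5^3) / (4 / 3 * pi * 11.5^3), 0.03)
  th <- ph$truth[[1]]$thickness
  expect_lt(abs(mean(th, na.rm = TRUE) - 3), 0.2)
  # labels nest with masks
  expect_true(all((ph$truth[[1]]$tissue > 0) == ph$truth[[1]]$brain_mask))
  expect_true(all(ph$truth[[1]]$roi_labels[!ph$truth[[1]]$brain_mask] == 0))
  expect_true(all(ph$truth[[1]]$cereb_mask <= ph$truth[[1]]$brain_mask))
})

test_that("invalid specifications are rejected", {
  expect_error(phantom_spec(radii = c(scalp = 40, skull = 44, csf = 36,
                                      gm_outer = 33, wm = 30)),
               "decreasing")
  expect_error(phantom_spec(gm_thinning_rate = 0.2), "thickness")
})
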