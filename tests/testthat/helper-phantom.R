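# Shared fixtures: small phantoms built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, .fixture_env)) assign(key, fn(), .fixture_env)
  get(key, .fixture_env)
}

# 48^3 static phantom, no jitter/thinning: the workhorse for unit tests.
small_phantom <- function() memo("small_phantom", function() {
  generate_phantom(phantom_spec(
    shape = c(48, 48, 48),
    radii = c(scalp = 21, skull = 19, csf = 17, gm_outer = 14.5, wm = 11.5),
    gm_thinning_rate = 0, jitter_mm = 0, jitter_deg = 0,
    cereb_center = c(0, -9, -7), cereb_radius = 3, seed = 7))
})

# Noise/bias-free variant of the same anatomy (exact class intensities).
clean_phantom <- function() memo("clean_phantom", function() {
  generate_phantom(phantom_spec(
    shape = c(48, 48, 48),
    radii = c(scalp = 21, skull = 19, csf = 17, gm_outer = 14.5, wm = 11.5),
    gm_thinning_rate = 0, jitter_mm = 0, jitter_deg = 0, noise_sd = 0,
    bias_amplitude = 0, texture_amplitude = c(wm = 0, gm = 0, csf = 0),
    smooth_mm = 0.01,
    cereb_center = c(0, -9, -7), cereb_radius = 3, seed = 7))
})

# Truth-initialized level-set state for a phantom timepoint.
truth_state <- function(ph, t = 1) {
  tr <- ph$truth[[t]]
  sp <- ph$series[[t]]$spacing
  st <- list(phi_wm = longbrain:::signed_distance(tr$tissue == 3L, sp),
             phi_gm = longbrain:::signed_distance(tr$tissue >= 2L, sp),
             phi_csf = longbrain:::signed_distance(tr$tissue >= 1L, sp),
             mask = tr$tissue > 0L)
  class(st) <- "levelset_state"
  st
}

dice_of <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
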