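# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# rate set whose nucleus/cytoplasm eigenvalues reproduce the printed
# validation values (-0.6342, -0.01577 1/s)
validation_rates <- function() {
  rate_constants(k1 = 0.016194, k_m1 = 0.016194, k2 = 0.005, k3 = 0.617582)
}

# noise-free basic scene, shortened for unit tests
basic_clean_sim <- function() fixture("basic_clean_sim", function() {
  render_stack(flip_scene("basic", n_frames = 120,
                          noise = list(model = "none")))
})

basic_clean_model <- function() fixture("basic_clean_model", function() {
  dmd(basic_clean_sim()$stack, rank = 3)
})

neighbor_clean_sim <- function() fixture("neighbor_clean_sim", function() {
  render_stack(flip_scene("with_neighbor", n_frames = 120,
                          noise = list(model = "none")))
})

neighbor_clean_model <- function() fixture("neighbor_clean_model", function() {
  dmd(neighbor_clean_sim()$stack, rank = 4)
})

# noisy basic scene at the default 2% Gaussian level
basic_noisy_sim <- function() fixture("basic_noisy_sim", function() {
  render_stack(flip_scene("basic", n_frames = 120, seed = 11))
})

basic_noisy_model <- function() fixture("basic_noisy_model", function() {
  dmd(basic_noisy_sim()$stack, rank = 3)
})

# mask of pixels fully covered by an aggregate disk (no anti-aliased rim),
# where the renderer paints the exact aggregate trajectory
aggregate_core_mask <- function(scene) {
  covs <- lapply(seq_len(nrow(scene$aggregates)), function(a)
    disk_coverage(scene$image_shape, scene$aggregates$x[a],
                  scene$aggregates$y[a], scene$aggregates$radius[a]))
  Reduce(`|`, lapply(covs, function(cv) cv >= 1))
}

# cytoplasm pixels untouched by any aggregate rim
cytoplasm_pure_mask <- function(scene) {
  covs <- lapply(seq_len(nrow(scene$aggregates)), function(a)
    disk_coverage(scene$image_shape, scene$aggregates$x[a],
                  scene$aggregates$y[a], scene$aggregates$radius[a]))
  scene$cell_mask & !scene$nucleus_mask & !Reduce(`|`, lapply(covs, `>`, 0))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
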