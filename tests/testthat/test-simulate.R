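test_that("Brownian step width follows sqrt(2 D dt)/pixel_size", {
  expect_equal(brownian_sigma_px(0, 1, 0.125), 0)
  expect_equal(brownian_sigma_px(0.004, 1, 0.125), sqrt(0.008) / 0.125)
  expect_equal(round(brownian_sigma_px(0.004, 1, 0.125), 5), 0.71554)
  expect_equal(brownian_sigma_px(0.0078125, 1, 0.125), 1)
  expect_error(brownian_sigma_px(0.004, 1, 0), "pixel_size")
  expect_error(brownian_sigma_px(-1, 1, 0.125), ">= 0")
})

test_that("Box-Muller deviates are standard normal", {
  set.seed(5)
  z <- box_muller(20000)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(sd(z) - 1), 0.02)
})

test_that("scene presets encode the documented study conditions", {
  sc <- flip_scene("basic")
  expect_equal(sc$image_shape, c(128L, 128L))
  expect_equal(sc$pixel_size, 0.125)
  expect_equal(sc$n_frames, 300L)
  expect_equal(sc$dt, 1)
  expect_equal(nrow(sc$aggregates), 3L)
  expect_equal(sort(sc$aggregates$radius), c(2, 4, 6))
  expect_null(sc$neighbor_cell_mask)
  expect_equal(sc$motion, list(D = 0, v = 0))
  expect_false(any(sc$aggregates$mobile))

  scm <- flip_scene("mobile_aggregate")
  expect_equal(scm$motion$D, 0.004)
  expect_true(scm$aggregates$mobile[which.min(scm$aggregates$radius)])

  scf <- flip_scene("flow_aggregate")
  expect_equal(scf$motion$v, 0.00625)
  expect_equal(scf$motion$D, 0)

  scn <- flip_scene("with_neighbor")
  expect_false(is.null(scn$neighbor_cell_mask))
  expect_false(any(scn$neighbor_cell_mask & scn$cell_mask))

  expect_error(flip_scene("nope"), "basic.*with_neighbor")
})

test_that("scene masks are nested and disjoint", {
  for (p in c("basic", "with_neighbor")) {
    sc <- flip_scene(p)
    expect_true(all(sc$cell_mask[sc$nucleus_mask]))
    cyto <- sc$cell_mask & !sc$nucleus_mask
    expect_true(all(cyto[sc$bleach_roi_mask]))
    # aggregate disks live in the cytoplasm
    for (a in seq_len(nrow(sc$aggregates))) {
      cov <- disk_coverage(sc$image_shape, sc$aggregates$x[a],
                           sc$aggregates$y[a], sc$aggregates$radius[a])
      expect_true(all(cyto[cov > 0]))
    }
  }
})

test_that("rendered intensities equal the analytic compartment kinetics", {
  sim <- basic_clean_sim()
  sc <- sim$scene
  traj <- solve_compartments(sc$rates, sc$init, (0:119) * sc$dt)
  # frame 1 equals the initial state on each pure mask
  f1 <- get_frame(sim$stack, 1)
  expect_true(all(f1[sc$nucleus_mask] == sc$init["N"]))
  expect_true(all(f1[cytoplasm_pure_mask(sc)] == sc$init["C"]))
  expect_true(all(f1[!sc$cell_mask] == 0))
  # aggregate-core pixel trace is A0 exp(-k2 t)
  core <- aggregate_core_mask(sc)
  px <- which(core, arr.ind = TRUE)[1, ]
  expect_lt(max(abs(sim$stack$data[px[1], px[2], ] -
                    sc$init["A"] * exp(-sc$rates$k2 * (0:119)))), 1e-12)
  # mask means match the trajectories exactly (noise-free)
  for (n in c(1, 40, 120)) {
    fr <- get_frame(sim$stack, n)
    expect_equal(mean(fr[sc$nucleus_mask]), unname(traj[n, "N"]))
    expect_equal(mean(fr[cytoplasm_pure_mask(sc)]), unname(traj[n, "C"]))
    expect_equal(mean(fr[core]), unname(traj[n, "A"]))
  }
})

test_that("noise-free static stacks have the rank of their exponential content", {
  X <- stack_to_snapshots(basic_clean_sim()$stack)$X
  d <- svd(X, nu = 0, nv = 0)$d
  expect_lt(d[4] / d[1], 1e-8)   # three exponentials: rank 3
  Xn <- stack_to_snapshots(neighbor_clean_sim()$stack)$X
  dn <- svd(Xn, nu = 0, nv = 0)$d
  expect_lt(dn[5] / dn[1], 1e-8) # + constant neighbor: rank 4
  expect_gt(dn[4] / dn[1], 1e-8)
})

test_that("identical scenes render bit-identical stacks", {
  s1 <- render_stack(flip_scene("basic", n_frames = 10, seed = 99))
  s2 <- render_stack(flip_scene("basic", n_frames = 10, seed = 99))
  expect_identical(s1$stack$data, s2$stack$data)
  s3 <- render_stack(flip_scene("basic", n_frames = 10, seed = 100))
  expect_false(identical(s3$stack$data, s1$stack$data))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(3)
  set.seed(123)
  invisible(render_stack(flip_scene("basic", n_frames = 5, seed = 77)))
  expect_identical(runif(3), a)
})

test_that("flow subtracts five percent of a pixel per frame along x", {
  sim <- render_stack(flip_scene("flow_aggregate", n_frames = 30,
                                 noise = list(model = "none")))
  small <- which.min(sim$scene$aggregates$radius)
  tr <- sim$centers[sim$centers$aggregate == small, ]
  x0 <- sim$scene$aggregates$x[small]
  expect_equal(tr$x[21], x0 - 1.0)         # 20 frames x 0.05 px
  expect_equal(unique(tr$y), sim$scene$aggregates$y[small])
})

test_that("mobile aggregates are clipped at the cell boundary with a warning", {
  sc <- flip_scene("mobile_aggregate", n_frames = 40,
                   noise = list(model = "none"), seed = 4)
  # park the mobile aggregate against the membrane and shake it hard
  sc$aggregates$x[1] <- 106
  sc$aggregates$y[1] <- 64
  sc$motion$D <- 0.5
  expect_warning(sim <- render_stack(sc), "clipped")
  for (n in seq_len(40)) {
    cov <- disk_coverage(sc$image_shape,
                         sim$centers$x[sim$centers$aggregate == 1][n],
                         sim$centers$y[sim$centers$aggregate == 1][n],
                         sc$aggregates$radius[1])
    expect_false(any(cov[!sc$cell_mask] > 0))
  }
})

test_that("noise models behave as declared", {
  clean <- render_stack(flip_scene("basic", n_frames = 8,
                                   noise = list(model = "none")))
  g <- render_stack(flip_scene("basic", n_frames = 8,
                               noise = list(model = "gaussian", sigma = 0.05),
                               seed = 2))
  resid <- g$stack$data - g$clean$data
  expect_equal(sd(resid), 0.05 * max(g$clean$data[, , 1]), tolerance = 0.02)
  expect_identical(g$clean$data, clean$stack$data)
  p <- render_stack(flip_scene("basic", n_frames = 8,
                               noise = list(model = "poisson",
                                            photon_scale = 200), seed = 2))
  expect_true(all(p$stack$data >= 0))
  expect_false(identical(p$stack$data, p$clean$data))
  expect_error(flip_scene("basic", noise = list(model = "gaussian",
                                                sigma = -1)), "sigma")
})
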