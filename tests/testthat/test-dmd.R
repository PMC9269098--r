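decay_stack <- function(h = 4, w = 5, k = 12, lam = 0.9, dt = 1) {
  base <- matrix(as.numeric(seq_len(h * w)), h, w)
  flip_stack(vapply(seq_len(k), function(n) base * lam^(n - 1),
                    base) |> array(c(h, w, k)), dt)
}

test_that("snapshot matrices satisfy the shift property and round-trip", {
  st <- decay_stack()
  sp <- stack_to_snapshots(st)
  expect_equal(dim(sp$X), c(20, 11))
  expect_identical(sp$X[, 2:11], sp$X_prime[, 1:10])
  # column 1 of X is frame 1 flattened row-major
  expect_identical(sp$X[, 1], as.vector(t(get_frame(st, 1))))
  # un-reshape(reshape(stack)) is bit-identical
  full <- cbind(sp$X, sp$X_prime[, ncol(sp$X_prime)])
  back <- snapshots_to_stack(full, sp$image_shape, st$dt)
  expect_identical(back$data, st$data)
  expect_error(stack_to_snapshots(flip_stack(array(1, c(2, 2, 2)), 1)),
               "at least 3 frames")
})

test_that("uniform exponential decay yields a single exact eigenvalue", {
  st <- decay_stack(lam = 0.9)
  m <- dmd(st, rank = 1)
  expect_equal(Re(m$lam), 0.9, tolerance = 1e-12)
  expect_equal(Im(m$lam), 0)
  m_opt <- dmd(st, rank = "optimal")
  expect_equal(m_opt$rank, 1L)
  expect_lt(Mod(m_opt$lam - 0.9), 1e-9)
  # one extrapolation step past the end is lambda * last frame
  pred <- dmd_predict(m, 1)
  expect_equal(pred$data[, , 1], 0.9 * get_frame(st, 12), tolerance = 1e-9)
})

test_that("a static stack is identity dynamics", {
  st <- flip_stack(array(rep(matrix(1:6, 2, 3), 10), c(2, 3, 10)), 2)
  m <- dmd(st, rank = 1)
  expect_equal(Re(m$lam), 1, tolerance = 1e-12)
  expect_equal(Mod(m$omega), 0, tolerance = 1e-12)
  pred <- dmd_predict(m, 3)
  expect_equal(pred$data[, , 3], get_frame(st, 1), tolerance = 1e-9)
})

test_that("noise-free simulation recovers the generating eigenvalues", {
  m <- basic_clean_model()
  ana <- sort(unname(model_eigenvalues(validation_rates())))
  expect_lt(max(abs(sort(Re(m$omega)) - ana)), 1e-6)
  expect_lt(max(abs(Im(m$omega))), 1e-9)
  # projected modes give the same spectrum
  mp <- dmd(basic_clean_sim()$stack, rank = 3, mode_type = "projected")
  expect_lt(max(abs(sort(Re(mp$omega)) - ana)), 1e-6)
})

test_that("oracle equivalence holds across random kinetic parameter sets", {
  set.seed(31)
  for (i in 1:4) {
    r <- rate_constants(k1 = runif(1, 0.005, 0.05), k_m1 = runif(1, 0.005, 0.05),
                        k2 = runif(1, 0.001, 0.01), k3 = runif(1, 0.1, 0.8))
    sim <- render_stack(flip_scene("basic", n_frames = 80, rates = r,
                                   noise = list(model = "none")))
    m <- dmd(sim$stack, rank = 3)
    expect_lt(max(abs(sort(Re(m$omega)) -
                      sort(unname(model_eigenvalues(r))))), 1e-6)
  }
})

test_that("eigenvalue rescaling uses the principal-branch log over dt", {
  expect_equal(rescale_eigenvalues(1, 5), 0 + 0i)
  expect_equal(Re(rescale_eigenvalues(exp(-0.015), 3)), -0.005)
  expect_equal(round(Re(rescale_eigenvalues(0.996257, 1)), 5), -0.00375)
  om <- rescale_eigenvalues(complex(modulus = 0.9, argument = 2), 1)
  expect_true(Im(om) > -pi && Im(om) <= pi)
  expect_error(rescale_eigenvalues(0, 1), "zero eigenvalue")
  expect_error(rescale_eigenvalues(0.9, 0), "dt")
  expect_warning(rescale_eigenvalues(-0.5, 1), "negative real axis")
})

test_that("optimal hard threshold separates signal from noise", {
  # pure rank-1 spectrum
  expect_equal(optimal_rank(c(10, rep(1e-14, 9)), 100, 10), 1L)
  expect_error(optimal_rank(numeric(0), 10, 10), "empty")
  # i.i.d. Gaussian matrices are (almost) never assigned real structure
  set.seed(17)
  ranks <- vapply(1:100, function(i) {
    d <- svd(matrix(rnorm(400 * 200), 400, 200), nu = 0, nv = 0)$d
    optimal_rank(d, 400, 200)
  }, integer(1))
  expect_gte(mean(ranks <= 2), 0.95)
})

test_that("reconstruction is exact at the signal rank and matches Eq. forms", {
  sim <- basic_clean_sim(); m <- basic_clean_model()
  rec <- dmd_reconstruct(m)
  mx <- max(sim$stack$data)
  expect_lt(max(abs(rec$data - sim$stack$data)) / mx, 1e-8)
  # frame 1 is the least-squares mode expansion of the first snapshot
  f1 <- Re(m$Phi %*% m$b)
  expect_lt(max(abs(as.vector(t(get_frame(rec, 1))) - f1)), 1e-10)
  # discrete powers and continuous exponentials agree
  rc <- dmd_reconstruct(m, frames = c(1, 25, 60, 120), continuous = TRUE)
  rd <- dmd_reconstruct(m, frames = c(1, 25, 60, 120))
  expect_lt(max(abs(rc$data - rd$data)), 1e-10 * mx)
})

test_that("prediction extrapolates noise-free kinetics", {
  long <- render_stack(flip_scene("basic", n_frames = 150,
                                  noise = list(model = "none")))
  first100 <- flip_stack(long$stack$data[, , 1:100], long$stack$dt)
  m <- dmd(first100, rank = 3)
  pred <- dmd_predict(m, 50)
  truth <- get_frame(long$stack, 150)
  expect_lt(max(abs(pred$data[, , 50] - truth)) / max(truth), 1e-6)
  expect_error(dmd_predict(m, 0), "n_future")
  # growing modes trigger a warning
  mg <- m; mg$lam[1] <- 1.01 + 0i
  expect_warning(dmd_predict(mg, 1), "growing")
})

test_that("spectrum is invariant under spatial pixel permutation", {
  sim <- basic_clean_sim()
  sp <- stack_to_snapshots(sim$stack)
  set.seed(8)
  perm <- sample(nrow(sp$X))
  full <- cbind(sp$X, sp$X_prime[, ncol(sp$X_prime)])
  permuted <- snapshots_to_stack(full[perm, ], sp$image_shape, sp$dt)
  m1 <- basic_clean_model(); m2 <- dmd(permuted, rank = 3)
  expect_lt(max(Mod(sort(m1$lam) - sort(m2$lam))), 1e-9)
})

test_that("real stacks give conjugate-closed spectra and real reconstructions", {
  sim <- render_stack(flip_scene("flow_aggregate", n_frames = 60,
                                 noise = list(model = "none")))
  m <- dmd(sim$stack, rank = 6)
  # spectrum closed under conjugation
  expect_lt(max(Mod(sort(m$lam) - sort(Conj(m$lam)))), 1e-9)
  # complex expansion has negligible imaginary part at sampled frames
  mx <- max(sim$stack$data)
  for (n in c(1, 30, 60)) {
    v <- m$Phi %*% (m$lam^(n - 1) * m$b)
    expect_lt(max(abs(Im(v))), 1e-8 * mx)
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  zero <- flip_stack(array(0, c(4, 4, 6)), 1)
  expect_error(dmd(zero), "all-zero")
  st <- decay_stack(k = 6)
  expect_error(dmd(st, rank = 10), "1..k-1")
  expect_error(dmd(st, rank = 3), "lower rank")  # rank-1 data
})
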