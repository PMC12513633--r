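test_that("diffusion matrices match their printed forms", {
  p <- circadian_params(diffusion_form = "const", sigma0 = 0.1, c_corr = 0.2)
  expect_equal(circadian_diffusion_matrix(p, 0.5, -1),
               matrix(c(0.1, 0.02, 0.02, 0.1), 2, byrow = TRUE))
  p <- circadian_params(diffusion_form = "langevin", sigma0 = 0.3, c_corr = 0.5)
  expect_equal(circadian_diffusion_matrix(p, 0, 0), matrix(0, 2, 2))
  expect_equal(circadian_diffusion_matrix(p, -2, 1),
               0.3 * matrix(c(2, 0.5, 1, 1), 2, byrow = TRUE))
  # linear form keeps the signed diagonal and absolute off-diagonal entries
  p <- circadian_params(diffusion_form = "linear", sigma0 = 1, c_corr = 1)
  expect_equal(circadian_diffusion_matrix(p, -1, 1),
               matrix(c(-1, 1, 1, 1), 2, byrow = TRUE))
})

test_that("noise-free simulation matches the damped rotation closed form", {
  p <- circadian_params(sigma0 = 0)
  e <- circadian_simulate(p, n_traj = 1, times = seq(0, 1, by = 0.002), seed = 3)
  xt <- -exp(-0.19 * e$times) * sin(0.21 * e$times)
  yt <- exp(-0.19 * e$times) * cos(0.21 * e$times)
  expect_lt(max(abs(e$values[1, , 1] - xt)), 2e-4)
  expect_lt(max(abs(e$values[1, , 2] - yt)), 2e-4)
})

test_that("one-step covariance increments match the diffusion matrix", {
  # freeze the state, take one EM step many times, compare E[dX dX^T]/dt
  for (form in c("const", "langevin", "linear")) {
    p <- circadian_params(diffusion_form = form, sigma0 = 0.25, c_corr = 0.6)
    f <- circadian_field(p)
    x <- c(-0.4, 0.8); dt <- 0.01; n <- 4e4
    e <- em_integrate(f, x, c(0.25, 0.6), c(0, dt), n, seed = 17)
    dX <- e$values[, 2, ] - rep(x, each = n)
    emp <- crossprod(dX) / n / dt
    xi <- circadian_diffusion_matrix(p, x[1], x[2])
    expect_lt(max(abs(emp - xi %*% t(xi))), 0.012)
  }
})

test_that("stationary covariance of the const form solves the Lyapunov equation", {
  p <- circadian_params(diffusion_form = "const", sigma0 = 0.2, c_corr = 0.4)
  A <- matrix(c(-0.19, -0.21, 0.21, -0.19), 2, byrow = TRUE)
  xi <- circadian_diffusion_matrix(p, 0, 0); D <- xi %*% t(xi)
  # solve A S + S A^T + D = 0 via vectorization
  K <- kronecker(diag(2), A) + kronecker(A, diag(2))
  S <- matrix(solve(K, -as.vector(D)), 2)
  e <- circadian_simulate(p, times = seq(0, 40, by = 0.02), n_traj = 1500, seed = 23)
  tail_idx <- seq(1500, 2001, by = 50)   # well past the relaxation time
  emp <- crossprod(matrix(aperm(e$values[, tail_idx, ], c(1, 2, 3)), ncol = 2)) /
    (1500 * length(tail_idx))
  expect_lt(max(abs(emp - S)) / max(abs(S)), 0.12)
})

test_that("the reference grid dataset realizes the study conditions", {
  g <- circadian_grid_dataset("const", seed = 2, n_traj = 4)
  expect_equal(length(g$entries), 25L)
  oms <- do.call(rbind, lapply(g$entries, `[[`, "omega"))
  expect_setequal(round(unique(oms[, 1]), 10), c(0.10, 0.15, 0.20, 0.25, 0.30))
  expect_setequal(round(unique(oms[, 2]), 10), c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(sum(vapply(g$entries, function(e) dim(e$ensemble$values)[1], 0L)), 100L)
  e <- g$entries[[1]]$ensemble
  expect_equal(range(e$times), c(0, 1))
  expect_equal(unname(e$values[1, 1, ]), c(0, 1))
  g2 <- circadian_grid_dataset("const", seed = 3, n_traj = 4)
  expect_equal(lapply(g$entries, `[[`, "omega"), lapply(g2$entries, `[[`, "omega"))
  expect_false(identical(g$entries[[1]]$ensemble$values, g2$entries[[1]]$ensemble$values))
})

test_that("extrinsic-noise dataset covers the k grid with the stated diffusion", {
  g <- circadian_ext_dataset(sigma0 = 0.1, sigma1 = 0.1, seed = 4, n_traj = 2)
  expect_equal(length(g$entries), 25L)
  oms <- do.call(rbind, lapply(g$entries, `[[`, "omega"))
  expect_setequal(unique(oms[, 1]), c(-1, -0.5, 0, 0.5, 1))
  # (k1,k2) = (1,1): effective diffusion coefficients 0.2 x, 0.2 y
  p <- circadian_params(diffusion_form = "eq_ext", sigma0 = 0.1, sigma1 = 0.1,
                        k1 = 1, k2 = 1)
  f <- circadian_field(p)
  S <- f$diffusion(matrix(c(2, -3), 1), c(1, 1))
  expect_equal(as.vector(S), c(0.2 * 2, 0, 0, 0.2 * -3))
  # sigma1 = 0 makes the diffusion k-independent
  p0 <- circadian_params(diffusion_form = "eq_ext", sigma0 = 0.1, sigma1 = 0,
                         k1 = 1, k2 = -1)
  S0 <- circadian_field(p0)$diffusion(matrix(c(1, 1), 1), c(1, -1))
  expect_equal(as.vector(S0), c(0.1, 0, 0, 0.1))
})
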