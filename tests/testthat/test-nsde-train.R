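# Training-level behavior on small fixtures. Heavier end-to-end accuracy
# checks live in test-acceptance.R.

test_that("training reduces the loss and is reproducible for a fixed seed", {
  obs <- ou_ensemble(n_traj = 60, seed = 4, times = seq(0, 1, by = 0.05))
  g <- param_grid(list(obs))
  cfg <- run_config(seed = 2, imax = 40, width = 8, depth = 1, lr = 1e-2)
  m1 <- end_nsde(g, cfg, noise_dim = 1)
  m2 <- end_nsde(g, cfg, noise_dim = 1)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(coef(m1)$drift$W, coef(m2)$drift$W)
  m3 <- end_nsde(g, run_config(seed = 3, imax = 40, width = 8, depth = 1, lr = 1e-2),
                 noise_dim = 1)
  expect_false(identical(m1$loss_history, m3$loss_history))
})

test_that("self-consistent data keeps the loss from increasing", {
  # data generated by an SDE the model can represent exactly from epoch 1:
  # a field with zero drift and constant diffusion
  f <- sde_field(function(X, w) X * 0, function(X, w) matrix(0.2, nrow(X), 1), 1, 0, 1)
  obs <- em_integrate(f, 0, numeric(0), seq(0, 1, by = 0.05), 80, seed = 5)
  g <- param_grid(list(obs))
  m <- end_nsde(g, run_config(seed = 1, imax = 50, width = 8, depth = 1, lr = 5e-3),
                noise_dim = 1)
  expect_lte(tail(m$loss_history, 1), m$loss_history[1])
})

test_that("prediction honours seeds, omegas and initial-state pools", {
  g <- circadian_grid_dataset("const", seed = 11, n_traj = 10,
                              sigma0_values = c(0.1, 0.3), c_values = c(0.2, 1.0))
  m <- end_nsde(g, run_config(seed = 1, imax = 15, width = 8, depth = 1))
  om <- g$entries[[1]]$omega
  p1 <- predict(m, omega = om, n_traj = 7, seed = 3)
  p2 <- predict(m, omega = om, n_traj = 7, seed = 3)
  p3 <- predict(m, omega = om, n_traj = 7, seed = 4)
  expect_identical(p1$values, p2$values)
  expect_false(identical(p1$values, p3$values))
  expect_true(attr(p1, "seen_in_training"))
  expect_equal(n_traj(p1), 7L)
  # unseen omega: still predicts, tagged accordingly
  pu <- predict(m, omega = c(0.2, 0.6), n_traj = 3, seed = 1)
  expect_false(attr(pu, "seen_in_training"))
  expect_equal(dim(pu$values), c(3L, length(m$times), 2L))
  expect_error(predict(m, omega = om, x0 = matrix(1, 3, 5)), "mismatch")
  # simulate() is the nsim-flavoured alias
  s <- simulate(m, nsim = 4, seed = 3, omega = om)
  expect_equal(n_traj(s), 4L)
})

test_that("the latent mask keeps masked-out components from entering the loss", {
  # two-component data where component 2 is pure noise: masking it out must
  # change the recorded loss
  set.seed(6)
  v <- array(rnorm(20 * 6 * 2), c(20, 6, 2))
  v[, , 1] <- 0.1 * v[, , 1]
  e <- trajectory_ensemble(seq(0, 1, length.out = 6), v, omega = 0.5)
  g <- param_grid(list(e))
  m_all <- end_nsde(g, run_config(seed = 1, imax = 2, width = 4, depth = 1))
  m_masked <- end_nsde(g, run_config(seed = 1, imax = 2, width = 4, depth = 1), mask = 1L)
  expect_gt(m_all$loss_history[1], m_masked$loss_history[1])
})

test_that("print, summary and plot methods run on a fitted model", {
  g <- param_grid(list(ou_ensemble(n_traj = 10, seed = 1, times = seq(0, 1, by = 0.1))))
  m <- end_nsde(g, run_config(seed = 1, imax = 3, width = 4, depth = 1), noise_dim = 1)
  expect_output(print(m), "neural SDE")
  expect_output(print(summary(m)), "training loss")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})
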