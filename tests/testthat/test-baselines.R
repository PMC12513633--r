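test_that("the neural ODE baseline tracks a noise-free system closely", {
  g <- circadian_grid_dataset("const", seed = 21, n_traj = 20,
                              sigma0_values = 1e-8, c_values = 0.2)
  m <- fit_baseline("node", g, run_config(seed = 1, imax = 150, width = 16, depth = 2, lr = 1e-2))
  om <- g$entries[[1]]$omega
  p <- predict(m, omega = om, x0 = c(0, 1), times = g$entries[[1]]$ensemble$times,
               n_traj = 1, seed = 1)
  xt <- -exp(-0.19 * p$times) * sin(0.21 * p$times)
  yt <- exp(-0.19 * p$times) * cos(0.21 * p$times)
  expect_lt(mean(abs(p$values[1, , 1] - xt)), 0.05)
  expect_lt(mean(abs(p$values[1, , 2] - yt)), 0.05)
})

test_that("deterministic baselines are bounded below by the dispersion floor", {
  # on stochastic data, a point-mass prediction cannot beat the per-time
  # ensemble variance; any deterministic rollout from one x0 is a point mass
  obs <- ou_ensemble(n_traj = 80, seed = 31, times = seq(0, 1, by = 0.05), x0 = 0)
  g <- param_grid(list(trajectory_ensemble(obs$times, obs$values, omega = 1)))
  floor_ <- sum(vapply(seq_len(n_times(obs) - 1), function(j)
    0.05 * mean((obs$values[, j, 1] - mean(obs$values[, j, 1]))^2), 0))
  for (fam in c("rnn", "lstm")) {
    m <- fit_baseline(fam, g, run_config(seed = 1, imax = 60, width = 8, lr = 1e-2))
    rep <- evaluate_loss(m, g, seed = 2)
    expect_gte(rep$total, floor_ * 0.999)
  }
})

test_that("recurrent rollouts are deterministic and learn a decay trend", {
  e <- em_integrate(ou_field(theta = 2, s = 0.02), 1, numeric(0),
                    seq(0, 1, by = 0.05), 40, seed = 7)
  g <- param_grid(list(trajectory_ensemble(e$times, e$values, omega = 1)))
  for (fam in c("rnn", "lstm")) {
    m <- fit_baseline(fam, g, run_config(seed = 2, imax = 250, width = 16, lr = 1e-2))
    p1 <- predict(m, omega = 1, x0 = 1, times = e$times, n_traj = 2, seed = 1)
    p2 <- predict(m, omega = 1, x0 = 1, times = e$times, n_traj = 2, seed = 9)
    expect_identical(p1$values, p2$values)             # deterministic
    expect_identical(p1$values[1, , ], p1$values[2, , ])
    expect_lt(mean(abs(p1$values[1, , 1] - exp(-2 * p1$times))), 0.12)
  }
})

test_that("the GP baseline approximates linear-SDE marginals", {
  # data: OU with omega-dependent scale; GP regresses state on omega and
  # draws calibrated per-time Gaussians
  ens <- lapply(c(0.1, 0.2, 0.3, 0.4), function(s) {
    e <- em_integrate(ou_field(theta = 1, s = s), 1, numeric(0),
                      seq(0, 1, by = 0.05), 60, seed = round(100 * s))
    trajectory_ensemble(e$times, e$values, omega = s)
  })
  g <- param_grid(ens)
  m <- fit_baseline("gp", g, run_config(seed = 1))
  p <- predict(m, omega = 0.25, times = ens[[1]]$times, n_traj = 400, seed = 5)
  # mean path follows the OU mean; dispersion interpolates between levels
  expect_lt(max(abs(colMeans(p$values[, , 1]) - exp(-p$times))), 0.05)
  s21 <- sd(p$values[, 21, 1])
  expect_gt(s21, 0.1); expect_lt(s21, 0.25)
})

test_that("benchmarking scores all models with the identical loss and sorts", {
  g <- circadian_grid_dataset("const", seed = 41, n_traj = 12,
                              sigma0_values = c(0.1, 0.3), c_values = 0.6)
  cfg <- run_config(seed = 1, imax = 10, width = 8, depth = 1)
  ma <- fit_baseline("rnn", g, cfg)
  mb <- fit_baseline("rnn", g, cfg)
  tab <- benchmark_models(list(a = ma, b = mb), g, seed = 3)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$loss[1], tab$loss[2])   # identical models, identical losses
  expect_true(!is.unsorted(tab$loss))
})
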