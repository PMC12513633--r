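test_that("core drift reproduces the Hill-regulated transcription identities", {
  p <- nfkb_params(kbasal = 0.01, kmax = 0.2, K_NFkB = 0.5, n_NFkB = 3, kdeg = 0.1)
  u <- c(u2 = 0.1, u3 = 0.1, u4 = 0.1, u5 = 0.1, u6 = 0.3, u7 = 0.1,
         u9 = 0.1, u10 = 0.1, u52 = 0)
  # u52 = 0: the Hill term vanishes
  expect_equal(unname(nfkb_drift_core(u, p)[, "du6"]), 0.01 - 0.1 * 0.3)
  # u52 = K: half saturation for any Hill coefficient
  u["u52"] <- 0.5
  expect_equal(unname(nfkb_drift_core(u, p)[, "du6"]), 0.01 + 0.1 - 0.1 * 0.3)
  # saturation limit
  u["u52"] <- 1e9
  expect_close(unname(nfkb_drift_core(u, p)[, "du6"]), 0.01 + 0.2 - 0.03, tol = 1e-6)
  u["u52"] <- -1
  expect_error(nfkb_drift_core(u, p), "negative Hill")
})

test_that("zero noise reduces to a deterministic trajectory independent of seed", {
  e1 <- nfkb_simulate(n_traj = 3, seed = 1, sigma = c(0, 0))
  e2 <- nfkb_simulate(n_traj = 2, seed = 99, sigma = c(0, 0))
  expect_equal(e1$values[1, , ], e1$values[3, , ])
  expect_equal(e1$values[1, , ], e2$values[2, , ])
  expect_equal(e1$times, seq(0, 150, by = 5))
  expect_equal(n_times(e1), 31L)
})

test_that("translocation noise is antisymmetric: u9 + u10 is conserved by it", {
  # strip all kinetics so only the noise terms act: u9 + u10 must then be
  # exactly constant along every path while u9 itself fluctuates
  p0 <- nfkb_params(kbasal = 0, kmax = 0, kdeg = 0, kimp = 0, kexp = 0,
                    ka_IkB_NFkB = 0, kd_IkB_NFkB = 0, kdeg_NFkB = 0, kphos = 0)
  lat <- nfkb_standin_latent(p0, ktl = 0, kdeg2 = 0, kin = 0, kdeg3 = 0,
                             kikk = 0, ke5 = 0, kpol = 0, kpoff = 0)
  u0 <- lat$u0; u0[] <- 5     # far from the zero clamp so only noise acts
  e <- nfkb_simulate(p0, lat, u0 = u0, n_traj = 4, seed = 6, sigma = c(0, 0.02))
  s <- e$values[, , match("u9", lat$state_names)] +
       e$values[, , match("u10", lat$state_names)]
  expect_equal(max(abs(s - 10)), 0, tolerance = 1e-12)
  expect_gt(sd(e$values[, 31, match("u9", lat$state_names)]), 0)
})

test_that("ensemble dispersion grows with the noise intensities", {
  lo <- nfkb_simulate(n_traj = 40, seed = 7, sigma = c(10^-3.2, 10^-2.5))
  hi <- nfkb_simulate(n_traj = 40, seed = 7, sigma = c(10^-2.2, 10^-1.5))
  dlo <- mean(apply(nfkb_readout(lo)$values[, , 1], 2, sd)[-1])
  dhi <- mean(apply(nfkb_readout(hi)$values[, , 1], 2, sd)[-1])
  expect_gt(dhi, dlo)
  # ensemble means approach the deterministic path as noise shrinks
  det <- nfkb_readout(nfkb_simulate(n_traj = 1, seed = 1, sigma = c(0, 0)))
  tiny <- nfkb_readout(nfkb_simulate(n_traj = 60, seed = 8, sigma = c(1e-5, 1e-5)))
  expect_lt(max(abs(colMeans(tiny$values[, , 1]) - det$values[1, , 1])), 5e-3)
})

test_that("the default noise grid has 121 combinations including both regimes", {
  g <- nfkb_noise_grid(n_traj = 1, seed = 1, times = c(0, 5), dt = 5)
  expect_equal(length(g$entries), 121L)
  keys <- vapply(g$entries, function(e) paste(signif(e$omega, 6), collapse = ","), "")
  expect_true(paste(signif(c(10^-3.2, 10^-2.5), 6), collapse = ",") %in% keys)
  expect_true(paste(signif(c(10^-2.2, 10^-1.5), 6), collapse = ",") %in% keys)
  g1 <- nfkb_noise_grid(lg_sigma1 = -3, lg_sigma2 = -2, n_traj = 1, seed = 1,
                        times = c(0, 5), dt = 5)
  expect_equal(length(g1$entries), 1L)
})

test_that("the experimental stand-in matches the recording geometry", {
  lv <- rbind(c(10^-3.0, 10^-2.0), c(10^-2.5, 10^-1.8))
  e <- nfkb_experimental_standin(12, lv, seed = 10)
  expect_equal(e$times, seq(0, 150, by = 5))
  expect_equal(dim(e$values), c(12L, 31L, 1L))
  tn <- attr(e, "true_noise")
  expect_equal(dim(tn), c(12L, 2L))
  expect_true(all(tn[, 1] %in% lv[, 1]))
  # single level: homogeneous labels
  e1 <- nfkb_experimental_standin(5, lv[1, , drop = FALSE], seed = 2)
  expect_true(all(attr(e1, "true_noise")[, 2] == lv[1, 2]))
})
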