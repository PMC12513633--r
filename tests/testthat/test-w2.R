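test_that("marginal squared W2 matches hand-derived cases", {
  expect_equal(marginal_w2_squared(c(0.3, 1.7), c(0.3, 1.7)), 0)
  expect_equal(marginal_w2_squared(0, 1), 1)
  # brute force over the two couplings of {0,2} vs {1,3}: sorted pairing
  # costs (1+1)/2 = 1, crossed pairing (9+1)/2 = 5
  expect_equal(marginal_w2_squared(c(0, 2), c(1, 3)), 1)
  expect_equal(marginal_w2_squared(c(2, 0), c(3, 1)), 1)   # order-free
  expect_error(marginal_w2_squared(1:3, 1:2), "sizes differ")
  expect_error(marginal_w2_squared(numeric(0), numeric(0)), "empty")
})

test_that("order-statistics coupling equals the exhaustive-coupling oracle", {
  set.seed(11)
  for (r in 1:40) {
    n <- sample(2:5, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(marginal_w2_squared(a, b), endnsde:::w2_exhaustive(a, b),
                 tolerance = 1e-12)
  }
})

test_that("large-sample W2 matches the Gaussian closed form", {
  set.seed(5)
  n <- 1e5
  a <- rnorm(n, 0, 1); b <- rnorm(n, 2, 1)
  expect_close(marginal_w2_squared(a, b), 4, tol = 0.08)   # (m1-m2)^2 + (s1-s2)^2
  a <- rnorm(n, 1, 2); b <- rnorm(n, -1, 0.5)
  expect_close(marginal_w2_squared(a, b), 4 + 1.5^2, tol = 0.13)
})

test_that("root-W2 satisfies the triangle inequality on random instances", {
  set.seed(21)
  for (r in 1:25) {
    n <- sample(2:12, 1)
    a <- rnorm(n); b <- rnorm(n, 1); c <- rexp(n)
    expect_lte(sqrt(marginal_w2_squared(a, c)),
               sqrt(marginal_w2_squared(a, b)) + sqrt(marginal_w2_squared(b, c)) + 1e-12)
  }
})

test_that("analytic W2 gradient matches finite differences away from ties", {
  set.seed(31)
  a <- rnorm(7); b <- rnorm(7)
  g <- endnsde:::marginal_w2_grad(a, b)
  h <- 1e-6
  for (i in seq_along(a)) {
    ap <- a; ap[i] <- ap[i] + h
    am <- a; am[i] <- am[i] - h
    fd <- (marginal_w2_squared(ap, b) - marginal_w2_squared(am, b)) / (2 * h)
    expect_close(g[i], fd, tol = 1e-5)
  }
})

test_that("temporal loss integrates per-time marginals with quadrature weights", {
  # constant-offset ensembles: every marginal cost is c^2, integral c^2 * T
  obs <- toy_ensemble(array(0, c(4, 6, 1)), times = seq(0, 2, length.out = 6))
  pred <- toy_ensemble(array(3, c(4, 6, 1)), times = seq(0, 2, length.out = 6))
  expect_equal(temporal_w2_squared(obs, pred), 9 * 2)
  expect_equal(temporal_w2_squared(obs, obs), 0)
  # hand-listed 2-trajectory scalar ensembles on a 3-point grid vs
  # exhaustive couplings at each time
  va <- array(c(0, 1, 0.5, 2, -1, 0), c(2, 3, 1))
  vb <- array(c(1, 0, 1.5, 0.5, 2, 1), c(2, 3, 1))
  ta <- toy_ensemble(va, times = c(0, 0.5, 2)); tb <- toy_ensemble(vb, times = c(0, 0.5, 2))
  manual <- 0.5 * endnsde:::w2_exhaustive(va[, 1, 1], vb[, 1, 1]) +
            1.5 * endnsde:::w2_exhaustive(va[, 2, 1], vb[, 2, 1])
  expect_equal(temporal_w2_squared(ta, tb), manual)
  expect_error(temporal_w2_squared(ta, toy_ensemble(vb, times = c(0, 1, 2))), "grids differ")
})

test_that("temporal loss is invariant to trajectory relabeling", {
  set.seed(41)
  va <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  vb <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  a <- toy_ensemble(va); b <- toy_ensemble(vb)
  ap <- toy_ensemble(va[sample(5), , , drop = FALSE])
  bp <- toy_ensemble(vb[sample(5), , , drop = FALSE])
  expect_equal(temporal_w2_squared(a, b), temporal_w2_squared(ap, bp), tolerance = 1e-12)
})

test_that("extrinsic loss sums per-omega temporal losses", {
  set.seed(51)
  mk <- function(om, shift = 0)
    trajectory_ensemble(0:3, array(rnorm(8 * 4, shift), c(8, 4, 1)), omega = om)
  go <- param_grid(list(mk(1), mk(2), mk(3)))
  gp <- param_grid(list(mk(1, 1), mk(2, 2), mk(3, 0.5)))
  rep <- extrinsic_loss(go, gp)
  v <- vapply(1:3, function(i)
    temporal_w2_squared(go$entries[[i]]$ensemble, gp$entries[[i]]$ensemble), 0)
  expect_equal(rep$total, sum(v))
  expect_equal(unname(rep$per_omega), v)
  expect_equal(extrinsic_loss(go, go)$total, 0)
  # single omega reduces to one temporal loss
  g1o <- param_grid(list(mk(9))); g1p <- param_grid(list(mk(9, 2)))
  expect_equal(extrinsic_loss(g1o, g1p)$total,
               temporal_w2_squared(g1o$entries[[1]]$ensemble, g1p$entries[[1]]$ensemble))
  expect_error(extrinsic_loss(go, g1p), "omega mismatch")
})
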