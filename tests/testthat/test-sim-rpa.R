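test_that("event enumeration matches hand-worked configurations", {
  p <- rpa_params(k1 = 2, km1 = 3, k2 = 5, km2 = 7, L = 20)
  # empty lattice of exactly one footprint: a single bind event
  ev <- rpa_events(data.frame(start = integer(0), mode = integer(0)), p)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "bind"); expect_equal(ev$pos, 0L)
  expect_equal(ev$propensity, 2)
  # L = 30, one 20-mode protein at 0: unbind + extend, no room to bind
  p30 <- rpa_params(k1 = 2, km1 = 3, k2 = 5, km2 = 7, L = 30)
  ev <- rpa_events(data.frame(start = 0L, mode = 20L), p30)
  expect_setequal(ev$type, c("unbind", "extend"))
  expect_equal(sum(ev$propensity), 3 + 5)
  # L = 50, one 30-mode protein at 0: binds only at start 30, plus revert
  p50 <- rpa_params(k1 = 2, km1 = 3, k2 = 5, km2 = 7, L = 50)
  ev <- rpa_events(data.frame(start = 0L, mode = 30L), p50)
  expect_equal(sort(unique(ev$type)), c("bind", "revert"))
  expect_equal(ev$pos[ev$type == "bind"], 30L)
  expect_equal(ev$propensity[ev$type == "revert"], 7)
  expect_error(rpa_events(data.frame(start = c(0L, 10L), mode = c(20L, 20L)), p50),
               "overlapping")
})

test_that("R and C++ propensity enumerations agree on random configurations", {
  set.seed(61)
  p <- rpa_params(k1 = 1e-3, km1 = 2e-4, k2 = 5e-3, km2 = 7e-4, L = 200)
  for (r in 1:30) {
    # build a random valid configuration by sequential placement
    st <- data.frame(start = integer(0), mode = integer(0))
    for (tries in 1:10) {
      s <- sample(0:(200 - 30), 1); m <- sample(c(20L, 30L), 1)
      if (!nrow(st) || all(s + m <= st$start | s >= st$start + st$mode))
        st <- rbind(st, data.frame(start = s, mode = m))
    }
    ev <- rpa_events(st, p)
    rtot <- tapply(ev$propensity, factor(ev$type, c("bind", "unbind", "extend", "revert")), sum)
    rtot[is.na(rtot)] <- 0
    ctot <- endnsde:::.rpa_propensities_cpp(p$L, st$start, st$mode,
                                            p$k1, p$km1, p$k2, p$km2)
    expect_equal(as.numeric(rtot), as.numeric(ctot), tolerance = 1e-12)
  }
})

test_that("single-event binding times follow the exponential law", {
  p <- rpa_params(k1 = 1e-3, km1 = 0, k2 = 0, km2 = 0, L = 20,
                  horizon = 1e8, grid = c(0, 1e8))
  tt <- vapply(1:2000, function(i) {
    e <- rpa_ssa(p, seed = i, keep_log = TRUE, normalize_time = FALSE)
    attr(e, "events")$t[1]
  }, 0)
  ks <- suppressWarnings(ks.test(tt, "pexp", rate = 1e-3))
  expect_gt(ks$p.value, 0.01)
  expect_close(mean(tt), 1000, tol = 60)
})

test_that("occupancy invariants hold along full simulations", {
  p <- rpa_params(k1 = 5e-3, km1 = 1e-3, k2 = 5e-3, km2 = 1e-3, L = 200,
                  horizon = 5000, grid = seq(0, 5000, length.out = 21))
  for (s in 1:5) {
    e <- rpa_ssa(p, seed = s, debug = TRUE)   # C++ asserts after every event
    x <- e$values[1, , ]
    expect_true(all(x >= 0), all(rowSums(x) <= 1 + 1e-12))
  }
})

test_that("irreversible deposition reaches the jamming coverage of the RSA oracle", {
  L <- 47L
  p <- rpa_params(k1 = 1e-2, km1 = 0, k2 = 0, km2 = 0, L = L,
                  horizon = 1e9, grid = c(0, 1e9))
  cov_ssa <- mean(vapply(1:600, function(i) rpa_ssa(p, seed = 3000 + i)$values[1, 2, 1], 0))
  cov_oracle <- rsa_jamming_oracle(L, n_rep = 600, seed = 99)
  # both are means of 600 replicates; allow a few standard errors
  expect_close(cov_ssa, cov_oracle, tol = 0.02)
})

test_that("the k2 sweep dataset has the study's shape and monotone 30nt uptake", {
  base <- rpa_params(L = 1000, horizon = 5000, grid = seq(0, 5000, length.out = 26))
  g <- rpa_k2_dataset(base, seed = 5, lg_k2 = c(-4, -3, -2, -1.5), n_traj = 10)
  sp <- vapply(g$entries, `[[`, "", "split")
  expect_equal(sum(sp == "train"), 4L)
  expect_equal(sum(sp == "test"), 4L)
  tr <- Filter(function(e) e$split == "train", g$entries)
  oms <- vapply(tr, `[[`, 0, "omega")
  expect_equal(sort(oms), c(-4, -3, -2, -1.5))
  # higher k2 -> more 30nt-mode at the end of the window
  x2 <- vapply(tr[order(oms)], function(e) mean(e$ensemble$values[, 26, 2]), 0)
  expect_lt(x2[1], x2[4])
  # times normalized to the observation window
  expect_equal(range(tr[[1]]$ensemble$times), c(0, 1))
})
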