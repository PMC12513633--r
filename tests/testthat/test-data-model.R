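test_that("ensemble constructor enforces its invariants", {
  e <- trajectory_ensemble(c(0, 1, 2), array(1:12, c(2, 3, 2)), omega = c(0.1, 0.2))
  expect_s3_class(e, "trajectory_ensemble")
  expect_error(trajectory_ensemble(c(0, 1, 1), array(1, c(1, 3, 1))), "increasing")
  expect_error(trajectory_ensemble(c(0, 1), array(1, c(1, 3, 1))), "match")
  v <- array(1, c(2, 3, 2)); v[2, 3, 1] <- NaN
  expect_error(trajectory_ensemble(0:2, v, c(0.1, 0.2)),
               "trajectory 2, time index 3, component 1")
})

test_that("tsv and rds round trips are the identity up to floating precision", {
  td <- withr::local_tempdir()
  e <- trajectory_ensemble(c(0, 0.5, 1),
                           array(rnorm(12), c(2, 3, 2)),
                           omega = c(0.1, 0.2),
                           state_names = c("x", "y"), param_names = c("s0", "c"))
  for (fmt in c("tsv", "rds")) {
    f <- file.path(td, paste0("e.", fmt))
    write_ensemble(e, f, fmt)
    r <- read_ensemble(f)
    expect_equal(r$values, e$values, tolerance = 1e-12)
    expect_equal(r$omega, e$omega)
    expect_equal(r$state_names, e$state_names)
    expect_equal(r$times, e$times, tolerance = 1e-12)
  }
})

test_that("columnar reader is row-order invariant and rejects ragged files", {
  td <- withr::local_tempdir()
  e <- trajectory_ensemble(c(0, 0.5, 1), array(rnorm(18), c(3, 3, 2)), omega = 0.7)
  f <- file.path(td, "e.tsv")
  write_ensemble(e, f)
  lines <- readLines(f)
  hdr <- lines[1:4]   # 3 metadata lines + column header
  body <- lines[-(1:4)]
  writeLines(c(hdr, sample(body)), f)
  r <- read_ensemble(f)
  expect_equal(r$values, e$values, tolerance = 1e-12)
  # drop one row -> ragged
  writeLines(c(hdr, body[-3]), f)
  expect_error(read_ensemble(f), "ragged")
})

test_that("a grid with duplicate omegas is rejected", {
  e1 <- trajectory_ensemble(0:1, array(1, c(1, 2, 1)), omega = 0.5)
  e2 <- trajectory_ensemble(0:1, array(2, c(1, 2, 1)), omega = 0.5)
  expect_error(param_grid(list(e1, e2)), "unique")
})

test_that("split_grid partitions trajectories and respects heldout omegas", {
  ens <- lapply(1:6, function(i)
    trajectory_ensemble(0:2, array(rnorm(10 * 3), c(10, 3, 1)), omega = i / 10))
  g <- param_grid(ens)
  held <- list(0.2, 0.5)
  s <- split_grid(g, heldout_omegas = held, within_fraction = 0.5, seed = 9)
  sp <- vapply(s$entries, `[[`, "", "split")
  expect_equal(sum(sp == "heldout"), 2L)
  expect_equal(sum(sp == "train"), 4L)
  expect_equal(sum(sp == "test"), 4L)
  # per-omega partition: train + test trajectory counts = 10, no training
  # trajectories at heldout omegas
  for (om in c(0.1, 0.3, 0.4, 0.6)) {
    ns <- vapply(Filter(function(e) e$omega == om, s$entries),
                 function(e) dim(e$ensemble$values)[1L], 0L)
    expect_equal(sum(ns), 10L)
  }
  # determinism: same seed -> same membership; different seed -> different
  s2 <- split_grid(g, held, 0.5, seed = 9)
  s3 <- split_grid(g, held, 0.5, seed = 10)
  tr <- function(x) lapply(Filter(function(e) e$split == "train", x$entries),
                           function(e) e$ensemble$values)
  expect_identical(tr(s), tr(s2))
  expect_false(identical(tr(s), tr(s3)))
  expect_error(split_grid(g, list(0.99)), "not present")
})

test_that("grid directory round trip preserves omegas and splits", {
  td <- withr::local_tempdir()
  ens <- lapply(1:3, function(i)
    trajectory_ensemble(0:2, array(rnorm(6), c(2, 3, 1)), omega = i))
  g <- split_grid(param_grid(ens), within_fraction = 0.5, seed = 1)
  write_grid(g, td)
  r <- read_grid(td)
  expect_equal(length(r$entries), length(g$entries))
  for (i in seq_along(r$entries)) {
    expect_equal(r$entries[[i]]$omega, g$entries[[i]]$omega)
    expect_equal(r$entries[[i]]$split, g$entries[[i]]$split)
    expect_equal(r$entries[[i]]$ensemble$values, g$entries[[i]]$ensemble$values,
                 tolerance = 1e-12)
  }
})
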