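#' Trajectory ensembles on a common time grid
#'
#' A trajectory ensemble collects \code{n} multivariate trajectories sampled
#' on one strictly increasing time grid, all sharing the same vector
#' \code{omega} of extrinsic parameters (cell-to-cell heterogeneity such as
#' noise intensities or kinetic rates). It is the empirical stand-in for the
#' law \eqn{\mu(\omega)} of the stochastic process at that parameter value.
#'
#' @param times numeric vector, strictly increasing (model time units).
#' @param values numeric array of dimension \code{c(n_traj, length(times),
#'   state_dim)}; a matrix is accepted for a single scalar-state trajectory
#'   set (interpreted as \code{n_traj x n_times}).
#' @param omega numeric vector of extrinsic parameters shared by every
#'   trajectory in the ensemble. May be length 0 for unconditioned data.
#' @param state_names,param_names optional character labels for the state
#'   and parameter components.
#'
#' @return An object of class \code{"trajectory_ensemble"}: a list with
#'   elements \code{times}, \code{values}, \code{omega}, \code{state_names},
#'   \code{param_names}.
#' @export
trajectory_ensemble <- function(times, values, omega = numeric(0),
                                state_names = NULL, param_names = NULL) {
  times <- as.numeric(times)
  if (length(times) < 1L || anyNA(times)) stop("'times' must be non-empty and finite")
  if (is.null(dim(values))) values <- array(values, c(1L, length(values), 1L))
  if (length(dim(values)) == 2L) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 3L) stop("'values' must be a (trajectory, time, component) array")
  storage.mode(values) <- "double"
  if (dim(values)[2L] != length(times))
    stop("second dimension of 'values' (", dim(values)[2L],
         ") does not match length(times) (", length(times), ")")
  if (dim(values)[1L] < 1L) stop("ensemble must contain at least one trajectory")
  if (dim(values)[3L] < 1L) stop("state dimension must be >= 1")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(values))
    stop(sprintf("non-finite value at trajectory %d, time index %d, component %d",
                 idx[1L], idx[2L], idx[3L]))
  }
  omega <- as.numeric(omega)
  if (anyNA(omega)) stop("'omega' must be finite")
  if (!is.null(state_names) && length(state_names) != dim(values)[3L])
    stop("state_names length must equal the state dimension")
  if (!is.null(param_names) && length(param_names) != length(omega))
    stop("param_names length must equal length(omega)")
  structure(list(times = times, values = values, omega = omega,
                 state_names = state_names, param_names = param_names),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Trajectory ensemble: %d trajectories, %d time points, state dim %d\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  t in [%g, %g]; omega = (%s)\n", min(x$times), max(x$times),
              paste(signif(x$omega, 4), collapse = ", ")))
  invisible(x)
}

n_traj <- function(e) dim(e$values)[1L]
n_times <- function(e) dim(e$values)[2L]
state_dim <- function(e) dim(e$values)[3L]

#' Subset trajectories of an ensemble
#' @param ensemble a \code{trajectory_ensemble}.
#' @param idx integer vector of trajectory indices to keep.
#' @return a \code{trajectory_ensemble} with the selected trajectories.
#' @export
subset_trajectories <- function(ensemble, idx) {
  trajectory_ensemble(ensemble$times,
                      ensemble$values[idx, , , drop = FALSE],
                      ensemble$omega, ensemble$state_names, ensemble$param_names)
}

#' Extrinsic-parameter grids
#'
#' A parameter grid is the finite set \eqn{\Lambda} of extrinsic-parameter
#' values, each carrying its trajectory ensemble and a split tag in
#' \code{{"train","test","heldout"}}. It is the container consumed by
#' \code{\link{end_nsde}} and by the evaluation helpers.
#'
#' @param ensembles list of \code{trajectory_ensemble} objects with unique
#'   \code{omega} vectors.
#' @param split character vector of split tags, recycled if length 1.
#' @return object of class \code{"param_grid"}.
#' @export
param_grid <- function(ensembles, split = "train") {
  if (!length(ensembles)) stop("empty grid")
  ok <- vapply(ensembles, inherits, logical(1), "trajectory_ensemble")
  if (!all(ok)) stop("all entries must be trajectory_ensemble objects")
  split <- rep_len(match.arg(split, c("train", "test", "heldout"), several.ok = TRUE), length(ensembles))
  om <- vapply(ensembles, function(e) paste(format(e$omega, digits = 15), collapse = ","), "")
  if (anyDuplicated(om)) stop("omega vectors must be unique within a grid")
  structure(list(entries = Map(function(e, s) list(omega = e$omega, ensemble = e, split = s),
                               ensembles, split)),
            class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  sp <- vapply(x$entries, `[[`, "", "split")
  cat(sprintf("Extrinsic-parameter grid: %d omega values (%s)\n", length(x$entries),
              paste(sprintf("%s: %d", names(table(sp)), table(sp)), collapse = ", ")))
  invisible(x)
}

grid_omegas <- function(grid) lapply(grid$entries, `[[`, "omega")

grid_ensembles <- function(grid, split = NULL) {
  e <- grid$entries
  if (!is.null(split)) e <- Filter(function(en) en$split %in% split, e)
  lapply(e, `[[`, "ensemble")
}

omega_key <- function(omega) paste(format(as.numeric(omega), digits = 15), collapse = ",")

#' Split a parameter grid into train/test/heldout
#'
#' Entries whose omega appears in \code{heldout_omegas} are tagged
#' \code{heldout} and contribute no training trajectories. Every other
#' entry is split per-trajectory: a fraction \code{within_fraction} of its
#' trajectories (seeded, without replacement) becomes a training ensemble
#' and the remainder a test ensemble at the same omega.
#'
#' @param grid a \code{param_grid}.
#' @param heldout_omegas list of omega vectors to exclude from training.
#' @param within_fraction fraction in (0, 1] of trajectories kept for
#'   training at each remaining omega.
#' @param seed integer seed controlling the per-trajectory split.
#' @return a \code{param_grid} whose entries are tagged train/test/heldout.
#'   Train and test entries at the same omega are distinct entries sharing
#'   the omega (the grid invariant of unique omegas applies within a split).
#' @export
split_grid <- function(grid, heldout_omegas = list(), within_fraction = 0.5, seed = 1L) {
  stopifnot(within_fraction > 0, within_fraction <= 1)
  keys <- vapply(grid_omegas(grid), omega_key, "")
  hkeys <- vapply(heldout_omegas, omega_key, "")
  if (!all(hkeys %in% keys))
    stop("heldout omega not present in grid: ", paste(setdiff(hkeys, keys), collapse = "; "))
  entries <- list()
  rng <- substream_rng(seed, "split")
  for (i in seq_along(grid$entries)) {
    en <- grid$entries[[i]]
    if (keys[i] %in% hkeys) {
      en$split <- "heldout"
      entries[[length(entries) + 1L]] <- en
      next
    }
    n <- n_traj(en$ensemble)
    ntr <- max(1L, round(within_fraction * n))
    idx <- rng$sample(n, ntr)
    entries[[length(entries) + 1L]] <-
      list(omega = en$omega, ensemble = subset_trajectories(en$ensemble, sort(idx)),
           split = "train")
    if (ntr < n)
      entries[[length(entries) + 1L]] <-
        list(omega = en$omega, ensemble = subset_trajectories(en$ensemble, setdiff(seq_len(n), idx)),
             split = "test")
  }
  structure(list(entries = entries), class = "param_grid")
}

# Named RNG substream: isolates each source of randomness from the others,
# so e.g. adding training noise draws does not perturb the data split.
substream_rng <- function(seed, stream) {
  seed <- (as.integer(seed) + sum(utf8ToInt(stream)) * 10007L) %% 2147483647L
  env <- new.env(parent = emptyenv())
  local_seed <- function(expr_fn) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, globalenv()))
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    res <- expr_fn()
    env$state <- get(".Random.seed", globalenv())
    res
  }
  list(
    rnorm  = function(n) local_seed(function() stats::rnorm(n)),
    runif  = function(n) local_seed(function() stats::runif(n)),
    sample = function(n, k) local_seed(function() sample.int(n, k)),
    with   = function(fn) local_seed(fn)
  )
}

#' Write a trajectory ensemble to disk
#'
#' Two on-disk layouts are supported: \code{"tsv"}, a human-inspectable
#' columnar text file (commented metadata header carrying omega and labels,
#' then one row per trajectory per time point with columns
#' \code{traj_id, t, x_1..x_d}), and \code{"rds"}, R's binary serialization
#' for large ensembles.
#'
#' @param ensemble a \code{trajectory_ensemble}.
#' @param path output file path (parent directory must exist).
#' @param format \code{"tsv"} or \code{"rds"}.
#' @return \code{path}, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  if (format == "rds") {
    saveRDS(ensemble, path)
    return(invisible(path))
  }
  d <- dim(ensemble$values)
  sn <- ensemble$state_names %||% paste0("x_", seq_len(d[3L]))
  hdr <- c(sprintf("# omega: %s", paste(format(ensemble$omega, digits = 17), collapse = " ")),
           sprintf("# param_names: %s", paste(ensemble$param_names %||% character(0), collapse = " ")),
           sprintf("# state_names: %s", paste(sn, collapse = " ")))
  tab <- data.table::data.table(
    traj_id = rep(seq_len(d[1L]), times = d[2L]),
    t = rep(ensemble$times, each = d[1L]))
  for (k in seq_len(d[3L])) tab[[sn[k]]] <- as.vector(ensemble$values[, , k])
  writeLines(hdr, path)
  data.table::fwrite(tab, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a trajectory ensemble written by \code{write_ensemble}
#'
#' Rows may appear in any order; the file must contain every (trajectory,
#' time) combination exactly once and a single omega vector.
#'
#' @param path file path.
#' @param format \code{"tsv"}, \code{"rds"}, or \code{"auto"} (by extension).
#' @return a \code{trajectory_ensemble}.
#' @export
read_ensemble <- function(path, format = c("auto", "tsv", "rds")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "tsv"
  if (format == "rds") {
    e <- readRDS(path)
    if (!inherits(e, "trajectory_ensemble")) stop("not a trajectory_ensemble: ", path)
    return(trajectory_ensemble(e$times, e$values, e$omega, e$state_names, e$param_names))
  }
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- function(key) {
    line <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(line)) return(character(0))
    strsplit(trimws(sub(paste0("^# ", key, ":"), "", line[1L])), "\\s+")[[1L]]
  }
  omega <- as.numeric(meta("omega"))
  pn <- meta("param_names"); if (!length(pn)) pn <- NULL
  sn <- meta("state_names"); if (!length(sn)) sn <- NULL
  tab <- data.table::fread(path, sep = "\t", skip = length(hdr))
  if (!all(c("traj_id", "t") %in% names(tab))) stop("missing traj_id or t column in ", path)
  cols <- setdiff(names(tab), c("traj_id", "t"))
  if (!length(cols)) stop("no state columns in ", path)
  data.table::setorderv(tab, c("traj_id", "t"))
  times <- sort(unique(tab$t))
  ids <- unique(tab$traj_id)
  if (nrow(tab) != length(times) * length(ids))
    stop("ragged data: not every trajectory has a value at every grid time")
  vals <- array(NA_real_, c(length(ids), length(times), length(cols)))
  for (k in seq_along(cols))
    vals[, , k] <- matrix(tab[[cols[k]]], nrow = length(ids), byrow = TRUE)
  trajectory_ensemble(times, vals, omega, state_names = sn, param_names = pn)
}

#' Write / read a whole parameter grid
#'
#' The grid is laid out as one directory with an \code{index.yaml} manifest
#' plus one ensemble file per entry.
#'
#' @param grid a \code{param_grid}.
#' @param dir directory (created if absent).
#' @param format per-ensemble format, see \code{\link{write_ensemble}}.
#' @return \code{dir} (write) or a \code{param_grid} (read).
#' @export
write_grid <- function(grid, dir, format = c("tsv", "rds")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- list()
  for (i in seq_along(grid$entries)) {
    en <- grid$entries[[i]]
    f <- sprintf("ensemble_%03d.%s", i, format)
    write_ensemble(en$ensemble, file.path(dir, f), format)
    idx[[i]] <- list(file = f, omega = as.numeric(en$omega), split = en$split)
  }
  yaml::write_yaml(idx, file.path(dir, "index.yaml"))
  invisible(dir)
}

#' @rdname write_grid
#' @export
read_grid <- function(dir) {
  idx <- yaml::read_yaml(file.path(dir, "index.yaml"))
  entries <- lapply(idx, function(it) {
    e <- read_ensemble(file.path(dir, it$file))
    list(omega = as.numeric(it$omega), ensemble = e, split = it$split)
  })
  structure(list(entries = entries), class = "param_grid")
}

#' Run configuration
#'
#' Bundles every tunable of a training or simulation run: the master seed
#' (all randomness flows from it through named substreams), the
#' Euler--Maruyama step size, the horizon, network and optimizer
#' hyperparameters, and the maximum number of training epochs.
#'
#' @param seed master integer seed.
#' @param dt Euler--Maruyama step size (> 0, model time units).
#' @param horizon final time (> 0).
#' @param width,depth hidden width and number of hidden layers of the drift
#'   and diffusion multilayer perceptrons.
#' @param lr Adam learning rate.
#' @param imax maximum training epochs (>= 1).
#' @param ... further named options stored verbatim.
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(seed = 1L, dt = 0.02, horizon = 1, width = 32L,
                       depth = 2L, lr = 5e-3, imax = 300L, ...) {
  stopifnot(dt > 0, horizon > 0, imax >= 1)
  structure(c(list(seed = as.integer(seed), dt = dt, horizon = horizon,
                   width = as.integer(width), depth = as.integer(depth),
                   lr = lr, imax = as.integer(imax)), list(...)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
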