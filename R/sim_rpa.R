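#' Parameters of the RPA--ssDNA lattice binding model
#'
#' Replication protein A (RPA) binds single-stranded DNA in a 20-nt
#' footprint and can extend to a stabilized 30-nt footprint when the 10 nt
#' immediately downstream are free. Occupied DNA excludes further binding,
#' so the process is a continuous-time Markov chain on lattice
#' configurations.
#'
#' Rate semantics: \code{k1} is the binding propensity per eligible start
#' position (free solution RPA is treated as an unlimited reservoir, so the
#' total binding propensity is \code{k1} times the number of positions with
#' at least 20 consecutive free sites); \code{km1}, \code{k2}, \code{km2}
#' are per-protein propensities for unbinding (20-mode), 20-to-30
#' extension, and 30-to-20 reversion.
#'
#' @param k1 20nt-mode binding rate (per second, per eligible position).
#' @param km1 20nt-mode unbinding rate (per second).
#' @param k2 20-to-30 conversion rate (per second).
#' @param km2 30-to-20 reversion rate (per second).
#' @param L lattice length in nucleotides (>= 20).
#' @param horizon simulated time in seconds.
#' @param grid output time grid in seconds (last-value sampled).
#' @return object of class \code{"rpa_params"}.
#' @export
rpa_params <- function(k1 = 1e-3, km1 = 1e-6, k2 = 1e-3, km2 = 1e-6,
                       L = 50000L, horizon = 5000,
                       grid = seq(0, horizon, length.out = 51L)) {
  stopifnot(k1 >= 0, km1 >= 0, k2 >= 0, km2 >= 0, L >= 20)
  structure(list(k1 = k1, km1 = km1, k2 = k2, km2 = km2,
                 L = as.integer(L), horizon = horizon, grid = grid),
            class = "rpa_params")
}

#' Enumerate the possible events of a lattice configuration
#'
#' Pure-R reference enumeration of every event and its propensity for a
#' given occupancy state; the C++ simulation path recomputes the same
#' quantities internally and the two are cross-checked in the tests.
#'
#' @param state data.frame with columns \code{start} (0-based) and
#'   \code{mode} (20 or 30); footprints \code{[start, start+mode)} must be
#'   disjoint and inside \code{[0, L)}.
#' @param params an \code{\link{rpa_params}}.
#' @return data.frame with columns \code{type} (bind/unbind/extend/revert),
#'   \code{pos} (start position) and \code{propensity}; zero rows for a
#'   frozen configuration.
#' @export
rpa_events <- function(state, params) {
  L <- params$L
  state <- state[order(state$start), , drop = FALSE]
  ends <- state$start + state$mode
  if (nrow(state)) {
    if (any(state$start < 0) || any(ends > L) ||
        (nrow(state) > 1 && any(state$start[-1] < ends[-nrow(state)])))
      stop("invalid lattice state: overlapping or out-of-range footprints")
  }
  ev <- list()
  # bind-20: every start s with >= 20 consecutive free sites
  bounds <- c(0L, ends); nexts <- c(state$start, L)
  for (g in seq_along(bounds)) {
    gap <- nexts[g] - bounds[g]
    if (gap >= 20L && params$k1 > 0)
      ev[[length(ev) + 1L]] <- data.frame(
        type = "bind", pos = bounds[g] + seq_len(gap - 19L) - 1L,
        propensity = params$k1)
  }
  for (i in seq_len(nrow(state))) {
    if (state$mode[i] == 20L) {
      if (params$km1 > 0)
        ev[[length(ev) + 1L]] <- data.frame(type = "unbind", pos = state$start[i],
                                            propensity = params$km1)
      nxt <- if (i < nrow(state)) state$start[i + 1L] else L
      if (params$k2 > 0 && nxt - (state$start[i] + 20L) >= 10L)
        ev[[length(ev) + 1L]] <- data.frame(type = "extend", pos = state$start[i],
                                            propensity = params$k2)
    } else if (params$km2 > 0) {
      ev[[length(ev) + 1L]] <- data.frame(type = "revert", pos = state$start[i],
                                          propensity = params$km2)
    }
  }
  if (!length(ev)) return(data.frame(type = character(0), pos = integer(0),
                                     propensity = numeric(0)))
  do.call(rbind, ev)
}

#' Run the exact Gillespie simulation
#'
#' Draws exponential waiting times from the total propensity, picks events
#' proportionally to their propensities, and samples the filling fractions
#' \eqn{x_1 = 20 N_{20} / L} (20nt-mode) and \eqn{x_2 = 30 N_{30} / L}
#' (30nt-mode) onto \code{params$grid} by last-value interpolation. A zero
#' total propensity freezes the state until the horizon.
#'
#' @param params an \code{\link{rpa_params}}.
#' @param seed integer seed.
#' @param n_traj number of independent runs.
#' @param keep_log,debug keep the per-event log (single trajectory only) /
#'   re-check the occupancy invariants after every event.
#' @param normalize_time if TRUE (default) the returned ensemble's time
#'   axis is the fraction of the observation window (\code{grid/horizon}),
#'   so W2 losses integrate over a unit interval; the raw grid is kept as
#'   attribute \code{"seconds"}.
#' @return a \code{trajectory_ensemble} of (x1, x2); if \code{keep_log},
#'   the event log of the last run is attached as attribute
#'   \code{"events"}.
#' @export
rpa_ssa <- function(params, seed = 1L, n_traj = 1L, keep_log = FALSE,
                    debug = FALSE, normalize_time = TRUE) {
  rng <- substream_rng(seed, "ssa")
  J <- length(params$grid)
  vals <- array(NA_real_, c(n_traj, J, 2L))
  ev <- NULL
  for (i in seq_len(n_traj)) {
    res <- rng$with(function()
      .rpa_ssa_cpp(params$L, params$k1, params$km1, params$k2, params$km2,
                   params$grid, params$horizon, keep_log, debug))
    vals[i, , ] <- res$x
    if (keep_log) ev <- res$events
  }
  tt <- if (normalize_time) params$grid / max(params$grid) else params$grid
  e <- trajectory_ensemble(tt, vals, omega = log10(params$k2),
                           state_names = c("x1", "x2"), param_names = "lg_k2")
  attr(e, "seconds") <- params$grid
  if (keep_log) attr(e, "events") <- ev
  e
}

#' RPA surrogate-training dataset over the k2 sweep
#'
#' The conversion rate is swept over \eqn{\lg k_2 \in \{-4.0, -3.9, \dots,
#' -1.5\}} (26 values) with \eqn{k_1 = 10^{-3}}, \eqn{k_{-1} = 10^{-6}},
#' \eqn{k_{-2} = 10^{-6}} s\eqn{^{-1}}; each value contributes
#' \code{n_traj} trajectories of \eqn{(x_1, x_2)} with omega =
#' \eqn{\lg k_2}, split evenly into train and test.
#'
#' @param params_base an \code{\link{rpa_params}} supplying everything but
#'   k2.
#' @param seed integer seed.
#' @param lg_k2 vector of \eqn{\log_{10} k_2} values.
#' @param n_traj trajectories per k2 value (study default 100).
#' @param split_fraction fraction per value tagged train (default 0.5).
#' @return a \code{param_grid} with train/test entries and
#'   \code{noise_dim} attribute 2.
#' @export
rpa_k2_dataset <- function(params_base = rpa_params(), seed = 1L,
                           lg_k2 = seq(-4, -1.5, by = 0.1),
                           n_traj = 100L, split_fraction = 0.5) {
  ens <- vector("list", length(lg_k2))
  for (i in seq_along(lg_k2)) {
    p <- params_base; p$k2 <- 10^lg_k2[i]
    ens[[i]] <- rpa_ssa(p, seed = seed + 1000L * i, n_traj = n_traj)
  }
  g <- param_grid(ens, "train")
  attr(g, "noise_dim") <- 2L
  if (split_fraction < 1) g <- split_grid(g, within_fraction = split_fraction, seed = seed)
  attr(g, "noise_dim") <- 2L
  g
}

#' Independent random-sequential-adsorption oracle
#'
#' Direct Monte-Carlo of irreversible 20-mer deposition: repeatedly pick a
#' uniformly random eligible start until none remains, and report the mean
#' jammed coverage. Used as an independent check of the SSA in the
#' irreversible limit (km1 = k2 = km2 = 0), where the SSA's event selection
#' reduces to the same uniform choice.
#'
#' @param L lattice length.
#' @param n_rep number of independent depositions.
#' @param seed integer seed.
#' @param footprint deposited segment length (default 20).
#' @return mean coverage (fraction of occupied sites) at jamming.
#' @export
rsa_jamming_oracle <- function(L, n_rep = 2000L, seed = 1L, footprint = 20L) {
  rng <- substream_rng(seed, "rsa")
  rng$with(function() {
    cov <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      free <- rep(TRUE, L)
      placed <- 0L
      repeat {
        ok <- which(vapply(seq_len(L - footprint + 1L),
                           function(s) all(free[s:(s + footprint - 1L)]), TRUE))
        if (!length(ok)) break
        s <- ok[sample.int(length(ok), 1L)]
        free[s:(s + footprint - 1L)] <- FALSE
        placed <- placed + 1L
      }
      cov[r] <- footprint * placed / L
    }
    mean(cov)
  })
}
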