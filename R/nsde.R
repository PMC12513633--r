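#' Parameter-conditioned SDE fields
#'
#' An SDE field bundles a drift map \eqn{f(X; \omega)} and a diffusion map
#' \eqn{\sigma(X; \omega)} with their declared dimensions. Both maps are
#' vectorized over samples: \code{drift(X, omega)} takes an
#' \code{n x state_dim} state matrix and one omega vector and returns an
#' \code{n x state_dim} matrix; \code{diffusion(X, omega)} returns an
#' \code{n x (state_dim * noise_dim)} matrix holding each sample's
#' \eqn{d \times m} diffusion matrix in column-major order.
#'
#' @param drift,diffusion vectorized maps as described above.
#' @param state_dim,param_dim,noise_dim integer dimensions.
#' @param latent_mask optional integer subset of components entering the
#'   training loss; components outside it evolve but are never scored.
#' @return object of class \code{"sde_field"}.
#' @export
sde_field <- function(drift, diffusion, state_dim, param_dim = 0L,
                      noise_dim = state_dim, latent_mask = NULL) {
  stopifnot(is.function(drift), is.function(diffusion), state_dim >= 1)
  structure(list(drift = drift, diffusion = diffusion,
                 state_dim = as.integer(state_dim),
                 param_dim = as.integer(param_dim),
                 noise_dim = as.integer(noise_dim),
                 latent_mask = latent_mask),
            class = "sde_field")
}

#' Euler--Maruyama integration of an SDE field
#'
#' Simulates \code{n_traj} independent trajectories of
#' \eqn{dX = f(X;\omega)dt + \sigma(X;\omega)dB_t} on the requested grid:
#' \eqn{X_{j+1} = X_j + f(X_j;\omega)\Delta t_j + \sigma(X_j;\omega)\Delta B_j}
#' with \eqn{\Delta B_j \sim N(0, \Delta t_j I_m)} independent across
#' trajectories and steps.
#'
#' @param field an \code{\link{sde_field}}.
#' @param x0 initial state: vector of length \code{state_dim} (shared) or
#'   an \code{n_traj x state_dim} matrix.
#' @param omega extrinsic-parameter vector.
#' @param times strictly increasing output grid (integration grid).
#' @param n_traj number of trajectories.
#' @param seed integer seed (deterministic output for a fixed seed).
#' @param lower optional componentwise lower bound; states are clamped to
#'   it after every step (reflecting clamp used by concentration models).
#' @return a \code{\link{trajectory_ensemble}} tagged with \code{omega}.
#' @export
em_integrate <- function(field, x0, omega = numeric(0), times, n_traj = 1L,
                         seed = 1L, lower = NULL) {
  stopifnot(n_traj >= 1)
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  d <- field$state_dim; m <- field$noise_dim
  if (!is.matrix(x0) && length(x0) != d)
    stop("x0 dimension mismatch: expected state_dim ", d, ", got length ", length(x0))
  X <- if (is.matrix(x0)) x0 else matrix(x0, n_traj, d, byrow = TRUE)
  if (ncol(X) != d) stop("x0 dimension mismatch: expected state_dim ", d)
  if (nrow(X) != n_traj) stop("x0 must supply one row per trajectory")
  J <- length(times)
  out <- array(NA_real_, c(n_traj, J, d))
  out[, 1L, ] <- X
  rng <- substream_rng(seed, "em")
  dB <- array(rng$rnorm(n_traj * m * (J - 1L)), c(n_traj, m, J - 1L))
  dt <- diff(times)
  for (j in seq_len(J - 1L)) {
    Fv <- field$drift(X, omega)
    S <- field$diffusion(X, omega)
    if (!all(is.finite(Fv)) || !all(is.finite(S)))
      stop("non-finite drift/diffusion at step ", j)
    db <- dB[, , j, drop = FALSE] * sqrt(dt[j])
    noise <- matrix(0, n_traj, d)
    for (k in seq_len(m))
      noise <- noise + S[, (k - 1L) * d + seq_len(d), drop = FALSE] * db[, k, 1L]
    X <- X + Fv * dt[j] + noise
    if (!is.null(lower)) X <- pmax(X, rep(lower, each = n_traj))
    if (any(abs(X) > 1e8)) stop("state overflow at step ", j, " (|X| > 1e8)")
    out[, j + 1L, ] <- X
  }
  trajectory_ensemble(times, out, omega)
}

#' Fit an extrinsic-noise-driven neural SDE
#'
#' The main fitting function. Drift and diffusion are two multilayer
#' perceptrons taking the (z-scored) state and extrinsic-parameter vector
#' as inputs. Each epoch simulates, for every training omega, an ensemble
#' from the observed initial states by Euler--Maruyama with fresh Wiener
#' increments, evaluates the extrinsic-noise-driven temporally decoupled
#' squared W2 loss against the observed ensembles, and backpropagates the
#' exact gradient through the whole rollout (order-statistics coupling at
#' every time point) into an Adam update.
#'
#' @param grid a \code{\link{param_grid}}; entries tagged \code{"train"}
#'   are used (all entries if none is tagged).
#' @param config a \code{\link{run_config}}: \code{width}, \code{depth},
#'   \code{lr}, \code{imax}, \code{seed} are honoured here.
#' @param mask integer vector of state components entering the loss
#'   (default: all; latent components are excluded by listing only the
#'   observed ones).
#' @param noise_dim Wiener dimension m of the learned diffusion (default:
#'   the grid's \code{noise_dim} attribute, else the state dimension).
#' @param stochastic if FALSE, the diffusion is fixed at zero and only the
#'   drift network is trained (this is the neural-ODE limit used by the
#'   deterministic baseline).
#' @param verbose print the loss every 25 epochs.
#' @return an object of class \code{"end_nsde"} with the learned
#'   \code{\link{sde_field}}, the per-epoch loss history and provenance.
#' @seealso \code{\link{predict.end_nsde}}, \code{\link{evaluate_loss}},
#'   \code{\link{drift_error}}
#' @export
end_nsde <- function(grid, config = run_config(), mask = NULL,
                     noise_dim = NULL, stochastic = TRUE, verbose = FALSE) {
  ens <- grid_ensembles(grid, "train")
  if (!length(ens)) ens <- grid_ensembles(grid)
  if (!length(ens)) stop("grid has no training ensembles")
  times <- ens[[1L]]$times
  for (e in ens) if (length(e$times) != length(times) || any(abs(e$times - times) > 1e-10))
    stop("all training ensembles must share one time grid")
  d <- state_dim(ens[[1L]])
  p <- length(ens[[1L]]$omega)
  m <- as.integer(noise_dim %||% attr(grid, "noise_dim") %||% d)
  mask <- as.integer(mask %||% attr(grid, "mask") %||% seq_len(d))
  J <- length(times); dt <- diff(times)

  # stacked batch over all omegas
  ns <- vapply(ens, n_traj, 0L)
  N <- sum(ns)
  idx <- split(seq_len(N), rep(seq_along(ens), ns))
  X0 <- do.call(rbind, lapply(ens, function(e) matrix(e$values[, 1L, ], n_traj(e), d)))
  W0 <- do.call(rbind, lapply(ens, function(e) matrix(e$omega, n_traj(e), p, byrow = TRUE)))

  # input z-scoring constants from the observed data
  allX <- do.call(rbind, lapply(ens, function(e) matrix(e$values, ncol = d)))
  mu_x <- colMeans(allX); sd_x <- pmax(apply(allX, 2, stats::sd), 1e-8)
  mu_w <- if (p) colMeans(W0) else numeric(0)
  sd_w <- if (p) pmax(apply(W0, 2, stats::sd), 1e-8) else numeric(0)
  W0s <- if (p) sweep(sweep(W0, 2, mu_w), 2, sd_w, "/") else matrix(0, N, 0L)

  # observed order statistics per (omega, time, masked component)
  obs_sorted <- lapply(ens, function(e) {
    a <- array(NA_real_, c(n_traj(e), J, length(mask)))
    for (j in seq_len(J)) for (k in seq_along(mask))
      a[, j, k] <- sort(e$values[, j, mask[k]])
    a
  })

  rng_init <- substream_rng(config$seed, "init")
  fnet <- mlp_init(d + p, d, config$width, config$depth, rng_init)
  # the diffusion network defaults to a smaller capacity than the drift:
  # dispersion information per sample is weaker, and an over-flexible
  # diffusion invents spurious state-dependence off the data manifold
  snet <- mlp_init(d + p, d * m, config$width_diffusion %||% max(16L, config$width %/% 2L),
                   config$depth_diffusion %||% 1L, rng_init)
  # warm-start the diffusion from the pooled empirical quadratic
  # covariation, E[dX dX^T]/dt ~ sigma sigma^T: the output bias is set to a
  # Cholesky factor of the pooled estimate, so optimization starts at the
  # data's average noise structure (including cross-correlations, which the
  # marginal-decoupled loss identifies only slowly through dynamical mixing)
  qv <- matrix(0, d, d)
  for (e in ens) {
    dx <- apply(e$values, c(1L, 3L), diff)        # (J-1, n, d)
    dxs <- matrix(dx / sqrt(dt), ncol = d)
    qv <- qv + crossprod(dxs) / nrow(dxs) / length(ens)
  }
  ch <- tryCatch(t(chol(qv + diag(1e-12, d))), error = function(e) diag(sqrt(diag(qv)), d))
  for (k in seq_len(min(d, m))) for (i in seq_len(d))
    snet$b[[length(snet$b)]][(k - 1L) * d + i] <- ch[i, k]
  fst <- adam_init(fnet); sst <- adam_init(snet)
  rng_noise <- substream_rng(config$seed, "train-noise")

  scale_X <- function(X) sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  history <- numeric(config$imax)
  tail_start <- max(1L, ceiling((config$polyak_from %||% 0.7) * config$imax))
  favg <- fnet; savg <- snet; n_avg <- 0L

  # internal Euler substeps between observation times: systems whose
  # transients are fast relative to the measurement spacing need a finer
  # integration grid than the data grid; the loss is still evaluated at
  # the observation times only
  s <- max(1L, as.integer(config$substeps %||% 1L))
  Jf <- (J - 1L) * s
  dtf <- rep(dt / s, each = s)
  sqdtf <- sqrt(dtf)

  for (epoch in seq_len(config$imax)) {
    dB <- array(if (stochastic) rng_noise$rnorm(N * m * Jf) else 0,
                c(N, m, Jf))
    cf <- vector("list", Jf); cs <- vector("list", Jf)
    Xs <- vector("list", Jf + 1L); Xs[[1L]] <- X0
    X <- X0
    for (j in seq_len(Jf)) {
      inp <- cbind(scale_X(X), W0s)
      fw_f <- mlp_forward(fnet, inp, cache = TRUE)
      noise <- matrix(0, N, d)
      db <- dB[, , j, drop = FALSE] * sqdtf[j]
      if (stochastic) {
        fw_s <- mlp_forward(snet, inp, cache = TRUE)
        for (k in seq_len(m))
          noise <- noise + fw_s$out[, (k - 1L) * d + seq_len(d), drop = FALSE] * db[, k, 1L]
        cs[[j]] <- fw_s
      }
      X <- X + fw_f$out * dtf[j] + noise
      if (!all(is.finite(X)) || any(abs(X) > 1e8))
        stop("divergent rollout at epoch ", epoch, ", step ", j)
      cf[[j]] <- fw_f
      dB[, , j] <- db   # keep the scaled increments for the backward pass
      Xs[[j + 1L]] <- X
    }
    # loss and its gradient at the observation nodes (left-Riemann weights)
    loss <- 0
    G <- vector("list", Jf + 1L)
    for (j in seq_len(Jf + 1L)) G[[j]] <- matrix(0, N, d)
    for (j in 2:(J - 1L)) {
      jn <- (j - 1L) * s + 1L    # fine-grid node of observation time j
      for (i in seq_along(ens)) {
        ii <- idx[[i]]; n_i <- length(ii)
        for (k in seq_along(mask)) {
          a <- Xs[[jn]][ii, mask[k]]
          b <- obs_sorted[[i]][, j, k]
          oa <- sort.list(a, method = "radix")
          dv <- a[oa] - b
          loss <- loss + dt[j] * mean(dv * dv)
          g <- numeric(n_i); g[oa] <- (2 * dt[j] / n_i) * dv
          G[[jn]][ii, mask[k]] <- g
        }
      }
    }
    history[epoch] <- loss

    gF <- NULL; gS <- NULL
    A <- matrix(0, N, d)
    for (j in Jf:1L) {
      A <- A + G[[j + 1L]]
      bw_f <- mlp_backward(fnet, cf[[j]], A * dtf[j])
      gF <- grad_accum(gF, bw_f)
      gX <- bw_f$gX[, seq_len(d), drop = FALSE]
      if (stochastic) {
        dSg <- matrix(0, N, d * m)
        for (k in seq_len(m))
          dSg[, (k - 1L) * d + seq_len(d)] <- A * dB[, k, j]
        bw_s <- mlp_backward(snet, cs[[j]], dSg)
        gS <- grad_accum(gS, bw_s)
        gX <- gX + bw_s$gX[, seq_len(d), drop = FALSE]
      }
      A <- A + sweep(gX, 2, sd_x, "/")
    }
    sched <- if (epoch > 0.85 * config$imax) 0.1 else if (epoch > 0.6 * config$imax) 0.3 else 1
    up <- adam_step(fnet, gF, fst, config$lr * sched); fnet <- up$net; fst <- up$st
    wdf <- config$weight_decay_drift %||% 0
    if (wdf > 0) for (l in seq_along(fnet$W)) fnet$W[[l]] <- fnet$W[[l]] * (1 - wdf * sched)
    if (stochastic) {
      lr_s <- (config$lr_diffusion %||% (config$lr / 2)) * sched
      up <- adam_step(snet, gS, sst, lr_s); snet <- up$net; sst <- up$st
      # decoupled weight decay on the diffusion weights (not biases):
      # shrinks spurious state-dependence toward the quadratic-variation
      # warm start, countering the weak dispersion signal per sample
      wd <- config$weight_decay_diffusion %||% 1e-3
      if (wd > 0) {
        for (l in seq_along(snet$W)) snet$W[[l]] <- snet$W[[l]] * (1 - wd * lr_s / config$lr)
        # extra shrinkage on the state-input rows: per-time sampling quirks
        # of the empirical marginals are most easily chased through the
        # state input, so its smoothness prior is stronger than omega's
        wx <- config$weight_decay_state %||% (4 * wd)
        snet$W[[1L]][seq_len(d), ] <- snet$W[[1L]][seq_len(d), ] * (1 - wx * lr_s / config$lr)
      }
    }
    # Polyak tail averaging: the returned weights are the mean over the
    # final stretch of epochs, damping the stochastic-gradient wobble of
    # weakly determined directions
    if (epoch == tail_start) { favg <- fnet; savg <- snet; n_avg <- 1L }
    else if (epoch > tail_start) {
      n_avg <- n_avg + 1L
      mix <- function(avg, cur) {
        for (l in seq_along(avg$W)) {
          avg$W[[l]] <- avg$W[[l]] + (cur$W[[l]] - avg$W[[l]]) / n_avg
          avg$b[[l]] <- avg$b[[l]] + (cur$b[[l]] - avg$b[[l]]) / n_avg
        }
        avg
      }
      favg <- mix(favg, fnet); savg <- mix(savg, snet)
    }
    if (verbose && (epoch %% 25L == 0L || epoch == 1L))
      message(sprintf("epoch %4d  loss %.6g", epoch, loss))
  }

  if (n_avg > 0L) { fnet <- favg; snet <- savg }
  norm <- list(mu_x = mu_x, sd_x = sd_x, mu_w = mu_w, sd_w = sd_w)
  field <- neural_field(fnet, if (stochastic) snet else NULL, d, p, m, norm, mask)
  structure(list(
    field = field, drift_net = fnet,
    diffusion_net = if (stochastic) snet else NULL, norm = norm,
    config = config, times = times, mask = mask,
    state_names = ens[[1L]]$state_names,
    loss_history = history,
    omegas = lapply(ens, `[[`, "omega"),
    x0_pool = lapply(seq_along(ens), function(i) {
      x <- X0[idx[[i]], , drop = FALSE]; rownames(x) <- NULL; x
    }),
    provenance = list(seed = config$seed, n_traj = ns,
                      data_dim = c(n = N, J = J, d = d, p = p, m = m))),
    class = "end_nsde")
}

refine_times <- function(times, s) {
  out <- unlist(lapply(seq_len(length(times) - 1L), function(j)
    seq(times[j], times[j + 1L], length.out = s + 1L)[-(s + 1L)]))
  c(out, times[length(times)])
}

# Wrap trained networks (plus input normalization) as an sde_field.
neural_field <- function(fnet, snet, d, p, m, norm, mask = NULL) {
  mk_inp <- function(X, omega) {
    n <- nrow(X)
    Xi <- sweep(sweep(X, 2, norm$mu_x), 2, norm$sd_x, "/")
    if (p) {
      ws <- (as.numeric(omega) - norm$mu_w) / norm$sd_w
      cbind(Xi, matrix(ws, n, p, byrow = TRUE))
    } else Xi
  }
  sde_field(
    drift = function(X, omega) mlp_forward(fnet, mk_inp(X, omega)),
    diffusion = if (is.null(snet)) function(X, omega) matrix(0, nrow(X), d * m)
                else function(X, omega) mlp_forward(snet, mk_inp(X, omega)),
    state_dim = d, param_dim = p, noise_dim = m, latent_mask = mask)
}

#' @export
print.end_nsde <- function(x, ...) {
  pv <- x$provenance$data_dim
  cat("Extrinsic-noise-driven neural SDE\n")
  cat(sprintf("  state dim %d, param dim %d, noise dim %d; %d omega values, %d trajectories\n",
              pv["d"], pv["p"], pv["m"], length(x$omegas), pv["n"]))
  cat(sprintf("  trained %d epochs; loss %.5g -> %.5g\n",
              length(x$loss_history), x$loss_history[1L],
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @export
summary.end_nsde <- function(object, ...) {
  h <- object$loss_history
  res <- list(
    dims = object$provenance$data_dim,
    n_omegas = length(object$omegas),
    epochs = length(h),
    initial_loss = h[1L], final_loss = h[length(h)], best_loss = min(h),
    config = object$config)
  class(res) <- "summary.end_nsde"
  res
}

#' @export
print.summary.end_nsde <- function(x, ...) {
  cat("END neural SDE fit\n")
  cat(sprintf("  dims: d=%d p=%d m=%d, %d trajectories over %d omegas\n",
              x$dims["d"], x$dims["p"], x$dims["m"], x$dims["n"], x$n_omegas))
  cat(sprintf("  epochs: %d (width %d, depth %d, lr %g)\n",
              x$epochs, x$config$width, x$config$depth, x$config$lr))
  cat(sprintf("  training loss: initial %.5g, final %.5g, best %.5g\n",
              x$initial_loss, x$final_loss, x$best_loss))
  invisible(x)
}

#' @export
coef.end_nsde <- function(object, ...) {
  list(drift = object$drift_net, diffusion = object$diffusion_net,
       normalization = object$norm)
}

#' @export
plot.end_nsde <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "extrinsic-noise W2 loss", log = "y", ...)
  invisible(x)
}

#' Predict trajectory ensembles from a trained model
#'
#' Rolls out the learned SDE by Euler--Maruyama at an arbitrary omega
#' (inside or outside the training grid: the generalization use-case).
#'
#' @param object an \code{end_nsde} fit.
#' @param omega extrinsic-parameter vector.
#' @param x0 initial states; default: the observed initial states stored
#'   for this omega during training (resampled to \code{n_traj} rows), or
#'   the pooled initial states if omega was not seen in training.
#' @param times output grid; default: the training grid.
#' @param n_traj number of trajectories.
#' @param seed integer seed.
#' @param ... unused.
#' @return a \code{trajectory_ensemble}; attribute
#'   \code{"seen_in_training"} records whether omega was in the training
#'   grid.
#' @export
predict.end_nsde <- function(object, omega = numeric(0), x0 = NULL,
                             times = NULL, n_traj = 50L, seed = 1L, ...) {
  times <- times %||% object$times
  keys <- vapply(object$omegas, omega_key, "")
  hit <- match(omega_key(omega), keys)
  if (is.null(x0)) {
    pool <- if (!is.na(hit)) object$x0_pool[[hit]] else do.call(rbind, object$x0_pool)
    x0 <- pool[rep_len(seq_len(nrow(pool)), n_traj), , drop = FALSE]
  }
  s <- max(1L, as.integer(object$config$substeps %||% 1L))
  if (s > 1L) {
    fine <- refine_times(times, s)
    full <- em_integrate(object$field, x0, omega, fine, n_traj, seed)
    keep <- seq(1L, length(fine), by = s)
    out <- trajectory_ensemble(times, full$values[, keep, , drop = FALSE], full$omega)
  } else {
    out <- em_integrate(object$field, x0, omega, times, n_traj, seed)
  }
  out$state_names <- object$state_names
  attr(out, "seen_in_training") <- !is.na(hit)
  out
}

#' @export
simulate.end_nsde <- function(object, nsim = 50L, seed = 1L,
                              omega = numeric(0), ...) {
  predict(object, omega = omega, n_traj = nsim, seed = seed, ...)
}

#' Score a model's predictions against a reference grid
#'
#' For every omega of \code{grid}, simulates a predicted ensemble from the
#' observed initial states (matched trajectory count) and computes the
#' temporally decoupled squared W2 loss against the observed ensemble.
#'
#' @param model an \code{end_nsde} fit or any object with a
#'   \code{predict(object, omega, x0, times, n_traj, seed)} method
#'   returning a \code{trajectory_ensemble} (the baselines conform).
#' @param grid reference \code{param_grid}.
#' @param split which split tags of \code{grid} to score (default: all).
#' @param mask component mask for the loss.
#' @param seed integer seed for the predictive rollouts.
#' @return a \code{loss_report} with per-omega losses.
#' @export
evaluate_loss <- function(model, grid, split = NULL, mask = NULL, seed = 1L) {
  entries <- grid$entries
  if (!is.null(split)) entries <- Filter(function(e) e$split %in% split, entries)
  if (!length(entries)) stop("no grid entries in the requested split")
  mask <- mask %||% attr(grid, "mask")
  per_omega <- numeric(0)
  for (e in entries) {
    obs <- e$ensemble
    x0 <- matrix(obs$values[, 1L, ], n_traj(obs), state_dim(obs))
    pred <- predict(model, omega = obs$omega, x0 = x0, times = obs$times,
                    n_traj = n_traj(obs), seed = seed)
    per_omega[omega_key(e$omega)] <- temporal_w2_squared(obs, pred, mask)
  }
  structure(list(total = sum(per_omega), per_omega = per_omega, per_time = NULL),
            class = "loss_report")
}
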