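#' Comparator time-series models
#'
#' Four benchmark families trained on the same parameter-conditioned
#' ensembles and scored by the same extrinsic-noise W2 loss as the neural
#' SDE, each exposing the common
#' \code{predict(model, omega, x0, times, n_traj, seed)} contract:
#' \describe{
#'   \item{rnn, lstm}{sequence-to-sequence next-step predictors (one
#'     recurrent layer, teacher-forced mean-squared-error training on
#'     state increments, omega appended to every input) rolled out
#'     autoregressively; deterministic given (x0, omega).}
#'   \item{node}{a neural ODE: the drift network of the neural-SDE
#'     trainer with the diffusion fixed at zero, trained under the same
#'     W2 loss; deterministic.}
#'   \item{gp}{per-component Gaussian-process regression of the state on
#'     (t, omega) (RBF product kernel over standardized time and
#'     parameters, replicate ensembles collapsed to exact sufficient
#'     statistics, marginal-likelihood hyperparameters), predictions
#'     drawn i.i.d. from the per-time posterior predictive so the GP has
#'     a distribution to score under W2.}
#' }
#'
#' @param family one of \code{"rnn"}, \code{"lstm"}, \code{"node"},
#'   \code{"gp"}.
#' @param grid training \code{param_grid} (entries tagged train, or all).
#' @param config a \code{\link{run_config}}; \code{width} is the hidden
#'   width of the recurrent/neural families, \code{imax} their epochs.
#' @return object of class \code{c("baseline_<family>", "sde_baseline")}.
#' @export
fit_baseline <- function(family = c("rnn", "lstm", "node", "gp"),
                         grid, config = run_config()) {
  family <- match.arg(family)
  ens <- grid_ensembles(grid, "train")
  if (!length(ens)) ens <- grid_ensembles(grid)
  model <- switch(family,
    node = {
      fit <- end_nsde(grid, config, stochastic = FALSE)
      list(fit = fit)
    },
    rnn = fit_recurrent(ens, config, lstm = FALSE),
    lstm = fit_recurrent(ens, config, lstm = TRUE),
    gp = fit_gp(ens, config))
  structure(c(model, list(family = family, times = ens[[1L]]$times)),
            class = c(paste0("baseline_", family), "sde_baseline"))
}

#' @export
print.sde_baseline <- function(x, ...) {
  cat(sprintf("Baseline time-series model: %s\n", x$family))
  invisible(x)
}

#' @export
predict.sde_baseline <- function(object, omega = numeric(0), x0 = NULL,
                                 times = NULL, n_traj = 50L, seed = 1L, ...) {
  times <- times %||% object$times
  switch(object$family,
    node = {
      p <- predict(object$fit, omega = omega, x0 = x0, times = times,
                   n_traj = n_traj, seed = seed)
      p
    },
    rnn = ,
    lstm = recurrent_rollout(object, omega, x0, times, n_traj),
    gp = gp_draw(object, omega, times, n_traj, seed))
}

## ---- recurrent families -------------------------------------------------

fit_recurrent <- function(ens, config, lstm) {
  d <- state_dim(ens[[1L]]); p <- length(ens[[1L]]$omega)
  J <- n_times(ens[[1L]]); H <- config$width
  X <- do.call(rbind, lapply(ens, function(e) matrix(e$values, ncol = d)))
  mu_x <- colMeans(X); sd_x <- pmax(apply(X, 2, stats::sd), 1e-8)
  W0 <- do.call(rbind, lapply(ens, function(e)
    matrix(e$omega, n_traj(e), p, byrow = TRUE)))
  mu_w <- if (p) colMeans(W0) else numeric(0)
  sd_w <- if (p) pmax(apply(W0, 2, stats::sd), 1e-8) else numeric(0)

  # stacked (N, J, d) scaled states and scaled omega block
  vals <- do.call(abind3, lapply(ens, `[[`, "values"))
  N <- dim(vals)[1L]
  for (k in seq_len(d)) vals[, , k] <- (vals[, , k] - mu_x[k]) / sd_x[k]
  Ws <- if (p) sweep(sweep(W0, 2, mu_w), 2, sd_w, "/") else matrix(0, N, 0L)

  rng <- substream_rng(config$seed, "recurrent-init")
  sc <- function(nr, nc, s = 0.3) matrix(rng$rnorm(nr * nc) * s / sqrt(nr), nr, nc)
  ng <- if (lstm) 4L else 1L
  par <- list(Wx = sc(d + p, H * ng), Wh = sc(H, H * ng), bh = numeric(H * ng),
              Wo = sc(H, d, 0.1), bo = numeric(d))
  if (lstm) par$bh[H + seq_len(H)] <- 1   # forget-gate bias
  st <- adam_flat_init(par)

  for (epoch in seq_len(config$imax)) {
    fw <- recurrent_forward(par, vals, Ws, H, lstm)
    # teacher-forced next-step MSE on scaled increments
    G <- fw$pred
    loss <- 0
    for (j in seq_len(J - 1L)) {
      err <- fw$pred[[j]] - (vals[, j + 1L, ] - vals[, j, ])
      loss <- loss + sum(err^2)
      G[[j]] <- 2 * err / (N * (J - 1L))
    }
    gr <- recurrent_backward(par, fw, G, H, lstm)
    lr <- config$lr * if (epoch > 0.85 * config$imax) 0.1 else 1
    up <- adam_flat_step(par, gr, st, lr); par <- up$par; st <- up$st
  }
  list(par = par, H = H, lstm = lstm, d = d, p = p,
       norm = list(mu_x = mu_x, sd_x = sd_x, mu_w = mu_w, sd_w = sd_w))
}

abind3 <- function(...) {
  xs <- list(...)
  d23 <- dim(xs[[1L]])[2:3]
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1L], 0L)), d23))
  at <- 0L
  for (x in xs) { out[at + seq_len(dim(x)[1L]), , ] <- x; at <- at + dim(x)[1L] }
  out
}

# One recurrent layer over the whole batch; inputs are the *observed*
# scaled states (teacher forcing). Returns caches for BPTT.
recurrent_forward <- function(par, vals, Ws, H, lstm) {
  N <- dim(vals)[1L]; J <- dim(vals)[2L]
  h <- matrix(0, N, H); cst <- matrix(0, N, H)
  hs <- vector("list", J - 1L); cs <- vector("list", J - 1L)
  gates <- vector("list", J - 1L); inps <- vector("list", J - 1L)
  pred <- vector("list", J - 1L); hprev <- vector("list", J - 1L)
  for (j in seq_len(J - 1L)) {
    inp <- cbind(vals[, j, ], Ws)
    a <- inp %*% par$Wx + h %*% par$Wh + rep(par$bh, each = N)
    hprev[[j]] <- h
    if (lstm) {
      i <- stats::plogis(a[, seq_len(H)]); f <- stats::plogis(a[, H + seq_len(H)])
      o <- stats::plogis(a[, 2L * H + seq_len(H)]); g <- tanh(a[, 3L * H + seq_len(H)])
      cprev <- cst
      cst <- f * cprev + i * g
      tc <- tanh(cst)
      h <- o * tc
      gates[[j]] <- list(i = i, f = f, o = o, g = g, cprev = cprev, tc = tc)
    } else {
      h <- tanh(a)
    }
    hs[[j]] <- h; cs[[j]] <- cst; inps[[j]] <- inp
    pred[[j]] <- h %*% par$Wo + rep(par$bo, each = N)
  }
  list(hs = hs, cs = cs, gates = gates, inps = inps, pred = pred, hprev = hprev)
}

recurrent_backward <- function(par, fw, G, H, lstm) {
  J1 <- length(fw$pred)
  gr <- lapply(par, function(x) x * 0)
  dh_next <- matrix(0, nrow(G[[1L]]), H)
  dc_next <- dh_next
  for (j in J1:1L) {
    dh <- G[[j]] %*% t(par$Wo) + dh_next
    gr$Wo <- gr$Wo + crossprod(fw$hs[[j]], G[[j]])
    gr$bo <- gr$bo + colSums(G[[j]])
    if (lstm) {
      gt <- fw$gates[[j]]
      do <- dh * gt$tc
      dc <- dh * gt$o * (1 - gt$tc^2) + dc_next
      di <- dc * gt$g; df <- dc * gt$cprev; dg <- dc * gt$i
      dc_next <- dc * gt$f
      da <- cbind(di * gt$i * (1 - gt$i), df * gt$f * (1 - gt$f),
                  do * gt$o * (1 - gt$o), dg * (1 - gt$g^2))
    } else {
      da <- dh * (1 - fw$hs[[j]]^2)
    }
    gr$Wx <- gr$Wx + crossprod(fw$inps[[j]], da)
    gr$Wh <- gr$Wh + crossprod(fw$hprev[[j]], da)
    gr$bh <- gr$bh + colSums(da)
    dh_next <- da %*% t(par$Wh)
    if (!lstm) dc_next <- dc_next * 0
  }
  gr
}

recurrent_rollout <- function(object, omega, x0, times, n_traj) {
  d <- object$d; p <- object$p; H <- object$H; par <- object$par
  nm <- object$norm
  if (is.null(x0)) stop("recurrent baselines need initial states x0")
  X <- if (is.matrix(x0)) x0 else matrix(x0, n_traj, d, byrow = TRUE)
  n <- nrow(X)
  ws <- if (p) (as.numeric(omega) - nm$mu_w) / nm$sd_w else numeric(0)
  Ws <- matrix(ws, n, p, byrow = TRUE)
  J <- length(times)
  out <- array(NA_real_, c(n, J, d))
  out[, 1L, ] <- X
  xs <- sweep(sweep(X, 2, nm$mu_x), 2, nm$sd_x, "/")
  h <- matrix(0, n, H); cst <- matrix(0, n, H)
  for (j in seq_len(J - 1L)) {
    a <- cbind(xs, Ws) %*% par$Wx + h %*% par$Wh + rep(par$bh, each = n)
    if (object$lstm) {
      i <- stats::plogis(a[, seq_len(H)]); f <- stats::plogis(a[, H + seq_len(H)])
      o <- stats::plogis(a[, 2L * H + seq_len(H)]); g <- tanh(a[, 3L * H + seq_len(H)])
      cst <- f * cst + i * g
      h <- o * tanh(cst)
    } else h <- tanh(a)
    xs <- xs + h %*% par$Wo + rep(par$bo, each = n)
    out[, j + 1L, ] <- sweep(sweep(xs, 2, nm$sd_x, "*"), 2, nm$mu_x, "+")
  }
  trajectory_ensemble(times, out, as.numeric(omega))
}

## ---- Gaussian-process family -------------------------------------------

# Gaussian-process regression of each state component on (t, omega):
# RBF product kernel over standardized time and parameters, exact on the
# replicate-collapsed per-(omega, t) ensemble means (ybar ~ N(m, sn2/n_k),
# equivalent to regressing on all trajectories with iid noise).
# Hyperparameters (time/parameter lengthscales, signal variance) maximize
# the marginal likelihood, profiled on a time-thinned grid for speed; the
# noise variance is the within-ensemble variance at each design point.
# Predictions are i.i.d. draws from the per-time posterior predictive.
fit_gp <- function(ens, config) {
  d <- state_dim(ens[[1L]]); J <- n_times(ens[[1L]]); p <- length(ens[[1L]]$omega)
  if (!p) stop("the GP baseline conditions on omega; unconditioned grids are unsupported")
  Om <- do.call(rbind, lapply(ens, `[[`, "omega"))           # K x p distinct omegas
  sw <- pmax(apply(Om, 2, stats::sd), 1e-8)
  Os <- sweep(Om, 2, sw, "/")
  times <- ens[[1L]]$times
  ts <- (times - mean(times)) / max(stats::sd(times), 1e-8)
  K <- nrow(Om)
  nk <- vapply(ens, n_traj, 0L)
  ybar <- array(0, c(K, J, d)); yvar <- array(0, c(K, J, d))
  for (k in seq_len(K)) for (cc in seq_len(d)) {
    m <- matrix(ens[[k]]$values[, , cc], nk[k])
    ybar[k, , cc] <- colMeans(m)
    yvar[k, , cc] <- if (nk[k] > 1) apply(m, 2, stats::var) else 0
  }
  # design: rows = (omega k, time j), k fastest
  D2w <- as.matrix(stats::dist(Os))^2
  kern <- function(ellt, ellw, tsub) {
    Rt <- exp(-0.5 * outer(tsub, tsub, "-")^2 / ellt^2)
    kronecker(Rt, exp(-0.5 * D2w / ellw^2))
  }
  hyp <- matrix(NA_real_, d, 4L,
                dimnames = list(NULL, c("ellt", "ellw", "sf2", "mu")))
  chols <- vector("list", d); alphas <- vector("list", d)
  jthin <- unique(round(seq(1L, J, length.out = min(J, 17L))))
  for (cc in seq_len(d)) {
    ysub <- as.vector(ybar[, jthin, cc]); mu <- mean(ybar[, , cc])
    nsub <- rep(nk, length(jthin))
    vsub <- pmax(as.vector(yvar[, jthin, cc]), 1e-12)
    nll <- function(par) {
      Km <- exp(par[3L]) * kern(exp(par[1L]), exp(par[2L]), ts[jthin]) +
        diag(vsub / nsub)
      ch <- tryCatch(chol(Km), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      y <- ysub - mu
      sum(log(diag(ch))) + 0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
    }
    p0 <- c(log(0.3), log(max(stats::median(sqrt(D2w[D2w > 0])), 0.1)),
            log(max(stats::var(ysub), 1e-8)))
    fit <- stats::optim(p0, nll, method = "Nelder-Mead",
                        control = list(maxit = config$gp_maxit %||% 120L))
    ellt <- exp(fit$par[1L]); ellw <- exp(fit$par[2L]); sf2 <- exp(fit$par[3L])
    Km <- sf2 * kern(ellt, ellw, ts) +
      diag(pmax(as.vector(yvar[, , cc]), 1e-12) / rep(nk, J))
    ch <- chol(Km)
    y <- as.vector(ybar[, , cc]) - mu
    alphas[[cc]] <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
    chols[[cc]] <- ch
    hyp[cc, ] <- c(ellt, ellw, sf2, mu)
  }
  list(Om = Om, Os = Os, sw = sw, ts = ts, nk = nk, D2w = D2w,
       ybar = ybar, yvar = yvar, chols = chols, alphas = alphas, hyp = hyp,
       d = d, J = J)
}

gp_draw <- function(object, omega, times, n_traj, seed) {
  d <- object$d; J <- object$J
  os <- as.numeric(omega) / object$sw
  d2s <- colSums((t(object$Os) - os)^2)
  rng <- substream_rng(seed, "gp-draw")
  out <- array(NA_real_, c(n_traj, J, d))
  K <- nrow(object$Os)
  for (cc in seq_len(d)) {
    ellt <- object$hyp[cc, "ellt"]; ellw <- object$hyp[cc, "ellw"]
    sf2 <- object$hyp[cc, "sf2"]; mu <- object$hyp[cc, "mu"]
    kw <- exp(-0.5 * d2s / ellw^2)
    for (j in seq_len(J)) {
      kt <- exp(-0.5 * (object$ts[j] - object$ts)^2 / ellt^2)
      ks <- sf2 * as.vector(outer(kw, kt))      # k fastest, matching kron(Rt, Rw)
      mstar <- mu + sum(ks * object$alphas[[cc]])
      v <- backsolve(object$chols[[cc]], ks, transpose = TRUE)
      vlat <- max(sf2 - sum(v^2), 0)
      sn2 <- max(mean(object$yvar[, j, cc]), 1e-12)
      out[, j, cc] <- mstar + sqrt(vlat + sn2) * rng$rnorm(n_traj)
    }
  }
  trajectory_ensemble(times, out, as.numeric(omega))
}

#' Benchmark a set of models on a common test grid
#'
#' Scores every model with the identical extrinsic-noise-driven W2 loss
#' implementation (\code{\link{evaluate_loss}}) on the test entries of one
#' grid and returns the ranking, ascending in loss.
#'
#' @param models named list of fitted models (any mix of \code{end_nsde}
#'   and \code{sde_baseline} objects).
#' @param test_grid a \code{param_grid}; entries tagged \code{"test"} are
#'   scored (all entries if none is tagged).
#' @param mask loss component mask.
#' @param seed rollout seed shared by all models.
#' @return data.frame with columns model, loss (Eq.-8 sum over test
#'   omegas), mean_per_omega; sorted ascending by loss.
#' @export
benchmark_models <- function(models, test_grid, mask = NULL, seed = 1L) {
  split <- if (any(vapply(test_grid$entries, `[[`, "", "split") == "test")) "test" else NULL
  rows <- lapply(names(models), function(nm) {
    rep <- evaluate_loss(models[[nm]], test_grid, split = split, mask = mask, seed = seed)
    data.frame(model = nm, loss = rep$total, mean_per_omega = mean(rep$per_omega))
  })
  out <- do.call(rbind, rows)
  out[order(out$loss), , drop = FALSE]
}
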