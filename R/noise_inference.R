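#' Rank trajectories by similarity to a reference and group them
#'
#' Computes the cosine similarity of every trajectory's scalar readout to
#' the deterministic representative-cell reference, sorts descending, and
#' cuts the sorted order into consecutive blocks of size \code{g} (the
#' last block may be smaller). Cells whose dynamics deviate little from
#' the noise-free model land in low-rank groups, which the workflow
#' interprets as low intrinsic-noise cells.
#'
#' @param trajectories scalar-state \code{trajectory_ensemble} (or an
#'   \code{n x J} matrix) on the reference's grid.
#' @param reference numeric vector: the deterministic readout on the same
#'   grid.
#' @param g group size (>= 1).
#' @return list of \code{"trajectory_group"} objects: each has
#'   \code{values} (g x J matrix, similarity-sorted rows), \code{rank}
#'   (1 = most reference-like), \code{similarity} (per member) and
#'   \code{members} (row indices into the input).
#' @export
rank_and_group <- function(trajectories, reference, g) {
  stopifnot(g >= 1)
  M <- group_input_matrix(trajectories)
  if (!nrow(M)) stop("empty input")
  if (ncol(M) != length(reference)) stop("grid mismatch with reference")
  sim <- apply(M, 1L, cosine_similarity, traj_b = reference)
  ord <- order(sim, decreasing = TRUE)
  starts <- seq(1L, length(ord), by = g)
  lapply(seq_along(starts), function(b) {
    ii <- ord[starts[b]:min(starts[b] + g - 1L, length(ord))]
    structure(list(values = M[ii, , drop = FALSE], rank = b,
                   similarity = sim[ii], members = ii),
              class = "trajectory_group")
  })
}

group_input_matrix <- function(trajectories) {
  if (inherits(trajectories, "trajectory_ensemble")) {
    if (state_dim(trajectories) != 1L)
      stop("grouping operates on scalar readouts; extract one first")
    matrix(trajectories$values[, , 1L], n_traj(trajectories), n_times(trajectories))
  } else as.matrix(trajectories)
}

# Order-invariant featurization of a group: per-time mean and standard
# deviation, plus per-time order statistics (rows sorted by value at each
# time). Invariant to within-group trajectory order by construction.
group_features <- function(values) {
  v <- as.matrix(values)
  qs <- apply(v, 2L, sort)
  if (is.null(dim(qs))) qs <- matrix(qs, 1L)
  sds <- if (nrow(v) > 1L) apply(v, 2L, stats::sd) else numeric(ncol(v))
  c(colMeans(v), sds, as.vector(qs))
}

#' Train a noise-intensity regression network
#'
#' Learns to map a fixed-size group of scalar trajectories to the pair of
#' noise intensities \eqn{(\sigma_1, \sigma_2)} that generated them, from
#' labeled synthetic groups. Features are order-invariant (per-time mean,
#' standard deviation and order statistics); the network is a multilayer
#' perceptron trained by Adam on mean squared error in
#' \eqn{\log_{10}\sigma}, so predictions are positive by construction.
#'
#' @param groups list of group matrices (each \code{g x J}) or
#'   \code{trajectory_group} objects.
#' @param labels matrix with one (sigma1, sigma2) row per group.
#' @param config a \code{\link{run_config}} (width, depth, lr, imax, seed).
#' @return object of class \code{"noise_net"} with a
#'   \code{\link{infer_noise}} method-like interface.
#' @export
fit_noise_net <- function(groups, labels, config = run_config(imax = 400L)) {
  labels <- matrix(as.numeric(labels), ncol = 2L)
  stopifnot(length(groups) == nrow(labels), all(labels > 0))
  feats <- t(vapply(groups, function(gr)
    group_features(if (inherits(gr, "trajectory_group")) gr$values else gr),
    numeric(length(group_features(
      if (inherits(groups[[1L]], "trajectory_group")) groups[[1L]]$values else groups[[1L]])))))
  mu <- colMeans(feats); sd <- pmax(apply(feats, 2L, stats::sd), 1e-8)
  Xs <- sweep(sweep(feats, 2L, mu), 2L, sd, "/")
  Y <- log10(labels)
  my <- colMeans(Y); sy <- pmax(apply(Y, 2L, stats::sd), 1e-8)
  Ys <- sweep(sweep(Y, 2L, my), 2L, sy, "/")
  rng <- substream_rng(config$seed, "noise-net")
  net <- mlp_init(ncol(Xs), 2L, config$width, config$depth, rng, out_scale = 0.5)
  st <- adam_init(net)
  n <- nrow(Xs)
  for (epoch in seq_len(config$imax)) {
    fw <- mlp_forward(net, Xs, cache = TRUE)
    G <- 2 * (fw$out - Ys) / n
    bw <- mlp_backward(net, fw, G)
    lr <- config$lr * if (epoch > 0.85 * config$imax) 0.1 else 1
    up <- adam_step(net, bw, st, lr); net <- up$net; st <- up$st
  }
  structure(list(net = net, mu = mu, sd = sd, my = my, sy = sy,
                 group_size = nrow(if (inherits(groups[[1L]], "trajectory_group"))
                   groups[[1L]]$values else as.matrix(groups[[1L]]))),
            class = "noise_net")
}

#' Infer noise intensities for groups of trajectories
#'
#' @param noise_net a fitted \code{\link{fit_noise_net}} model.
#' @param groups list of group matrices or \code{trajectory_group}s
#'   (group size should match the training size; smaller terminal groups
#'   are padded by recycling members).
#' @return list of \code{"noise_estimate"} objects: \code{sigma1_hat},
#'   \code{sigma2_hat}, \code{rank} (when available).
#' @export
infer_noise <- function(noise_net, groups) {
  lapply(groups, function(gr) {
    v <- if (inherits(gr, "trajectory_group")) gr$values else as.matrix(gr)
    g0 <- noise_net$group_size
    if (nrow(v) < g0) v <- v[rep_len(seq_len(nrow(v)), g0), , drop = FALSE]
    x <- (group_features(v) - noise_net$mu) / noise_net$sd
    z <- mlp_forward(noise_net$net, matrix(x, 1L))
    s <- 10^(z[1L, ] * noise_net$sy + noise_net$my)
    structure(list(sigma1_hat = s[1L], sigma2_hat = s[2L],
                   rank = if (inherits(gr, "trajectory_group")) gr$rank else NA_integer_),
              class = "noise_estimate")
  })
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("Noise estimate: sigma1 = %.4g, sigma2 = %.4g%s\n",
              x$sigma1_hat, x$sigma2_hat,
              if (is.na(x$rank)) "" else sprintf(" (group rank %d)", x$rank)))
  invisible(x)
}

#' Relative error of a noise estimate against known truth
#'
#' Mean over the two components of \eqn{|\hat\sigma - \sigma| / \sigma}
#' on the linear scale (defined only for labeled synthetic data).
#'
#' @param estimate a \code{noise_estimate} (or list with sigma1_hat,
#'   sigma2_hat).
#' @param truth length-2 positive vector \code{(sigma1, sigma2)}.
#' @param log_scale if TRUE, use \eqn{|\log\hat\sigma - \log\sigma| /
#'   |\log\sigma|} instead.
#' @return nonnegative scalar; 0 iff exact.
#' @export
noise_relative_error <- function(estimate, truth, log_scale = FALSE) {
  truth <- as.numeric(truth)
  if (any(truth <= 0)) stop("truth components must be positive")
  est <- c(estimate$sigma1_hat, estimate$sigma2_hat)
  if (log_scale) mean(abs(log10(est) - log10(truth)) / abs(log10(truth)))
  else mean(abs(est - truth) / truth)
}

#' Reconstruct grouped trajectories with inferred noise
#'
#' Completes the inference workflow: for each group, infer
#' \eqn{(\hat\sigma_1, \hat\sigma_2)}, drive the trained neural SDE with
#' them (matched ensemble size, initial states resolved per
#' \code{x0_resolver}), and score the simulated readout against the group
#' by the temporally decoupled squared W2 loss.
#'
#' @param groups list of \code{trajectory_group}s on grid \code{times}.
#' @param noise_net fitted \code{\link{fit_noise_net}}.
#' @param model trained \code{end_nsde} over the full (latent-bearing)
#'   state.
#' @param times the groups' time grid.
#' @param readout_fn function mapping a full-state predicted ensemble to
#'   its scalar readout ensemble (default \code{\link{nfkb_readout}}).
#' @param seed rollout seed.
#' @return data.frame with one row per group: rank, sigma1_hat,
#'   sigma2_hat, w2.
#' @export
reconstruct_with_inferred_noise <- function(groups, noise_net, model, times,
                                            readout_fn = nfkb_readout, seed = 1L) {
  est <- infer_noise(noise_net, groups)
  rows <- lapply(seq_along(groups), function(i) {
    gr <- groups[[i]]
    pred <- predict(model, omega = c(est[[i]]$sigma1_hat, est[[i]]$sigma2_hat),
                    times = times, n_traj = nrow(gr$values), seed = seed)
    pred_r <- readout_fn(pred)
    obs <- trajectory_ensemble(times, array(gr$values, c(dim(gr$values), 1L)),
                               omega = pred_r$omega)
    data.frame(rank = gr$rank,
               sigma1_hat = est[[i]]$sigma1_hat, sigma2_hat = est[[i]]$sigma2_hat,
               w2 = temporal_w2_squared(obs, pred_r))
  })
  do.call(rbind, rows)
}
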