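#' Relative error of a reconstructed drift function
#'
#' Both fields are evaluated at the observed states of the ensemble
#' (teacher-forced evaluation, which pairs trajectory indices coherently);
#' for each trajectory the l1 deviation summed over the grid is divided by
#' the summed l1 magnitude of the true drift along that trajectory, and
#' the per-trajectory ratios are averaged. Trajectories with an all-zero
#' true drift are excluded with a warning.
#'
#' @param true_field,learned_field \code{\link{sde_field}}s evaluable at
#'   the ensemble's states and omega.
#' @param ensemble a \code{trajectory_ensemble} supplying states and omega.
#' @return nonnegative scalar (0 when the fields agree on the data).
#' @export
drift_error <- function(true_field, learned_field, ensemble) {
  v <- ensemble$values; om <- ensemble$omega
  n <- dim(v)[1L]; J <- dim(v)[2L]; d <- dim(v)[3L]
  X <- matrix(v, n * J, d)
  num <- rowSums(abs(true_field$drift(X, om) - learned_field$drift(X, om)))
  den <- rowSums(abs(true_field$drift(X, om)))
  num <- rowSums(matrix(num, n, J)); den <- rowSums(matrix(den, n, J))
  ok <- den > 0
  if (!all(ok)) warning(sum(!ok), " trajectories with all-zero true drift excluded")
  if (!any(ok)) stop("true drift vanishes on every trajectory")
  mean(num[ok] / den[ok])
}

# sigma sigma^T for a stacked diffusion output (rows = samples, columns =
# column-major d x m matrices); returns rows of column-major d x d.
sigma_sq <- function(S, d, m) {
  out <- matrix(0, nrow(S), d * d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    acc <- 0
    for (k in seq_len(m))
      acc <- acc + S[, (k - 1L) * d + i] * S[, (k - 1L) * d + j]
    out[, (j - 1L) * d + i] <- acc
  }
  out
}

#' Relative error of a reconstructed diffusion function
#'
#' Diffusion matrices are compared through \eqn{\sigma\sigma^T} (the only
#' identified quantity: any right-orthogonal refactoring leaves it
#' unchanged), entrywise-absolute, under the matrix norm
#' \eqn{\|A\|_m = \sum_{ij} |A_{ij}|}: per trajectory, the grid-summed
#' norm of \eqn{|\sigma\sigma^T| - |\hat\sigma\hat\sigma^T|} is divided by
#' the grid-summed norm of \eqn{\sigma\sigma^T}, and ratios are averaged
#' over trajectories.
#'
#' @inheritParams drift_error
#' @return nonnegative scalar.
#' @export
diffusion_error <- function(true_field, learned_field, ensemble) {
  v <- ensemble$values; om <- ensemble$omega
  n <- dim(v)[1L]; J <- dim(v)[2L]; d <- dim(v)[3L]
  X <- matrix(v, n * J, d)
  A <- sigma_sq(true_field$diffusion(X, om), d, true_field$noise_dim)
  B <- sigma_sq(learned_field$diffusion(X, om), d, learned_field$noise_dim)
  num <- rowSums(abs(abs(A) - abs(B)))
  den <- rowSums(abs(A))
  num <- rowSums(matrix(num, n, J)); den <- rowSums(matrix(den, n, J))
  ok <- den > 0
  if (!all(ok)) warning(sum(!ok), " trajectories with all-zero true diffusion excluded")
  if (!any(ok)) stop("true diffusion vanishes on every trajectory")
  mean(num[ok] / den[ok])
}

#' Per-omega error report for a trained model
#'
#' Convenience wrapper computing the relative drift error, relative
#' diffusion error and predictive W2 loss for every omega of a reference
#' grid, plus their grid means.
#'
#' @param model an \code{end_nsde} fit.
#' @param grid reference \code{param_grid}.
#' @param true_field_fn function(omega vector) returning the ground-truth
#'   \code{sde_field} at that omega.
#' @param mask loss mask, as elsewhere.
#' @param seed seed for predictive rollouts.
#' @return object of class \code{"error_report"}: data.frame with one row
#'   per omega (columns: omega components, drift_error, diffusion_error,
#'   w2, split) and attribute \code{"means"}.
#' @export
error_report <- function(model, grid, true_field_fn, mask = NULL, seed = 1L) {
  rows <- list()
  for (e in grid$entries) {
    ens <- e$ensemble
    tf <- true_field_fn(e$omega)
    x0 <- matrix(ens$values[, 1L, ], n_traj(ens), state_dim(ens))
    pred <- predict(model, omega = ens$omega, x0 = x0, times = ens$times,
                    n_traj = n_traj(ens), seed = seed)
    om <- as.list(ens$omega)
    names(om) <- ens$param_names %||% paste0("omega_", seq_along(ens$omega))
    rows[[length(rows) + 1L]] <- data.frame(
      om,
      drift_error = drift_error(tf, model$field, ens),
      diffusion_error = diffusion_error(tf, model$field, ens),
      w2 = temporal_w2_squared(ens, pred, mask %||% attr(grid, "mask")),
      split = e$split)
  }
  out <- do.call(rbind, rows)
  attr(out, "means") <- c(drift_error = mean(out$drift_error),
                          diffusion_error = mean(out$diffusion_error),
                          w2 = mean(out$w2))
  class(out) <- c("error_report", "data.frame")
  out
}

#' @export
print.error_report <- function(x, ...) {
  m <- attr(x, "means")
  NextMethod()
  cat(sprintf("\nGrid means: drift %.4g, diffusion %.4g, W2 %.4g\n",
              m["drift_error"], m["diffusion_error"], m["w2"]))
  invisible(x)
}

#' Cosine similarity between two trajectories
#'
#' Inner product over the product of norms, on readouts sampled at a
#' common grid. Used to rank measured cells by their similarity to the
#' deterministic representative-cell trajectory.
#'
#' @param traj_a,traj_b numeric vectors of equal length with nonzero norm.
#' @return scalar in [-1, 1].
#' @export
cosine_similarity <- function(traj_a, traj_b) {
  if (length(traj_a) != length(traj_b)) stop("lengths differ")
  na <- sqrt(sum(traj_a^2)); nb <- sqrt(sum(traj_b^2))
  if (na == 0 || nb == 0) stop("zero-norm trajectory")
  sum(traj_a * traj_b) / (na * nb)
}

#' Long-format table of per-omega metrics
#'
#' Flattens per-omega reports into a long table (omega components, metric,
#' value, split) suitable for heatmap plotting; heldout omegas keep their
#' tag so they can be rendered as blank cells.
#'
#' @param report an \code{\link{error_report}} (or compatible data.frame
#'   with omega columns, metric columns and a split column).
#' @param metrics which metric columns to keep.
#' @return long-format data.frame.
#' @export
heatmap_table <- function(report, metrics = c("drift_error", "diffusion_error", "w2")) {
  report <- as.data.frame(report)
  if (!nrow(report))
    return(data.frame(metric = character(0), value = numeric(0), split = character(0)))
  metrics <- intersect(metrics, names(report))
  omcols <- setdiff(names(report), c(metrics, "split"))
  out <- list()
  for (m in metrics)
    out[[m]] <- data.frame(report[omcols], metric = m, value = report[[m]],
                           split = report$split %||% "train", row.names = NULL)
  do.call(rbind, out)
}
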