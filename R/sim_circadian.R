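#' Parameters of the damped-oscillator circadian clock SDE
#'
#' The minimal stochastic model of per-gene circadian dynamics: a linear
#' rotation-damping drift \eqn{(-\alpha x - \beta y,\ \beta x - \alpha y)}
#' for the dimensionless mRNA (\eqn{x}) and protein (\eqn{y})
#' concentrations, driven by two independent Wiener processes through one
#' of four diffusion forms:
#' \describe{
#'   \item{const}{\eqn{\sigma_0 [[1, c], [c, 1]]} — additive noise.}
#'   \item{langevin}{\eqn{\sigma_0 [[|x|, c|y|], [c|x|, |y|]]} —
#'     multiplicative, magnitude-coupled.}
#'   \item{linear}{\eqn{\sigma_0 [[x, c|y|], [c|x|, y]]} — multiplicative
#'     with signed diagonal entries (the sign asymmetry between the signed
#'     diagonal and absolute off-diagonal entries is part of the model).}
#'   \item{eq_ext}{diagonal \eqn{((\sigma_0+\sigma_1 k_1)x,
#'     (\sigma_0+\sigma_1 k_2)y)} — an intrinsic/extrinsic-noise split
#'     where \eqn{\sigma_0} sets the average intrinsic level,
#'     \eqn{\sigma_1} the extrinsic spread, and \eqn{(k_1,k_2)} the
#'     per-group extrinsic coefficients.}
#' }
#'
#' @param alpha damping rate (> 0, per unit time); default 0.19.
#' @param beta angular frequency (> 0, per unit time); default 0.21.
#' @param diffusion_form one of \code{"const"}, \code{"langevin"},
#'   \code{"linear"}, \code{"eq_ext"}.
#' @param sigma0 intrinsic noise intensity (>= 0).
#' @param c_corr cross-correlation coefficient of the two noise channels
#'   (forms const/langevin/linear).
#' @param sigma1,k1,k2 extrinsic-noise strength and per-group coefficients
#'   (form \code{eq_ext} only; \code{k1, k2} in [-1, 1]).
#' @return object of class \code{"circadian_params"}.
#' @export
circadian_params <- function(alpha = 0.19, beta = 0.21,
                             diffusion_form = c("const", "langevin", "linear", "eq_ext"),
                             sigma0 = 0.1, c_corr = 0.2,
                             sigma1 = 0, k1 = 0, k2 = 0) {
  diffusion_form <- match.arg(diffusion_form)
  stopifnot(alpha > 0, beta > 0, sigma0 >= 0)
  if (diffusion_form == "eq_ext") stopifnot(sigma1 >= 0, abs(k1) <= 1, abs(k2) <= 1)
  structure(list(alpha = alpha, beta = beta, diffusion_form = diffusion_form,
                 sigma0 = sigma0, c_corr = c_corr,
                 sigma1 = sigma1, k1 = k1, k2 = k2),
            class = "circadian_params")
}

#' Diffusion matrix of the circadian SDE at a state
#'
#' @param params a \code{\link{circadian_params}} with
#'   \code{diffusion_form} in const/langevin/linear (the extrinsic form is
#'   diagonal and routed through its own field).
#' @param x,y state coordinates.
#' @return the 2x2 diffusion matrix \eqn{[\xi_{x1}, \xi_{x2};
#'   \xi_{y1}, \xi_{y2}]}.
#' @export
circadian_diffusion_matrix <- function(params, x, y) {
  s0 <- params$sigma0; cc <- params$c_corr
  switch(params$diffusion_form,
    const    = s0 * matrix(c(1, cc, cc, 1), 2, byrow = TRUE),
    langevin = s0 * matrix(c(abs(x), cc * abs(y), cc * abs(x), abs(y)), 2, byrow = TRUE),
    linear   = s0 * matrix(c(x, cc * abs(y), cc * abs(x), y), 2, byrow = TRUE),
    stop("diffusion_form '", params$diffusion_form,
         "' has a diagonal extrinsic field; use circadian_field()"))
}

#' Ground-truth SDE field of the circadian model
#'
#' Exposes the generator as an \code{\link{sde_field}} so the evaluation
#' metrics can compare it with a learned field on equal terms.
#'
#' @param params a \code{\link{circadian_params}}.
#' @return an \code{sde_field} with d = 2 states and m = 2 Wiener channels.
#' @export
circadian_field <- function(params) {
  a <- params$alpha; b <- params$beta
  s0 <- params$sigma0; cc <- params$c_corr
  drift <- function(X, omega) cbind(-a * X[, 1L] - b * X[, 2L],
                                     b * X[, 1L] - a * X[, 2L])
  diffusion <- switch(params$diffusion_form,
    const = function(X, omega) {
      n <- nrow(X)
      cbind(rep(s0, n), rep(s0 * cc, n), rep(s0 * cc, n), rep(s0, n))
    },
    langevin = function(X, omega)
      s0 * cbind(abs(X[, 1L]), cc * abs(X[, 1L]), cc * abs(X[, 2L]), abs(X[, 2L])),
    linear = function(X, omega)
      s0 * cbind(X[, 1L], cc * abs(X[, 1L]), cc * abs(X[, 2L]), X[, 2L]),
    eq_ext = function(X, omega) {
      g1 <- params$sigma0 + params$sigma1 * params$k1
      g2 <- params$sigma0 + params$sigma1 * params$k2
      cbind(g1 * X[, 1L], 0 * X[, 1L], 0 * X[, 2L], g2 * X[, 2L])
    })
  sde_field(drift, diffusion, state_dim = 2L, param_dim = 2L, noise_dim = 2L)
}

#' Simulate the circadian SDE
#'
#' Euler--Maruyama with two independent Wiener streams. The ensemble's
#' omega is \code{(sigma0, c_corr)} for the const/langevin/linear forms
#' and \code{(k1, k2)} for the extrinsic form.
#'
#' @param params a \code{\link{circadian_params}}.
#' @param x0 initial state, default \code{c(0, 1)}.
#' @param times output grid, default 51 points on [0, 1] (step 0.02).
#' @param n_traj trajectories to draw.
#' @param seed integer seed.
#' @return a \code{trajectory_ensemble}.
#' @export
circadian_simulate <- function(params, x0 = c(0, 1),
                               times = seq(0, 1, by = 0.02),
                               n_traj = 50L, seed = 1L) {
  field <- circadian_field(params)
  omega <- if (params$diffusion_form == "eq_ext") c(params$k1, params$k2)
           else c(params$sigma0, params$c_corr)
  e <- em_integrate(field, x0, omega, times, n_traj, seed)
  e$state_names <- c("x", "y")
  e$param_names <- if (params$diffusion_form == "eq_ext") c("k1", "k2") else c("sigma0", "c")
  e
}

#' Reference circadian dataset over the (sigma0, c) grid
#'
#' The study conditions for the circadian benchmark: 25 combinations
#' \eqn{(\sigma_0, c) = (0.1 + 0.05 i,\ 0.2 + 0.2 j)},
#' \eqn{i, j \in \{0,\dots,4\}}, 50 trajectories each, \eqn{t \in [0,1]}
#' from \eqn{(x_0, y_0) = (0, 1)}, with \eqn{\alpha = 0.19},
#' \eqn{\beta = 0.21}.
#'
#' @param form diffusion form: const, langevin or linear.
#' @param seed integer seed.
#' @param n_traj trajectories per combination (defaults to the study's 50).
#' @param sigma0_values,c_values optional grid overrides (defaults above).
#' @return a \code{param_grid} with \code{noise_dim} attribute 2.
#' @export
circadian_grid_dataset <- function(form = c("const", "langevin", "linear"),
                                   seed = 1L, n_traj = 50L,
                                   sigma0_values = 0.1 + 0.05 * 0:4,
                                   c_values = 0.2 + 0.2 * 0:4) {
  form <- match.arg(form)
  ens <- list()
  k <- 0L
  for (s0 in sigma0_values) for (cc in c_values) {
    k <- k + 1L
    p <- circadian_params(diffusion_form = form, sigma0 = s0, c_corr = cc)
    ens[[k]] <- circadian_simulate(p, n_traj = n_traj, seed = seed + 1000L * k)
  }
  g <- param_grid(ens, "train")
  attr(g, "noise_dim") <- 2L
  attr(g, "form") <- form
  g
}

#' Extrinsic-noise circadian dataset over the (k1, k2) grid
#'
#' 25 groups \eqn{(k_1, k_2) \in \{0, \pm 0.5, \pm 1\}^2} with 50
#' trajectories each under the diagonal intrinsic/extrinsic diffusion;
#' \code{sigma0} and \code{sigma1} are recorded as grid attributes.
#'
#' @param sigma0 intrinsic noise level (>= 0).
#' @param sigma1 extrinsic noise strength (>= 0).
#' @param seed integer seed.
#' @param n_traj trajectories per group.
#' @return a \code{param_grid} keyed by \code{(k1, k2)}.
#' @export
circadian_ext_dataset <- function(sigma0 = 0.1, sigma1 = 0.1, seed = 1L,
                                  n_traj = 50L) {
  stopifnot(sigma0 >= 0, sigma1 >= 0)
  ks <- c(-1, -0.5, 0, 0.5, 1)
  ens <- list(); i <- 0L
  for (k1 in ks) for (k2 in ks) {
    i <- i + 1L
    p <- circadian_params(diffusion_form = "eq_ext", sigma0 = sigma0,
                          sigma1 = sigma1, k1 = k1, k2 = k2)
    ens[[i]] <- circadian_simulate(p, n_traj = n_traj, seed = seed + 1000L * i)
  }
  g <- param_grid(ens, "train")
  attr(g, "noise_dim") <- 2L
  attr(g, "sigma0") <- sigma0
  attr(g, "sigma1") <- sigma1
  g
}
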