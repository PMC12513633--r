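#' Parameters of the stochastic NF-kB signalling core
#'
#' The core converts three components of a high-dimensional NF-kB
#' signalling ODE model into SDEs: IkBa mRNA (u6), cytoplasmic free NF-kB
#' (u9) and nuclear NF-kB (u10). Transcription of IkBa carries Brownian
#' noise of intensity \code{sigma1} (on u6) and nucleocytoplasmic NF-kB
#' translocation carries intensity \code{sigma2}, entering u9 and u10 with
#' opposite signs through one shared Wiener increment, so translocation
#' noise moves molecules between compartments without creating them.
#'
#' Kinetic constants (all >= 0, time in minutes, concentrations in
#' arbitrary units): \code{kbasal}/\code{kmax}/\code{K_NFkB}/\code{n_NFkB}
#' parameterize basal plus Hill-activated IkBa transcription driven by
#' transcription-ready nuclear NF-kB (u52); \code{kdeg} degrades the mRNA;
#' \code{kimp}/\code{kexp} are nuclear import/export rates with
#' nuclear-to-cytoplasmic volume ratio \code{v};
#' \code{ka_IkB_NFkB}/\code{kd_IkB_NFkB} associate/dissociate IkBa with
#' NF-kB (cytoplasmic IkBa u2, nuclear IkBa u3, complexes u4 and u5);
#' \code{kdeg_NFkB} degrades free NF-kB; \code{kphos} releases NF-kB from
#' the IKK-bound complex u7. Defaults are the bundled stand-in's values,
#' not literature estimates; for the published high-dimensional model,
#' supply its constants via this constructor and its right-hand side via
#' the latent interface.
#'
#' @param kbasal,kmax,K_NFkB,n_NFkB,kdeg,kimp,kexp,ka_IkB_NFkB,kd_IkB_NFkB,kdeg_NFkB,kphos,v
#'   kinetic constants as described above.
#' @param sigma1 IkBa-transcription noise intensity (>= 0).
#' @param sigma2 NF-kB-translocation noise intensity (>= 0).
#' @return object of class \code{"nfkb_params"}.
#' @export
nfkb_params <- function(kbasal = 5e-4, kmax = 0.06, K_NFkB = 0.12, n_NFkB = 2,
                        kdeg = 0.035, kimp = 0.01, kexp = 0.05,
                        ka_IkB_NFkB = 0.6, kd_IkB_NFkB = 0.03,
                        kdeg_NFkB = 0.02, kphos = 0.06, v = 3,
                        sigma1 = 0, sigma2 = 0) {
  p <- as.list(environment())
  stopifnot(all(unlist(p) >= 0), n_NFkB >= 1)
  structure(p, class = "nfkb_params")
}

#' Drift of the three stochastic core components
#'
#' Evaluates the deterministic part of the (u6, u9, u10) SDEs at given
#' full states:
#' \deqn{du_6 = k_{basal} + k_{max} u_{52}^n / (u_{52}^n + K^n) - k_{deg} u_6}
#' \deqn{du_9 = k_{imp} u_9 - k_a u_2 u_9 - k_{deg,N} u_9 + v^{-1} k_{exp} u_{10} + k_d u_4 + k_{phos} u_7}
#' \deqn{du_{10} = -k_{exp} u_{10} - k_a u_3 u_{10} + v k_{imp} u_9 + k_d u_5}
#'
#' @param U numeric matrix of full states (one row per sample) with named
#'   columns including u2, u3, u4, u5, u6, u7, u9, u10, u52; a named
#'   vector is accepted for a single state.
#' @param params an \code{\link{nfkb_params}}.
#' @return matrix with columns \code{du6}, \code{du9}, \code{du10}.
#' @export
nfkb_drift_core <- function(U, params) {
  if (is.null(dim(U))) U <- matrix(U, 1L, dimnames = list(NULL, names(U)))
  if (any(U[, "u52"] < 0)) stop("negative Hill argument u52")
  p <- params
  hill <- U[, "u52"]^p$n_NFkB / (U[, "u52"]^p$n_NFkB + p$K_NFkB^p$n_NFkB)
  hill[U[, "u52"] == 0] <- 0
  du6 <- p$kbasal + p$kmax * hill - p$kdeg * U[, "u6"]
  du9 <- p$kimp * U[, "u9"] - p$ka_IkB_NFkB * U[, "u2"] * U[, "u9"] -
    p$kdeg_NFkB * U[, "u9"] + p$kexp / p$v * U[, "u10"] +
    p$kd_IkB_NFkB * U[, "u4"] + p$kphos * U[, "u7"]
  du10 <- -p$kexp * U[, "u10"] - p$ka_IkB_NFkB * U[, "u3"] * U[, "u10"] +
    p$v * p$kimp * U[, "u9"] + p$kd_IkB_NFkB * U[, "u5"]
  out <- cbind(du6 = du6, du9 = du9, du10 = du10)
  if (!all(is.finite(out))) stop("non-finite core drift")
  out
}

#' Bundled latent dynamics: a low-dimensional IkBa--NF-kB feedback stand-in
#'
#' The published high-dimensional NF-kB model supplies 49 latent ODE
#' components; this package consumes any such right-hand side through the
#' interface returned here. The bundled object is a synthetic stand-in: a
#' stable 9-component negative-feedback loop (IkBa mRNA translation,
#' nuclear import of IkBa, complex formation in both compartments,
#' IKK-mediated complex processing under a constant TNF dose folded into
#' \code{kikk}, and a transcription-ready pool u52 tracking nuclear NF-kB)
#' that makes every workflow runnable without the literature model. It
#' emulates the feedback topology, not the published kinetics.
#'
#' @param params an \code{\link{nfkb_params}} (shared constants).
#' @param ktl,kdeg2,kin,kdeg3,kikk,ke5,kpol,kpoff stand-in rate constants:
#'   IkBa translation, cytoplasmic IkBa degradation, IkBa nuclear import,
#'   nuclear IkBa degradation, IKK processing of the cytoplasmic complex,
#'   nuclear-complex export/decay, loading and unloading of the
#'   transcription-ready NF-kB pool.
#' @return object of class \code{"nfkb_latent"}: list with
#'   \code{state_names}, \code{latent_names}, \code{u0} (a rested initial
#'   state with most NF-kB sequestered in the cytoplasmic complex), and
#'   \code{rhs(U, t)} returning latent derivatives.
#' @export
nfkb_standin_latent <- function(params = nfkb_params(), ktl = 0.5, kdeg2 = 0.02,
                                kin = 0.06, kdeg3 = 0.02, kikk = 0.04,
                                ke5 = 0.01, kpol = 0.25, kpoff = 0.6) {
  state_names <- c("u2", "u3", "u4", "u5", "u6", "u7", "u9", "u10", "u52")
  latent_names <- c("u2", "u3", "u4", "u5", "u7", "u52")
  p <- params
  rhs <- function(U, t) {
    d2 <- ktl * U[, "u6"] - p$ka_IkB_NFkB * U[, "u2"] * U[, "u9"] - kdeg2 * U[, "u2"] -
      kin * U[, "u2"]
    d3 <- kin * U[, "u2"] - p$ka_IkB_NFkB * U[, "u3"] * U[, "u10"] - kdeg3 * U[, "u3"]
    d4 <- p$ka_IkB_NFkB * U[, "u2"] * U[, "u9"] - p$kd_IkB_NFkB * U[, "u4"] -
      kikk * U[, "u4"]
    d5 <- p$ka_IkB_NFkB * U[, "u3"] * U[, "u10"] - p$kd_IkB_NFkB * U[, "u5"] -
      ke5 * U[, "u5"]
    d7 <- kikk * U[, "u4"] - p$kphos * U[, "u7"]
    d52 <- kpol * U[, "u10"] - kpoff * U[, "u52"]
    cbind(u2 = d2, u3 = d3, u4 = d4, u5 = d5, u7 = d7, u52 = d52)
  }
  u0 <- c(u2 = 0.02, u3 = 0.01, u4 = 0.8, u5 = 0.02, u6 = 0.01,
          u7 = 0.05, u9 = 0.02, u10 = 0.01, u52 = 0.005)
  structure(list(state_names = state_names, latent_names = latent_names,
                 u0 = u0, rhs = rhs),
            class = "nfkb_latent")
}

# Full-system SDE field: latent components advance deterministically, the
# core (u6, u9, u10) carries the two noise channels.
nfkb_field <- function(params, latent) {
  sn <- latent$state_names
  i6 <- match("u6", sn); i9 <- match("u9", sn); i10 <- match("u10", sn)
  il <- match(latent$latent_names, sn)
  d <- length(sn)
  drift <- function(X, omega) {
    colnames(X) <- sn
    out <- matrix(0, nrow(X), d)
    out[, il] <- latent$rhs(X, NA_real_)
    core <- nfkb_drift_core(X, params)
    out[, i6] <- core[, "du6"]; out[, i9] <- core[, "du9"]; out[, i10] <- core[, "du10"]
    out
  }
  diffusion <- function(X, omega) {
    n <- nrow(X)
    s1 <- omega[1L]; s2 <- omega[2L]
    S <- matrix(0, n, d * 2L)
    S[, i6] <- s1                 # +sigma1 dB1 on u6
    S[, d + i9] <- -s2            # -sigma2 dB2 on u9
    S[, d + i10] <- s2            # +sigma2 dB2 on u10 (same increment)
    S
  }
  sde_field(drift, diffusion, state_dim = d, param_dim = 2L, noise_dim = 2L,
            latent_mask = match(c("u5", "u10"), sn))
}

#' Simulate the stochastic NF-kB system
#'
#' Euler--Maruyama on the full state: latent components advance by the
#' latent right-hand side (no noise); u6, u9, u10 advance with the core
#' drift plus noise (+sigma1 dB1 on u6; -sigma2 dB2 on u9 and +sigma2 dB2
#' on u10 sharing one Wiener increment). Concentrations are clamped at 0
#' after each step. With sigma1 = sigma2 = 0 the output is the
#' deterministic representative-cell trajectory.
#'
#' @param params an \code{\link{nfkb_params}} (its sigma1/sigma2 set the
#'   noise unless overridden by \code{sigma}).
#' @param latent latent dynamics, default the bundled stand-in.
#' @param u0 named initial state; default \code{latent$u0}.
#' @param times output grid in minutes (default 31 points, 5-min spacing).
#' @param dt internal Euler step (minutes); \code{times} must lie on the
#'   fine grid.
#' @param n_traj number of cells.
#' @param seed integer seed.
#' @param sigma optional length-2 override \code{c(sigma1, sigma2)}.
#' @return a \code{trajectory_ensemble} of the full state with omega =
#'   \code{(sigma1, sigma2)} and attribute \code{"readout"} naming the
#'   observable u5 + u10 (use \code{\link{nfkb_readout}} to extract it).
#' @export
nfkb_simulate <- function(params = nfkb_params(), latent = nfkb_standin_latent(params),
                          u0 = latent$u0, times = seq(0, 150, by = 5), dt = 0.5,
                          n_traj = 1L, seed = 1L, sigma = NULL) {
  sig <- sigma %||% c(params$sigma1, params$sigma2)
  stopifnot(length(sig) == 2L, all(sig >= 0), all(u0 >= 0))
  field <- nfkb_field(params, latent)
  fine <- seq(min(times), max(times), by = dt)
  keep <- vapply(times, function(t) which.min(abs(fine - t)), 0L)
  if (any(abs(fine[keep] - times) > 1e-8)) stop("'times' must lie on the dt grid")
  e <- em_integrate(field, u0[latent$state_names], omega = sig, times = fine,
                    n_traj = n_traj, seed = seed, lower = 0)
  out <- trajectory_ensemble(times, e$values[, keep, , drop = FALSE], sig,
                             state_names = latent$state_names,
                             param_names = c("sigma1", "sigma2"))
  attr(out, "readout") <- c("u5", "u10")
  attr(out, "mask") <- match(c("u5", "u10"), latent$state_names)
  out
}

#' Scalar nuclear NF-kB readout of an ensemble
#'
#' Extracts the experimentally measured observable, total nuclear NF-kB
#' (nuclear IkBa--NF-kB complex plus free nuclear NF-kB, u5 + u10), as a
#' scalar-state ensemble.
#'
#' @param ensemble full-state ensemble from \code{\link{nfkb_simulate}}.
#' @return scalar-state \code{trajectory_ensemble}.
#' @export
nfkb_readout <- function(ensemble) {
  sn <- ensemble$state_names
  i5 <- match("u5", sn); i10 <- match("u10", sn)
  if (anyNA(c(i5, i10))) stop("ensemble lacks u5/u10 components")
  v <- ensemble$values[, , i5, drop = FALSE] + ensemble$values[, , i10, drop = FALSE]
  trajectory_ensemble(ensemble$times, v, ensemble$omega,
                      state_names = "nuclear_nfkb", param_names = ensemble$param_names)
}

#' Noise-intensity grid dataset
#'
#' Ensembles of NF-kB trajectories under a log-spaced grid of noise
#' intensities, by default 11 x 11 = 121 combinations with
#' \eqn{\lg \sigma_1 \in [-3.2, -2.2]} and
#' \eqn{\lg \sigma_2 \in [-2.5, -1.5]} in steps of 0.1.
#'
#' @param lg_sigma1,lg_sigma2 axes of \eqn{\log_{10}} noise intensities.
#' @param n_traj cells per combination.
#' @param seed integer seed.
#' @param params,latent model specification.
#' @param times,dt output grid and Euler step (minutes).
#' @return a \code{param_grid} with omega = (sigma1, sigma2), noise_dim 2
#'   and the u5/u10 loss mask attached.
#' @export
nfkb_noise_grid <- function(lg_sigma1 = seq(-3.2, -2.2, by = 0.1),
                            lg_sigma2 = seq(-2.5, -1.5, by = 0.1),
                            n_traj = 50L, seed = 1L,
                            params = nfkb_params(),
                            latent = nfkb_standin_latent(params),
                            times = seq(0, 150, by = 5), dt = 0.5) {
  ens <- list(); i <- 0L
  for (s1 in 10^lg_sigma1) for (s2 in 10^lg_sigma2) {
    i <- i + 1L
    ens[[i]] <- nfkb_simulate(params, latent, times = times, dt = dt,
                              n_traj = n_traj, seed = seed + 1000L * i,
                              sigma = c(s1, s2))
  }
  g <- param_grid(ens, "train")
  attr(g, "noise_dim") <- 2L
  attr(g, "mask") <- match(c("u5", "u10"), latent$state_names)
  g
}

#' Synthetic stand-in for the live-cell NF-kB recordings
#'
#' Emulates the measured single-cell dataset: scalar nuclear NF-kB
#' readouts on 31 frames at 5-minute spacing, with cells drawn from a
#' mixture over noise intensities. The per-cell ground-truth
#' \code{(sigma1, sigma2)} is stored as attribute \code{"true_noise"} so
#' the inference workflow can be validated; a real recording offers no
#' such labels. This is a synthetic stand-in, not experimental data.
#'
#' @param n_cells number of cells (>= 1).
#' @param noise_levels matrix with columns sigma1, sigma2: the mixture
#'   support.
#' @param weights mixture weights (default uniform).
#' @param seed integer seed.
#' @param params,latent,times,dt as in \code{\link{nfkb_simulate}}.
#' @return scalar-state \code{trajectory_ensemble} with attribute
#'   \code{"true_noise"} (n_cells x 2 matrix).
#' @export
nfkb_experimental_standin <- function(n_cells, noise_levels, weights = NULL,
                                      seed = 1L, params = nfkb_params(),
                                      latent = nfkb_standin_latent(params),
                                      times = seq(0, 150, by = 5), dt = 0.5) {
  stopifnot(n_cells >= 1)
  noise_levels <- matrix(as.numeric(noise_levels), ncol = 2L)
  w <- weights %||% rep(1, nrow(noise_levels))
  rng <- substream_rng(seed, "standin-mix")
  lev <- rng$with(function()
    sample.int(nrow(noise_levels), n_cells, replace = TRUE, prob = w / sum(w)))
  vals <- array(NA_real_, c(n_cells, length(times), 1L))
  for (k in seq_len(nrow(noise_levels))) {
    ii <- which(lev == k)
    if (!length(ii)) next
    e <- nfkb_simulate(params, latent, times = times, dt = dt,
                       n_traj = length(ii), seed = seed + 7000L * k,
                       sigma = noise_levels[k, ])
    vals[ii, , 1L] <- nfkb_readout(e)$values[, , 1L]
  }
  out <- trajectory_ensemble(times, vals, omega = numeric(0),
                             state_names = "nuclear_nfkb")
  attr(out, "true_noise") <- noise_levels[lev, , drop = FALSE]
  out
}
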