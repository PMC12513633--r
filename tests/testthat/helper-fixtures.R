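# Shared fixtures, built in code at test time.

# Small 1-D Ornstein-Uhlenbeck generator: dX = -theta X dt + s dB.
ou_field <- function(theta = 1, s = 0.3) {
  sde_field(function(X, w) -theta * X,
            function(X, w) matrix(s, nrow(X), 1L),
            state_dim = 1L, param_dim = 0L, noise_dim = 1L)
}

ou_ensemble <- function(n_traj = 100L, seed = 1L, theta = 1, s = 0.3,
                        times = seq(0, 1, by = 0.02), x0 = 1) {
  em_integrate(ou_field(theta, s), x0, numeric(0), times, n_traj, seed)
}

# Tiny deterministic ensemble with hand-listed values.
toy_ensemble <- function(values, times = seq_len(dim(values)[2]) - 1, omega = numeric(0)) {
  trajectory_ensemble(times, values, omega)
}

expect_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}
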