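# Minimal multilayer-perceptron engine: batched forward, exact reverse-mode
# gradients (weights and inputs), and Adam. tanh hidden layers, linear
# output. All matrices are (sample x feature); weights W[[l]] are
# (in x out), biases row vectors. This is the substrate for the neural
# drift/diffusion fields, the recurrent baselines and the noise-inference
# regressor, so its gradients are finite-difference-checked in the tests.

mlp_init <- function(n_in, n_out, width, depth, rng, out_scale = 0.1) {
  sizes <- c(n_in, rep(width, depth), n_out)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    sc <- sqrt(2 / (sizes[l] + sizes[l + 1L]))
    if (l == length(W)) sc <- sc * out_scale
    W[[l]] <- matrix(rng$rnorm(sizes[l] * sizes[l + 1L]) * sc, sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  H <- if (cache) vector("list", L - 1L) else NULL
  A <- X
  for (l in seq_len(L)) {
    A <- A %*% net$W[[l]] + rep(net$b[[l]], each = nrow(A))
    if (l < L) {
      A <- tanh(A)
      if (cache) H[[l]] <- A
    }
  }
  if (cache) list(out = A, X = X, H = H) else A
}

# G: upstream gradient on the output (n x n_out). Returns weight/bias
# gradients and the gradient with respect to the input matrix.
mlp_backward <- function(net, fw, G) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  D <- G
  for (l in rev(seq_len(L))) {
    inp <- if (l == 1L) fw$X else fw$H[[l - 1L]]
    gW[[l]] <- crossprod(inp, D)
    gb[[l]] <- colSums(D)
    D <- D %*% t(net$W[[l]])
    if (l > 1L) D <- D * (1 - fw$H[[l - 1L]]^2)
  }
  list(gW = gW, gb = gb, gX = D)
}

adam_init <- function(net) {
  zero <- function(x) lapply(x, function(m) m * 0)
  list(mW = zero(net$W), vW = zero(net$W), mb = zero(net$b), vb = zero(net$b), t = 0L)
}

adam_step <- function(net, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grad$gW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grad$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grad$gb[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grad$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

# Adam over an arbitrary named list of parameter arrays (used by the
# recurrent baselines, whose parameters do not fit the W/b layer shape).
adam_flat_init <- function(par) list(m = lapply(par, function(x) x * 0),
                                     v = lapply(par, function(x) x * 0), t = 0L)

adam_flat_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (k in names(par)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grad[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grad[[k]]^2
    par[[k]] <- par[[k]] - lr * (st$m[[k]] / c1) / (sqrt(st$v[[k]] / c2) + eps)
  }
  list(par = par, st = st)
}

grad_accum <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (l in seq_along(acc$gW)) {
    acc$gW[[l]] <- acc$gW[[l]] + g$gW[[l]]
    acc$gb[[l]] <- acc$gb[[l]] + g$gb[[l]]
  }
  acc
}
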