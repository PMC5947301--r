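# Tiny-network fixtures and independent oracles used across test files.

# a 3-motor / 2-visual / 4-hidden toy model with seeded weights
toy_params <- function(seed = 42, init_range = 0.5) {
  set.seed(seed)
  init_params(n_motor = 3, n_visual = 2, n_hidden = 4,
              init_range = init_range)
}

toy_inputs <- function(seed = 7) {
  set.seed(seed)
  list(u = runif(3), y = runif(2), h = runif(4),
       teacher_y = runif(2), teacher_u = runif(3))
}

# matrix-free reimplementation of one forward step (explicit loops; the
# oracle stays independent of the %*% path it checks)
naive_forward_step <- function(params, u, y, h) {
  nh <- nrow(params$W_mu)
  h_new <- numeric(nh)
  for (i in seq_len(nh)) {
    s <- 0
    for (j in seq_along(u)) s <- s + params$W_mu[i, j] * u[j]
    if (!is.null(y)) for (j in seq_along(y)) s <- s + params$W_vy[i, j] * y[j]
    for (j in seq_along(h)) s <- s + params$W_hh[i, j] * h[j]
    h_new[i] <- 1 / (1 + exp(-s))
  }
  ny <- nrow(params$W_hy)
  y_pred <- numeric(ny)
  for (i in seq_len(ny)) {
    s <- 0
    for (j in seq_len(nh)) s <- s + params$W_hy[i, j] * h_new[j]
    y_pred[i] <- 1 / (1 + exp(-s))
  }
  list(h = h_new, y_pred = y_pred)
}

naive_inverse_step <- function(params, y, h_f) {
  nh <- nrow(params$V_y)
  h_inv <- numeric(nh)
  for (i in seq_len(nh)) {
    s <- 0
    for (j in seq_along(y)) s <- s + params$V_y[i, j] * y[j]
    for (j in seq_along(h_f)) s <- s + params$V_h[i, j] * h_f[j]
    h_inv[i] <- 1 / (1 + exp(-s))
  }
  nu <- nrow(params$V_u)
  u_post <- numeric(nu)
  for (i in seq_len(nu)) {
    s <- 0
    for (j in seq_len(nh)) s <- s + params$V_u[i, j] * h_inv[j]
    u_post[i] <- 1 / (1 + exp(-s))
  }
  list(h_inv = h_inv, u_post = u_post)
}

# central-finite-difference gradient of a scalar loss over one weight matrix
numeric_grad <- function(loss_fn, params, which, eps = 1e-6) {
  W <- params[[which]]
  G <- W * 0
  for (k in seq_along(W)) {
    pp <- params; pp[[which]][k] <- W[k] + eps
    pm <- params; pm[[which]][k] <- W[k] - eps
    G[k] <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
  }
  G
}

# analytic gradient recovered from one update at learning rate eta
update_grad <- function(params, updated, which, eta) {
  (params[[which]] - updated[[which]]) / eta
}

rel_err <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-12)
}
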