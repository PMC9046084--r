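# planted two-program embedding generator: disjoint-support bases, one
# fixed nonmalignant component, known per-sample weights
planted_embedding <- function(N = 50, G = 200, depth = 1e5, env_frac = 0.3,
                              seed = 1) {
  set.seed(seed)
  eta_true <- matrix(0, 2, G)
  eta_true[1, 1:(G / 2)] <- rexp(G / 2)
  eta_true[2, (G / 2 + 1):G] <- rexp(G / 2)
  eta_true <- sweep(eta_true, 1, rowSums(eta_true), "/")
  psi_env <- matrix(rexp(G), 1)
  psi_env <- psi_env / sum(psi_env)
  theta_env <- matrix(env_frac, N, 1)
  kappa <- rdirichlet(N, c(1, 1))
  omega_true <- (1 - env_frac) * kappa
  X <- matrix(0L, N, G, dimnames = list(NULL, paste0("g", seq_len(G))))
  for (n in seq_len(N)) {
    p <- as.numeric(c(omega_true[n, ], env_frac) %*% rbind(eta_true, psi_env))
    X[n, ] <- as.integer(rmultinom(1, depth, p))
  }
  list(bulk = bulk_expression(X), eta_true = eta_true,
       omega_true = omega_true, psi_env = psi_env, theta_env = theta_env)
}
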