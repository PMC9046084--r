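# Independent oracles used by the unit and acceptance tests. These never
# call the code paths they validate.

# all k-part compositions of n, as a k x (number of compositions) matrix
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L))
  out <- NULL
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1L)
    out <- cbind(out, rbind(i, rest))
  }
  unname(out)
}

# Exact posterior mean of the state fractions under the
# Dirichlet-multinomial mixture, by enumeration of all read-assignment
# matrices U (S x G) consistent with the observed counts x.
# p(U | x) is proportional to prod_{s,g} phi_sg^{U_sg} / U_sg! times
# prod_s Gamma(alpha + R_s), and E[mu_s | U] = (alpha + R_s) / (S alpha + R).
exact_posterior_mu <- function(x, phi, alpha) {
  S <- nrow(phi)
  G <- length(x)
  parts <- lapply(x, function(xg) compositions(xg, S))
  counts <- vapply(parts, ncol, integer(1))
  grid <- as.matrix(expand.grid(lapply(counts, seq_len)))
  logw <- numeric(nrow(grid))
  Emu <- matrix(0, nrow(grid), S)
  lphi <- log(phi)
  R <- sum(x)
  for (i in seq_len(nrow(grid))) {
    U <- vapply(seq_len(G), function(g) parts[[g]][, grid[i, g]], numeric(S))
    U <- matrix(U, S, G)
    Rs <- rowSums(U)
    logw[i] <- sum(U * lphi - lfactorial(U)) + sum(lgamma(alpha + Rs))
    Emu[i, ] <- (alpha + Rs) / (S * alpha + R)
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  colSums(Emu * w)
}

# Dense two-stage grid search for the 2-gene nonmalignant MAP profile:
# maximizes the stated objective over log-gamma on [-lim, lim]^2, then
# refines around the optimum. Independent of the package optimizer.
grid_psi_env_oracle <- function(z, phi, sigma, lim = 5, n = 201, stages = 4) {
  center <- c(0, 0)
  half <- lim
  best <- NULL
  for (st in seq_len(stages)) {
    v1 <- seq(center[1] - half, center[1] + half, length.out = n)
    v2 <- seq(center[2] - half, center[2] + half, length.out = n)
    w1 <- phi[1] * exp(v1)
    w2 <- phi[2] * exp(v2)
    obj <- outer(z[1] * log(w1) - v1^2 / (2 * sigma^2),
                 z[2] * log(w2) - v2^2 / (2 * sigma^2), "+") -
      sum(z) * log(outer(w1, w2, "+"))
    ij <- arrayInd(which.max(obj), dim(obj))
    center <- c(v1[ij[1]], v2[ij[2]])
    half <- half * 4 / (n - 1)  # a few grid cells around the optimum
    best <- center
  }
  w <- phi * exp(best)
  list(v = best, psi = w / sum(w))
}

# direct Pearson correlation from the covariance formula (no cor())
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# cosine similarity between two vectors
cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# greedy row matching of estimated to true bases by cosine similarity
match_rows <- function(est, truth) {
  K <- nrow(truth)
  sim <- outer(seq_len(K), seq_len(K), Vectorize(function(i, j)
    cosine_sim(est[i, ], truth[j, ])))
  apply(sim, 2L, which.max)
}

# small labelled single-cell fixture: 2 types, 3 states, 4 genes
tiny_cells <- function() {
  counts <- rbind(
    c(5, 3, 1, 1), c(6, 2, 1, 1),   # state a1 (type A, malignant)
    c(1, 7, 1, 1), c(2, 6, 1, 1),   # state a2 (type A)
    c(1, 1, 6, 2), c(1, 1, 5, 3))   # state b1 (type B)
  colnames(counts) <- paste0("g", 1:4)
  rownames(counts) <- paste0("cell", 1:6)
  list(counts = counts,
       states = rep(c("a1", "a2", "b1"), each = 2),
       types = rep(c("A", "A", "B"), each = 2))
}
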