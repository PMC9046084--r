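# ---- KL-divergence NMF (multiplicative updates) -------------------------
#
# Used only to initialize the gene-program bases; the embedding itself is
# fit by EM under the generative model. Minimizes the generalized
# Kullback-Leibler divergence D(V || W H) with the classic multiplicative
# updates.
nmf_kl <- function(V, K, n_iter = 200, eps = 1e-12) {
  N <- nrow(V); G <- ncol(V)
  W <- matrix(stats::runif(N * K, 0.1, 1), N, K)
  H <- matrix(stats::runif(K * G, 0.1, 1), K, G)
  for (it in seq_len(n_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / pmax(rowSums(H), eps)
  }
  WH <- W %*% H + eps
  div <- sum(V * log((V + eps) / WH) - V + WH)
  list(W = W, H = H, divergence = div)
}

# connectivity of samples by dominant basis for one NMF run
connectivity <- function(W) {
  cl <- max.col(W, ties.method = "first")
  outer(cl, cl, "==") * 1
}

#' Initialize malignant gene-program bases by consensus NMF
#'
#' Runs KL-divergence NMF with random restarts on the normalized malignant
#' expression matrix for each candidate number of programs K, scores each K
#' by the cophenetic correlation of the consensus (co-clustering) matrix
#' across runs, and suggests the K whose score precedes the first
#' significant drop (a drop larger than `drop_frac` of the observed score
#' range; if none occurs, the K with the best score). For the selected K
#' the factorization is rerun `n_restarts` times and the basis with the
#' smallest divergence is returned, rows normalized to 1.
#'
#' @param Z_mal_norm N x G matrix of per-sample normalized malignant
#'   expression (nonnegative).
#' @param K_grid Candidate numbers of programs (default 2..12).
#' @param K Fixed K, skipping selection (optional).
#' @param n_restarts Random restarts for the final fit (default 200).
#' @param n_consensus Runs per K for the consensus score (default 30).
#' @param n_iter Multiplicative-update iterations per run.
#' @param drop_frac Fraction of the score range that counts as a
#'   significant drop (default 0.1).
#' @param seed Integer seed.
#' @return List with `eta0` (K x G row-stochastic prior bases), `K`, and
#'   `scores` (data frame of K vs cophenetic score; `NULL` when K fixed).
#' @export
nmf_init <- function(Z_mal_norm, K_grid = 2:12, K = NULL, n_restarts = 200,
                     n_consensus = 30, n_iter = 200, drop_frac = 0.1,
                     seed = 1) {
  V <- as.matrix(Z_mal_norm)
  stopifnot(all(V >= 0))
  scores <- NULL
  if (is.null(K)) {
    if (max(K_grid) > min(dim(V))) {
      stop("K_grid exceeds min(n_samples, n_genes)")
    }
    set.seed(as.integer(seed))
    sc <- numeric(length(K_grid))
    for (i in seq_along(K_grid)) {
      cons <- matrix(0, nrow(V), nrow(V))
      for (r in seq_len(n_consensus)) {
        cons <- cons + connectivity(nmf_kl(V, K_grid[i], n_iter)$W)
      }
      cons <- cons / n_consensus
      d <- stats::as.dist(1 - cons)
      if (max(d) < 1e-12) {
        sc[i] <- 1  # perfectly stable co-clustering
      } else {
        hc <- stats::hclust(d, method = "average")
        sc[i] <- stats::cor(d, stats::cophenetic(hc))
      }
    }
    scores <- data.frame(K = K_grid, cophenetic = sc)
    rng <- diff(range(sc))
    drops <- -diff(sc)
    big <- which(drops > drop_frac * max(rng, 1e-12))
    K <- if (length(big)) K_grid[big[1L]] else K_grid[which.max(sc)]
  }
  if (K > min(dim(V))) stop("K exceeds min(n_samples, n_genes)")
  set.seed(derive_seed(seed, 31L))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- nmf_kl(V, K, n_iter)
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  eta0 <- sweep(best$H, 1L, rowSums(best$H), "/")
  rownames(eta0) <- paste0("program", seq_len(K))
  colnames(eta0) <- colnames(V)
  list(eta0 = eta0, K = K, scores = scores)
}

#' Learn malignant gene programs by EM
#'
#' Factorizes bulk expression as a multinomial mixture whose rows are K
#' malignant program bases `eta` (inferred) followed by the fixed pooled
#' nonmalignant profiles `psi_env`, with mixing weights per sample given by
#' the program weights `omega` (inferred; rows sum to the malignant
#' fraction `tau_n`) followed by the fixed nonmalignant fractions
#' `theta_env`. `eta` carries a log-normal fold-change prior around the
#' initial bases `eta0` with scale `sigma`, and the normalized program
#' weights carry a symmetric Dirichlet(`alpha`) prior.
#'
#' The E-step computes expected read assignments over mixture rows; the
#' M-step re-estimates each basis as a MAP profile (same optimizer contract
#' as [estimate_psi_env()]) and sets `omega` to its posterior mean given
#' the expected program counts. The log posterior is tracked and must be
#' non-decreasing; a decrease beyond numerical tolerance is an error.
#'
#' @param bulk A `bulk_expression`.
#' @param theta_env N x (T-1) fixed nonmalignant fractions (may have zero
#'   columns for pure-tumor data).
#' @param psi_env (T-1) x G fixed nonmalignant profiles.
#' @param eta0 K x G prior bases (e.g. from [nmf_init()]).
#' @param alpha Dirichlet hyperparameter on normalized weights.
#' @param sigma Log-normal prior scale on basis fold changes.
#' @param em_max_iter,em_tol EM stopping rule (relative log-posterior
#'   change).
#' @param cg_max_iter Iteration cap for the per-basis MAP optimizer.
#' @return An `embedding_result`: `eta`, `eta0`, `lambda`, `omega`,
#'   `kappa` (omega normalized to the simplex), `tau`, `omega_norm`
#'   (alias of `kappa`, emitted for downstream use), `log_posterior`
#'   (trace), `n_iter`.
#' @export
fit_embedding <- function(bulk, theta_env, psi_env, eta0, alpha = 1e-8,
                          sigma = 2, em_max_iter = 50, em_tol = 1e-8,
                          cg_max_iter = 1e4) {
  stopifnot(inherits(bulk, "bulk_expression"))
  X <- bulk$X
  N <- nrow(X); G <- ncol(X)
  theta_env <- as.matrix(theta_env)
  if (nrow(theta_env) == 0L) theta_env <- matrix(0, N, 0L)
  psi_env <- matrix(psi_env, ncol = G)
  K <- nrow(eta0)
  Tm1 <- ncol(theta_env)
  stopifnot(nrow(psi_env) == Tm1, ncol(eta0) == G, nrow(theta_env) == N)
  theta_env_in <- theta_env  # kept to verify fixed blocks are untouched

  tau <- 1 - rowSums(theta_env)
  if (any(tau <= 0)) {
    stop("nonpositive malignant weight tau for sample(s): ",
         paste(bulk$sample_ids[tau <= 0], collapse = ", "))
  }

  # a strictly positive prior basis keeps mixture probabilities positive
  dn <- dimnames(eta0)
  eta0 <- matrix(t(apply(eta0, 1L, norm_to_one, pseudo_min = 1e-8)),
                 K, G, dimnames = dn)
  eta <- eta0
  lambda <- matrix(1, K, G)
  omega <- matrix(tau / K, N, K)

  log_post <- function(eta, lambda, omega) {
    ups <- cbind(omega, theta_env)
    zeta <- rbind(eta, psi_env)
    p <- ups %*% zeta
    sum(X * log(p)) - sum(log(lambda)^2) / (2 * sigma^2)
  }

  trace <- numeric(0)
  lp_old <- log_post(eta, lambda, omega)
  trace <- c(trace, lp_old)
  for (it in seq_len(em_max_iter)) {
    ups <- cbind(omega, theta_env)
    zeta <- rbind(eta, psi_env)
    denom <- ups %*% zeta          # N x G mixture probabilities
    A <- X / denom                 # N x G
    # expected counts: per-basis pooled over samples (for eta), and
    # per-sample per-basis totals (for omega)
    pooled <- (t(ups[, seq_len(K), drop = FALSE]) %*% A) *
      eta                          # K x G: sum_n V[n,k,g]
    c_nk <- (A %*% t(eta)) * ups[, seq_len(K), drop = FALSE]  # N x K

    for (k in seq_len(K)) {
      fit <- map_profile(pooled[k, ], eta0[k, ], sigma, cg_max_iter)
      eta[k, ] <- fit$profile
      lambda[k, ] <- fit$gamma
    }
    omega <- tau * (alpha + c_nk) / rowSums(alpha + c_nk)

    lp <- log_post(eta, lambda, omega)
    trace <- c(trace, lp)
    if (lp < lp_old - 1e-8 * abs(lp_old)) {
      stop("log posterior decreased during EM (", lp_old, " -> ", lp, ")")
    }
    if (abs(lp - lp_old) <= em_tol * abs(lp_old)) {
      lp_old <- lp
      break
    }
    lp_old <- lp
  }
  stopifnot(identical(theta_env, theta_env_in))

  dimnames(eta) <- dimnames(eta0)
  dimnames(lambda) <- dimnames(eta0)
  dimnames(omega) <- list(bulk$sample_ids, rownames(eta0))
  kappa <- omega / tau
  structure(
    list(eta = eta, eta0 = eta0, lambda = lambda,
         omega = omega, kappa = kappa, omega_norm = kappa, tau = tau,
         log_posterior = trace, n_iter = length(trace) - 1L),
    class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("Embedding:", nrow(x$eta), "programs x", ncol(x$eta), "genes;",
      nrow(x$omega), "samples;", x$n_iter, "EM iterations\n")
  invisible(x)
}
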