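#' Gibbs sampler configuration
#'
#' Defaults follow the fixed schedule used throughout the package: a chain
#' of 1000 sweeps, the first 500 discarded, every other retained sweep used
#' for the posterior mean, and a near-flat symmetric Dirichlet prior on
#' fractions (`alpha = 1e-8`).
#'
#' @param alpha Symmetric Dirichlet hyperparameter on fractions (> 0).
#' @param chain_length Total Gibbs sweeps.
#' @param burn_in Sweeps discarded from the start (< `chain_length`).
#' @param thinning Keep every `thinning`-th retained sweep (>= 1).
#' @param seed Integer seed; per-sample RNG streams are derived from
#'   `(seed, sample index)` so results do not depend on processing order.
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(alpha = 1e-8, chain_length = 1000L, burn_in = 500L,
                         thinning = 2L, seed = 1L) {
  stopifnot(alpha > 0, chain_length >= 1, burn_in >= 0,
            burn_in < chain_length, thinning >= 1)
  structure(list(alpha = alpha,
                 chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed)),
            class = "gibbs_config")
}

# deterministic 32-bit stream seed for sample n
derive_seed <- function(seed, n) {
  as.integer((as.numeric(seed) * 10007 + n * 97 + 12345) %% 2147483647)
}

#' Sample per-gene read assignments given fractions
#'
#' Conditional draw of the latent assignment matrix: for each gene g, the
#' x[g] reads are split across the S states by a multinomial with event
#' probabilities proportional to `mu[s] * phi[s, g]`. Reads are conserved
#' exactly: `colSums(U) == x`.
#'
#' Sampling is vectorized over genes via the sequential-binomial
#' decomposition of the multinomial.
#'
#' @param x Integer vector of G gene counts.
#' @param phi S x G matrix of positive state profiles.
#' @param mu Length-S fraction vector on the simplex.
#' @return S x G matrix of nonnegative integers.
#' @export
sample_assignments <- function(x, phi, mu) {
  S <- nrow(phi); G <- ncol(phi)
  stopifnot(length(x) == G, length(mu) == S)
  W <- mu * phi                      # S x G unnormalized event weights
  U <- matrix(0, S, G, dimnames = dimnames(phi))
  if (S == 1L) {
    U[1L, ] <- x
    return(U)
  }
  rem <- as.numeric(x)
  remW <- colSums(W)
  if (any(rem > 0 & remW <= 0)) {
    stop("gene with reads but zero total assignment weight; ",
         "reference profiles must be strictly positive")
  }
  for (s in seq_len(S - 1L)) {
    p <- ifelse(remW > 0, W[s, ] / remW, 0)
    p <- pmin(pmax(p, 0), 1)
    draw <- stats::rbinom(G, rem, p)
    U[s, ] <- draw
    rem <- rem - draw
    remW <- remW - W[s, ]
  }
  U[S, ] <- rem
  U
}

#' Sample fractions given read assignments
#'
#' Conditional draw of the state fractions from
#' Dirichlet(alpha + R_s), where R_s is the total number of reads assigned
#' to state s.
#'
#' @param U S x G assignment matrix (nonnegative).
#' @param alpha Symmetric Dirichlet hyperparameter.
#' @return Length-S vector on the simplex.
#' @export
sample_theta <- function(U, alpha = 1e-8) {
  R_s <- rowSums(U)
  g <- stats::rgamma(length(R_s), shape = alpha + R_s, rate = 1)
  tot <- sum(g)
  if (tot <= 0 || !is.finite(tot)) {
    # all shapes underflowed (possible only when every R_s is 0)
    g <- stats::rgamma(length(R_s), shape = 1, rate = 1)
    tot <- sum(g)
  }
  g / tot
}

# One full chain for a single sample; returns retained-draw means.
gibbs_chain <- function(x, phi, cfg) {
  S <- nrow(phi); G <- ncol(phi)
  mu <- rep(1 / S, S)
  mu_acc <- numeric(S)
  U_acc <- matrix(0, S, G)
  kept <- 0L
  retain <- seq.int(cfg$burn_in + 1L, cfg$chain_length)
  retain <- retain[(seq_along(retain) - 1L) %% cfg$thinning == 0L]
  retain_flag <- logical(cfg$chain_length)
  retain_flag[retain] <- TRUE
  for (it in seq_len(cfg$chain_length)) {
    U <- sample_assignments(x, phi, mu)
    mu <- sample_theta(U, cfg$alpha)
    if (retain_flag[it]) {
      mu_acc <- mu_acc + mu
      U_acc <- U_acc + U
      kept <- kept + 1L
    }
  }
  list(mu_bar = mu_acc / kept, U_bar = U_acc / kept)
}

#' Run the deconvolution Gibbs sampler over a bulk cohort
#'
#' For each bulk sample independently, alternates the two conditional draws
#' ([sample_assignments()] and [sample_theta()]) for `chain_length` sweeps,
#' discards the burn-in, applies thinning, and returns the arithmetic means
#' of the retained fraction and assignment draws. Deterministic given
#' `cfg$seed`; each sample uses its own RNG stream.
#'
#' @param bulk A `bulk_expression` (genes already aligned to `ref`).
#' @param ref A `cell_state_reference` (or any object with a row-stochastic
#'   profile matrix in `$phi` and matching `gene_ids`).
#' @param cfg A [gibbs_config()].
#' @return A `posterior_summary` with `mu_bar` (N x S, rows on the
#'   simplex), `U_bar` (N x S x G array; `sum over s` reproduces `X`),
#'   `state_ids`, `sample_ids`, `gene_ids`.
#' @export
run_gibbs <- function(bulk, ref, cfg = gibbs_config()) {
  stopifnot(inherits(bulk, "bulk_expression"))
  phi <- ref$phi
  if (!identical(colnames(phi), bulk$gene_ids)) {
    stop("bulk and reference gene ids are not aligned; call align_genes()")
  }
  N <- nrow(bulk$X); S <- nrow(phi); G <- ncol(phi)
  mu_bar <- matrix(0, N, S, dimnames = list(bulk$sample_ids, rownames(phi)))
  U_bar <- array(0, dim = c(N, S, G),
                 dimnames = list(bulk$sample_ids, rownames(phi), bulk$gene_ids))
  for (n in seq_len(N)) {
    set.seed(derive_seed(cfg$seed, n))
    res <- gibbs_chain(bulk$X[n, ], phi, cfg)
    mu_bar[n, ] <- res$mu_bar
    U_bar[n, , ] <- res$U_bar
  }
  structure(
    list(mu_bar = mu_bar, U_bar = U_bar,
         state_ids = rownames(phi),
         sample_ids = bulk$sample_ids,
         gene_ids = bulk$gene_ids,
         config = cfg),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary:", nrow(x$mu_bar), "samples x",
      ncol(x$mu_bar), "states\n")
  invisible(x)
}

#' Aggregate state-level posteriors to cell types
#'
#' Sums the posterior mean fractions and read assignments over the states
#' of each cell type, giving the first-pass type fractions `theta0` and the
#' per-type expression tallies `Z`.
#'
#' @param summary A `posterior_summary` from [run_gibbs()].
#' @param ref The `cell_state_reference` used for the run (supplies the
#'   state-to-type map).
#' @return A `cell_type_estimate` with `theta0` (N x T, simplex rows), `Z`
#'   (N x T x G), `R_nt` (N x T read totals), `type_ids`, `sample_ids`,
#'   `gene_ids`, `malignant_type`.
#' @export
aggregate_states <- function(summary, ref) {
  stopifnot(inherits(summary, "posterior_summary"),
            inherits(ref, "cell_state_reference"))
  if (!identical(summary$state_ids, ref$state_ids)) {
    stop("posterior summary and reference disagree on state ids")
  }
  N <- nrow(summary$mu_bar); Tn <- length(ref$type_ids)
  G <- length(summary$gene_ids)
  theta0 <- matrix(0, N, Tn, dimnames = list(summary$sample_ids, ref$type_ids))
  Z <- array(0, dim = c(N, Tn, G),
             dimnames = list(summary$sample_ids, ref$type_ids, summary$gene_ids))
  for (t in seq_len(Tn)) {
    idx <- which(ref$type_of_state == t)
    theta0[, t] <- rowSums(summary$mu_bar[, idx, drop = FALSE])
    Zt <- summary$U_bar[, idx, , drop = FALSE]
    Z[, t, ] <- apply(Zt, c(1L, 3L), sum)
  }
  structure(
    list(theta0 = theta0, Z = Z,
         R_nt = apply(Z, c(1L, 2L), sum),
         type_ids = ref$type_ids,
         sample_ids = summary$sample_ids,
         gene_ids = summary$gene_ids,
         malignant_type = ref$malignant_type),
    class = "cell_type_estimate")
}

#' @export
print.cell_type_estimate <- function(x, ...) {
  cat("Cell-type estimate:", nrow(x$theta0), "samples x",
      ncol(x$theta0), "types\n")
  invisible(x)
}
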