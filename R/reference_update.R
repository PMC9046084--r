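#' Per-sample malignant profile (maximum likelihood)
#'
#' The reads assigned to the malignant type in each sample are themselves a
#' multinomial draw from that sample's malignant profile, so the MLE is the
#' row-normalized assignment vector. A pseudo-count floor is applied with
#' [norm_to_one()]. Samples with no malignant reads fall back to the prior
#' malignant profile with a warning.
#'
#' @param est A `cell_type_estimate` from [aggregate_states()].
#' @param phi_prime_mal Prior malignant profile row (fallback), length G.
#' @param pseudo_min Pseudo-count floor.
#' @return N x G row-stochastic matrix `psi_mal`.
#' @export
estimate_psi_mal <- function(est, phi_prime_mal, pseudo_min = 1e-8) {
  stopifnot(inherits(est, "cell_type_estimate"))
  if (is.na(est$malignant_type)) stop("no malignant type designated")
  Zm <- est$Z[, est$malignant_type, , drop = TRUE]
  if (is.null(dim(Zm))) Zm <- matrix(Zm, nrow = 1L)
  psi <- matrix(0, nrow(Zm), ncol(Zm),
                dimnames = list(est$sample_ids, est$gene_ids))
  empty <- rowSums(Zm) == 0
  if (any(empty)) {
    warning("sample(s) with zero malignant reads fall back to the prior ",
            "profile: ", paste(est$sample_ids[empty], collapse = ", "))
    psi[empty, ] <- rep(phi_prime_mal, each = sum(empty))
  }
  for (n in which(!empty)) {
    psi[n, ] <- norm_to_one(Zm[n, ], pseudo_min = pseudo_min)
  }
  psi
}

# MAP objective and gradient for one nonmalignant type, in v = log(gamma).
# z: pooled assigned counts (length G); prior center phi (length G); the
# normalization of psi makes one direction flat, broken by the normal prior.
psi_env_objective <- function(v, z, phi, sigma) {
  w <- phi * exp(v)
  sum(z * (log(w) - log(sum(w)))) - sum(v^2) / (2 * sigma^2)
}
psi_env_gradient <- function(v, z, phi, sigma) {
  w <- phi * exp(v)
  z - sum(z) * w / sum(w) - v / sigma^2
}

# shared MAP machinery: maximize the multinomial log likelihood of pooled
# counts z under profile prior * gamma, penalized by log(gamma) ~ N(0, sigma),
# by conjugate gradients in log-gamma space. Returns the renormalized
# profile, the fold changes, and whether the optimum beats the prior point.
map_profile <- function(z, prior, sigma, cg_max_iter = 1e5) {
  G <- length(z)
  if (sum(z) == 0 || sigma == 0) {
    return(list(profile = prior, gamma = rep(1, G), improved = TRUE))
  }
  fit <- stats::optim(
    par = rep(0, G),
    fn = function(v) -psi_env_objective(v, z, prior, sigma),
    gr = function(v) -psi_env_gradient(v, z, prior, sigma),
    method = "CG",
    control = list(maxit = as.integer(cg_max_iter), reltol = 1e-10))
  if (!all(is.finite(fit$par)) || !is.finite(fit$value)) {
    stop("non-finite MAP objective")
  }
  f_opt <- -fit$value
  f_prior <- psi_env_objective(rep(0, G), z, prior, sigma)
  if (f_opt < f_prior) {
    return(list(profile = prior, gamma = rep(1, G), improved = FALSE))
  }
  g <- exp(fit$par)
  w <- prior * g
  list(profile = w / sum(w), gamma = g, improved = TRUE)
}

#' Pooled nonmalignant profiles (maximum a posteriori)
#'
#' For each nonmalignant cell type, pools the posterior read assignments
#' across all bulk samples and maximizes the multinomial log-likelihood
#' penalized by a log-normal prior on the gene-wise fold change gamma from
#' the prior profile: `log(gamma_tg) ~ Normal(0, sigma)`, with
#' `psi_env_tg = phi'_tg * gamma_tg / sum_g phi'_tg * gamma_tg`.
#' With no assigned reads (or as `sigma -> 0`) the estimate collapses to
#' the prior profile. Optimization is by conjugate gradients in
#' unconstrained log-gamma space, independently per type.
#'
#' @param est A `cell_type_estimate`.
#' @param type_ref A `cell_type_reference` (prior center `phi_prime`).
#' @param sigma Prior scale on log fold changes (default 2).
#' @param cg_max_iter Iteration cap for the conjugate-gradient optimizer
#'   (default 1e5).
#' @param types Integer indices of the types to update (default: all
#'   nonmalignant types, or all types when no malignant type is set).
#' @return List with `psi_env` (rows = updated types, row-stochastic) and
#'   `gamma` (fold changes, same shape).
#' @export
estimate_psi_env <- function(est, type_ref, sigma = 2, cg_max_iter = 1e5,
                             types = NULL) {
  stopifnot(inherits(est, "cell_type_estimate"),
            inherits(type_ref, "cell_type_reference"),
            sigma >= 0)
  if (!identical(est$gene_ids, type_ref$gene_ids)) {
    stop("estimate and type reference disagree on gene ids")
  }
  if (is.null(types)) {
    types <- seq_along(est$type_ids)
    if (!is.na(est$malignant_type)) types <- setdiff(types, est$malignant_type)
  }
  G <- length(est$gene_ids)
  psi_env <- matrix(0, length(types), G,
                    dimnames = list(est$type_ids[types], est$gene_ids))
  gamma <- matrix(1, length(types), G, dimnames = dimnames(psi_env))
  for (i in seq_along(types)) {
    t <- types[i]
    phi_t <- type_ref$phi_prime[match(est$type_ids[t], type_ref$type_ids), ]
    z <- apply(est$Z[, t, , drop = FALSE], 3L, sum)
    fit <- map_profile(z, phi_t, sigma, cg_max_iter)
    if (!fit$improved) {
      warning("MAP optimization failed to improve over the prior for type ",
              est$type_ids[t], "; returning the prior profile")
    }
    psi_env[i, ] <- fit$profile
    gamma[i, ] <- fit$gamma
  }
  list(psi_env = psi_env, gamma = gamma)
}

#' Update the reference using the first-pass posterior
#'
#' Combines the per-sample malignant MLE profiles ([estimate_psi_mal()])
#' with the pooled nonmalignant MAP profiles ([estimate_psi_env()]) into a
#' partly sample-specific reference at cell-type resolution. Nonmalignant
#' types whose estimated fraction never reaches 1% in any sample are
#' reported with a message: pooling assumes each updated type is actually
#' present somewhere in the cohort.
#'
#' @param est A `cell_type_estimate` from [aggregate_states()].
#' @param type_ref A `cell_type_reference` aligned to the same genes.
#' @param sigma Log-normal prior scale (default 2).
#' @param cg_max_iter Conjugate-gradient iteration cap (default 1e5).
#' @param pseudo_min Floor for the malignant MLE rows.
#' @return An `updated_reference` with `psi_mal` (N x G or `NULL`),
#'   `psi_env`, `gamma`, `sigma`, `type_ids`, `env_type_ids`,
#'   `malignant_type`, `gene_ids`, `sample_ids`.
#' @export
update_reference <- function(est, type_ref, sigma = 2, cg_max_iter = 1e5,
                             pseudo_min = 1e-8) {
  stopifnot(inherits(est, "cell_type_estimate"))
  low <- apply(est$theta0, 2L, max) < 0.01
  if (!is.na(est$malignant_type)) low[est$malignant_type] <- FALSE
  if (any(low)) {
    message("type(s) never reaching 1% in any sample (pooled update is ",
            "weakly informed): ",
            paste(est$type_ids[low], collapse = ", "))
  }
  psi_mal <- NULL
  if (!is.na(est$malignant_type)) {
    mal_row <- type_ref$phi_prime[
      match(est$type_ids[est$malignant_type], type_ref$type_ids), ]
    psi_mal <- estimate_psi_mal(est, mal_row, pseudo_min = pseudo_min)
  }
  env <- estimate_psi_env(est, type_ref, sigma = sigma,
                          cg_max_iter = cg_max_iter)
  structure(
    list(psi_mal = psi_mal,
         psi_env = env$psi_env,
         gamma = env$gamma,
         sigma = sigma,
         type_ids = est$type_ids,
         env_type_ids = rownames(env$psi_env),
         malignant_type = est$malignant_type,
         gene_ids = est$gene_ids,
         sample_ids = est$sample_ids),
    class = "updated_reference")
}

#' @export
print.updated_reference <- function(x, ...) {
  cat("Updated reference:", length(x$type_ids), "types x",
      length(x$gene_ids), "genes;",
      if (is.null(x$psi_mal)) "no malignant type" else
        paste0("per-sample malignant rows for ", nrow(x$psi_mal), " samples"),
      "\n")
  invisible(x)
}

# assemble the T x G sample-specific reference for sample n
assemble_psi_n <- function(updated, n) {
  Tn <- length(updated$type_ids)
  psi <- matrix(0, Tn, length(updated$gene_ids),
                dimnames = list(updated$type_ids, updated$gene_ids))
  env_idx <- match(updated$env_type_ids, updated$type_ids)
  psi[env_idx, ] <- updated$psi_env
  if (!is.na(updated$malignant_type)) {
    psi[updated$malignant_type, ] <- updated$psi_mal[n, ]
  }
  psi
}

#' Re-estimate cell type fractions with the updated reference
#'
#' Runs the same Gibbs sampler at cell-type resolution, using each sample's
#' assembled reference (its own malignant row, shared nonmalignant rows),
#' and returns the posterior mean fractions `theta_f`.
#'
#' @param bulk A `bulk_expression` aligned to the reference genes.
#' @param updated An `updated_reference` from [update_reference()].
#' @param cfg A [gibbs_config()]; the defaults of the first pass are reused.
#' @return N x T matrix `theta_f` with rows on the simplex.
#' @export
refit_theta <- function(bulk, updated, cfg = gibbs_config()) {
  stopifnot(inherits(bulk, "bulk_expression"),
            inherits(updated, "updated_reference"))
  if (!identical(bulk$gene_ids, updated$gene_ids)) {
    stop("bulk and updated reference gene ids are not aligned")
  }
  N <- nrow(bulk$X)
  theta_f <- matrix(0, N, length(updated$type_ids),
                    dimnames = list(bulk$sample_ids, updated$type_ids))
  for (n in seq_len(N)) {
    psi_n <- assemble_psi_n(updated, n)
    set.seed(derive_seed(cfg$seed, n))
    res <- gibbs_chain(bulk$X[n, ], psi_n, cfg)
    theta_f[n, ] <- res$mu_bar
  }
  theta_f
}
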