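#' Draw rows from a Dirichlet distribution
#'
#' @param n Number of draws.
#' @param alpha Concentration vector.
#' @return n x length(alpha) matrix with rows on the simplex.
#' @export
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n), rate = 1),
              n, k)
  sweep(g, 1L, rowSums(g), "/")
}

# sparse log-normal expression profile over G genes, normalized to 1
random_profile <- function(G, sdlog = 1.5, sparsity = 0.3) {
  p <- stats::rlnorm(G, meanlog = 0, sdlog = sdlog)
  p[stats::runif(G) < sparsity] <- 0
  if (all(p == 0)) p[sample.int(G, 1L)] <- 1
  p / sum(p)
}

#' Multiplicative log-normal perturbation of expression profiles
#'
#' Multiplies every entry by `exp(eps)` with `eps ~ Normal(0, sigma_noise)`
#' and renormalizes each row. Used to decouple the profiles that generate
#' pseudo-bulk reads from the single-cell reference handed to the
#' deconvolution, emulating batch differences between platforms.
#'
#' @param phi Matrix of profiles (rows) or a single profile vector.
#' @param sigma_noise Standard deviation of the log-normal noise; 0 is the
#'   identity.
#' @param seed Optional integer seed (the caller's RNG is used when `NULL`).
#' @return Perturbed profiles, rows summing to 1.
#' @export
apply_lognormal_noise <- function(phi, sigma_noise, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  vec <- is.null(dim(phi))
  if (vec) phi <- matrix(phi, nrow = 1L)
  if (sigma_noise > 0) {
    eps <- matrix(stats::rnorm(length(phi), 0, sigma_noise),
                  nrow(phi), ncol(phi))
    phi <- phi * exp(eps)
  }
  phi <- sweep(phi, 1L, rowSums(phi), "/")
  if (vec) phi[1L, ] else phi
}

#' Simulate a labelled single-cell dataset and its reference
#'
#' Draws one sparse log-normal mean profile per cell type, derives state
#' profiles as a mixture of the type mean and a state-specific component
#' (so states within a type are more correlated than states across types),
#' samples cells multinomially per state, and builds the reference with
#' [build_state_reference()].
#'
#' @param n_types Number of cell types.
#' @param states_per_type Integer vector (recycled) of states per type.
#' @param n_genes Number of genes.
#' @param cells_per_state Cells drawn per state.
#' @param cell_depth Reads per cell.
#' @param malignant_type Index of the malignant type, or `NA` for none.
#' @param state_mix Weight of the state-specific component in state
#'   profiles (0 = all states identical to the type mean).
#' @param sdlog,sparsity Shape of the log-normal profile generator.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with `ref` (a `cell_state_reference`), `counts` (cells x
#'   genes), `state_labels`, `type_labels`, `state_profiles` (true S x G
#'   generating profiles), `type_of_state`.
#' @export
simulate_reference <- function(n_types = 4, states_per_type = 1,
                               n_genes = 1000, cells_per_state = 50,
                               cell_depth = 1000, malignant_type = 1,
                               state_mix = 0.3, sdlog = 1.5, sparsity = 0.3,
                               seed = 1) {
  set.seed(as.integer(seed))
  states_per_type <- rep_len(states_per_type, n_types)
  type_ids <- paste0("type", seq_len(n_types))
  if (!is.na(malignant_type)) type_ids[malignant_type] <- "malignant"
  gene_ids <- sprintf("G%04d", seq_len(n_genes))

  S <- sum(states_per_type)
  state_profiles <- matrix(0, S, n_genes)
  state_ids <- character(S)
  type_of_state <- integer(S)
  s <- 0L
  for (t in seq_len(n_types)) {
    m_t <- random_profile(n_genes, sdlog, sparsity)
    for (k in seq_len(states_per_type[t])) {
      s <- s + 1L
      e_s <- random_profile(n_genes, sdlog, sparsity)
      p <- (1 - state_mix) * m_t + state_mix * e_s
      state_profiles[s, ] <- p / sum(p)
      state_ids[s] <- paste0(type_ids[t], "_s", k)
      type_of_state[s] <- t
    }
  }
  dimnames(state_profiles) <- list(state_ids, gene_ids)

  counts <- matrix(0L, S * cells_per_state, n_genes,
                   dimnames = list(NULL, gene_ids))
  state_labels <- character(nrow(counts))
  type_labels <- character(nrow(counts))
  r <- 0L
  for (si in seq_len(S)) {
    draws <- stats::rmultinom(cells_per_state, cell_depth, state_profiles[si, ])
    counts[r + seq_len(cells_per_state), ] <- t(draws)
    state_labels[r + seq_len(cells_per_state)] <- state_ids[si]
    type_labels[r + seq_len(cells_per_state)] <- type_ids[type_of_state[si]]
    r <- r + cells_per_state
  }
  rownames(counts) <- paste0("cell", seq_len(nrow(counts)))

  ref <- build_state_reference(
    counts, state_labels, type_labels,
    malignant_type = if (is.na(malignant_type)) NULL else type_ids[malignant_type])
  list(ref = ref, counts = counts,
       state_labels = state_labels, type_labels = type_labels,
       state_profiles = state_profiles, type_of_state = type_of_state)
}

#' Simulate pseudo-bulk samples from state profiles or cells
#'
#' Two modes. In `"profile"` mode, per-state read totals are drawn
#' multinomially from the given state fractions at the requested depth and
#' each state's reads are then drawn from its profile; the realized (not
#' nominal) per-state read shares are recorded as the ground truth. In
#' `"cell"` mode, cells are sampled (with replacement) per state in
#' proportion to the fractions and their counts are summed; ground truth is
#' the realized share of reads contributed by each state.
#'
#' @param profiles S x G state profiles (`"profile"` mode).
#' @param fractions N x S matrix of state fractions, rows on the simplex.
#' @param depth Reads per pseudo-bulk (`"profile"` mode) or number of cells
#'   pooled per pseudo-bulk (`"cell"` mode).
#' @param mode `"profile"` or `"cell"`.
#' @param cells,state_labels Cell count matrix and labels (`"cell"` mode).
#' @param malignant_profiles Optional N x G per-sample malignant profiles
#'   overriding the malignant state's row (`"profile"` mode).
#' @param malignant_state Index of the state replaced by
#'   `malignant_profiles`.
#' @param seed Integer seed.
#' @return List with `bulk` (a `bulk_expression`) and `truth` (list with
#'   `state_fractions` = realized N x S read shares and the nominal
#'   `fractions`).
#' @export
simulate_pseudobulk <- function(profiles = NULL, fractions, depth,
                                mode = c("profile", "cell"),
                                cells = NULL, state_labels = NULL,
                                malignant_profiles = NULL,
                                malignant_state = NULL, seed = 1) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  fractions <- as.matrix(fractions)
  if (any(abs(rowSums(fractions) - 1) > 1e-8)) {
    stop("fraction rows must lie on the simplex")
  }
  N <- nrow(fractions)

  if (mode == "profile") {
    S <- nrow(profiles); G <- ncol(profiles)
    stopifnot(ncol(fractions) == S)
    X <- matrix(0L, N, G, dimnames = list(paste0("sample", seq_len(N)),
                                          colnames(profiles)))
    realized <- matrix(0, N, S,
                       dimnames = list(rownames(X), rownames(profiles)))
    for (n in seq_len(N)) {
      n_s <- as.integer(stats::rmultinom(1L, depth, fractions[n, ]))
      x <- numeric(G)
      for (s in seq_len(S)) {
        if (n_s[s] == 0L) next
        p <- if (!is.null(malignant_profiles) && identical(s, malignant_state))
          malignant_profiles[n, ] else profiles[s, ]
        x <- x + as.numeric(stats::rmultinom(1L, n_s[s], p))
      }
      X[n, ] <- as.integer(x)
      realized[n, ] <- n_s / depth
    }
  } else {
    stopifnot(!is.null(cells), !is.null(state_labels))
    state_ids <- colnames(fractions)
    if (is.null(state_ids)) state_ids <- unique(state_labels)
    S <- length(state_ids); G <- ncol(cells)
    X <- matrix(0L, N, G, dimnames = list(paste0("sample", seq_len(N)),
                                          colnames(cells)))
    realized <- matrix(0, N, S, dimnames = list(rownames(X), state_ids))
    for (n in seq_len(N)) {
      n_cells <- as.integer(stats::rmultinom(1L, depth, fractions[n, ]))
      x <- numeric(G)
      reads_s <- numeric(S)
      for (s in seq_len(S)) {
        if (n_cells[s] == 0L) next
        pool <- which(state_labels == state_ids[s])
        take <- sample(pool, n_cells[s], replace = TRUE)
        xs <- colSums(cells[take, , drop = FALSE])
        x <- x + xs
        reads_s[s] <- sum(xs)
      }
      X[n, ] <- as.integer(x)
      realized[n, ] <- reads_s / sum(reads_s)
    }
  }
  list(bulk = bulk_expression(X),
       truth = list(state_fractions = realized, nominal = fractions))
}

#' Simulate a complete benchmark cohort with ground truth
#'
#' Convenience wrapper tying the generators together: simulates a labelled
#' single-cell dataset and its reference, perturbs the true state profiles
#' by multiplicative log-normal noise (the reference stays unperturbed, so
#' reference and bulk disagree by the noise term), draws per-sample type
#' fractions, splits them over states, and generates pseudo-bulks in
#' profile mode.
#'
#' @param n_samples Number of pseudo-bulk samples.
#' @param depth Reads per pseudo-bulk.
#' @param sigma_noise Log-normal reference-vs-bulk noise scale.
#' @param fraction_conc Dirichlet concentration for type fractions.
#' @param purity_range Optional length-2 range: malignant fractions drawn
#'   uniformly from it, remaining mass split over nonmalignant types.
#' @param per_sample_malignant If `TRUE`, each sample's malignant
#'   component uses its own log-normal perturbation of the malignant
#'   profile (recorded in the truth); requires one malignant state.
#' @param seed Integer seed.
#' @inheritParams simulate_reference
#' @return List with `ref`, `cells` (the simulated single-cell counts) and
#'   their `cell_state_labels`/`cell_type_labels`, `bulk`, `truth`
#'   (realized type and state read fractions, nominal fractions,
#'   per-sample `malignant_profiles` when requested) and
#'   `generating_profiles` (the noise-perturbed S x G matrix).
#' @export
simulate_cohort <- function(n_types = 4, states_per_type = c(3, 1, 1, 1),
                            n_genes = 1000, cells_per_state = 50,
                            cell_depth = 1000, malignant_type = 1,
                            n_samples = 30, depth = 5e4, sigma_noise = 0.5,
                            fraction_conc = 1, purity_range = NULL,
                            per_sample_malignant = FALSE, seed = 1) {
  sim <- simulate_reference(n_types = n_types,
                            states_per_type = states_per_type,
                            n_genes = n_genes,
                            cells_per_state = cells_per_state,
                            cell_depth = cell_depth,
                            malignant_type = malignant_type,
                            seed = seed)
  set.seed(derive_seed(seed, 7919L))
  profiles <- apply_lognormal_noise(sim$state_profiles, sigma_noise)
  S <- nrow(profiles)
  Tn <- n_types
  type_of_state <- sim$type_of_state

  if (!is.null(purity_range)) {
    stopifnot(!is.na(malignant_type))
    f_mal <- stats::runif(n_samples, purity_range[1], purity_range[2])
    env <- rdirichlet(n_samples, rep(fraction_conc, Tn - 1L))
    type_frac <- matrix(0, n_samples, Tn)
    type_frac[, malignant_type] <- f_mal
    type_frac[, -malignant_type] <- env * (1 - f_mal)
  } else {
    type_frac <- rdirichlet(n_samples, rep(fraction_conc, Tn))
  }
  state_frac <- matrix(0, n_samples, S)
  for (t in seq_len(Tn)) {
    idx <- which(type_of_state == t)
    if (length(idx) == 1L) {
      state_frac[, idx] <- type_frac[, t]
    } else {
      w <- rdirichlet(n_samples, rep(1, length(idx)))
      state_frac[, idx] <- w * type_frac[, t]
    }
  }
  colnames(state_frac) <- rownames(profiles)

  mal_profiles <- NULL
  mal_state <- NULL
  if (per_sample_malignant) {
    idx <- which(type_of_state == malignant_type)
    if (length(idx) != 1L) {
      stop("per-sample malignant profiles require exactly one malignant state")
    }
    mal_state <- idx
    mal_profiles <- matrix(0, n_samples, n_genes,
                           dimnames = list(paste0("sample", seq_len(n_samples)),
                                           colnames(profiles)))
    for (n in seq_len(n_samples)) {
      mal_profiles[n, ] <- apply_lognormal_noise(sim$state_profiles[idx, ],
                                                 sigma_noise)
    }
  }

  pb <- simulate_pseudobulk(profiles = profiles, fractions = state_frac,
                            depth = depth, mode = "profile",
                            malignant_profiles = mal_profiles,
                            malignant_state = mal_state,
                            seed = derive_seed(seed, 104729L))
  realized_state <- pb$truth$state_fractions
  realized_type <- matrix(0, n_samples, Tn,
                          dimnames = list(rownames(realized_state),
                                          sim$ref$type_ids))
  for (t in seq_len(Tn)) {
    idx <- which(type_of_state == t)
    realized_type[, t] <- rowSums(realized_state[, idx, drop = FALSE])
  }
  list(ref = sim$ref,
       cells = sim$counts,
       cell_state_labels = sim$state_labels,
       cell_type_labels = sim$type_labels,
       bulk = pb$bulk,
       truth = list(type_fractions = realized_type,
                    state_fractions = realized_state,
                    nominal_type_fractions = type_frac,
                    malignant_profiles = mal_profiles),
       generating_profiles = profiles)
}

#' Per-cell-type benchmark metrics
#'
#' Pearson correlation and mean squared error between estimated and true
#' fraction matrices, computed across samples for each cell type.
#'
#' @param theta_hat N x T estimated fractions.
#' @param theta_true N x T true fractions (same column order).
#' @return Data frame with columns `type`, `pearson_r`, `mse`.
#' @export
benchmark_metrics <- function(theta_hat, theta_true) {
  stopifnot(all(dim(theta_hat) == dim(theta_true)))
  types <- colnames(theta_hat)
  if (is.null(types)) types <- paste0("type", seq_len(ncol(theta_hat)))
  data.frame(
    type = types,
    pearson_r = vapply(seq_len(ncol(theta_hat)), function(t)
      stats::cor(theta_hat[, t], theta_true[, t]), numeric(1)),
    mse = vapply(seq_len(ncol(theta_hat)), function(t)
      mean((theta_hat[, t] - theta_true[, t])^2), numeric(1)),
    stringsAsFactors = FALSE)
}
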