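make_phi <- function(rows) {
  phi <- do.call(rbind, rows)
  dimnames(phi) <- list(paste0("s", seq_len(nrow(phi))),
                        paste0("g", seq_len(ncol(phi))))
  phi
}

test_that("sample_assignments conserves reads and handles edge cases", {
  phi <- make_phi(list(c(0.9, 0.1)))
  x <- c(5L, 7L)
  U <- sample_assignments(x, phi, mu = 1)
  expect_equal(unname(U[1, ]), x)  # single state takes everything

  phi2 <- make_phi(list(c(0.9, 0.1), c(0.1, 0.9)))
  set.seed(1)
  U2 <- sample_assignments(x, phi2, mu = c(1, 0))
  expect_equal(unname(U2[1, ]), x)  # zero-weight state gets nothing
  expect_equal(unname(U2[2, ]), c(0L, 0L))

  set.seed(2)
  for (i in 1:20) {
    mu <- as.numeric(rdirichlet(1, c(1, 1)))
    U <- sample_assignments(c(13L, 4L), phi2, mu)
    expect_equal(unname(colSums(U)), c(13, 4))  # exact conservation
    expect_true(all(U >= 0))
  }
})

test_that("assignment split follows the binomial law for identical profiles", {
  phi <- make_phi(list(c(0.5, 0.5), c(0.5, 0.5)))
  set.seed(3)
  draws <- replicate(1000, sample_assignments(c(1000L, 0L), phi,
                                              c(0.5, 0.5))[1, 1])
  # mean 500, var 250; allow 4 standard errors of the MC mean
  expect_lt(abs(mean(draws) - 500), 4 * sqrt(250 / 1000))
  expect_equal(sd(draws), sqrt(250), tolerance = 0.1)
})

test_that("sample_theta draws from Dirichlet(alpha + assigned reads)", {
  U <- rbind(c(20, 10), c(8, 2))  # totals (30, 10)
  set.seed(4)
  draws <- t(replicate(1e4, sample_theta(U, alpha = 1e-8)))
  expect_equal(colMeans(draws), c(0.75, 0.25), tolerance = 0.01)

  U2 <- rbind(c(900, 100), c(0, 0))  # totals (1000, 0)
  set.seed(5)
  conc <- t(replicate(100, sample_theta(U2, alpha = 1e-8)))
  expect_true(all(conc[, 1] > 0.99))
})

test_that("run_gibbs reduces to the data for a single state", {
  tc <- tiny_cells()
  ref <- build_state_reference(tc$counts[5:6, , drop = FALSE],
                               c("b1", "b1"), c("B", "B"))
  X <- matrix(c(10L, 5L, 3L, 2L), 1, 4, dimnames = list("n1", paste0("g", 1:4)))
  bulk <- bulk_expression(X)
  res <- run_gibbs(bulk, ref, gibbs_config(chain_length = 20, burn_in = 5,
                                           seed = 1))
  expect_equal(unname(res$mu_bar[1, ]), 1)
  expect_equal(unname(res$U_bar[1, 1, ]), unname(X[1, ]))
})

test_that("identical profiles give symmetric posterior fractions", {
  counts <- rbind(c(5, 5), c(5, 5))
  colnames(counts) <- c("g1", "g2")
  ref <- build_state_reference(counts, c("s1", "s2"), c("A", "A"))
  # with identical rows the likelihood is flat in mu, so the posterior is
  # the prior; a unit Dirichlet and low depth keep the chain mixing
  X <- matrix(c(2L, 2L), 1, 2, dimnames = list("n1", c("g1", "g2")))
  res <- run_gibbs(bulk_expression(X), ref,
                   gibbs_config(alpha = 1, chain_length = 20000,
                                burn_in = 1000, seed = 2))
  expect_equal(unname(res$mu_bar[1, ]), c(0.5, 0.5), tolerance = 0.02)
})

test_that("posterior mean matches the enumeration oracle on a tiny instance", {
  phi <- make_phi(list(c(0.9, 0.1), c(0.1, 0.9)))
  x <- c(8L, 2L)
  exact <- exact_posterior_mu(x, phi, alpha = 1e-8)
  counts <- rbind(c(9, 1), c(1, 9))
  colnames(counts) <- c("g1", "g2")
  ref <- build_state_reference(counts, c("s1", "s2"), c("A", "A"),
                               pseudo_min = 1e-8)
  # use the exact phi rather than the fixture-estimated one
  ref$phi <- phi
  dimnames(ref$phi) <- list(ref$state_ids, ref$gene_ids)
  X <- matrix(x, 1, 2, dimnames = list("n1", c("g1", "g2")))
  res <- run_gibbs(bulk_expression(X), ref, gibbs_config(seed = 3))
  expect_equal(unname(res$mu_bar[1, ]), exact, tolerance = 0.02)
})

test_that("both conditionals target the exact posterior in the ergodic regime", {
  # with a unit Dirichlet prior the chain mixes freely, so arbitrary
  # random instances can be compared against full enumeration; the longer
  # schedule brings Monte-Carlo error below the tolerance
  set.seed(101)
  worst <- 0
  for (i in 1:5) {
    S <- sample(2:3, 1)
    G <- sample(2:3, 1)
    phi <- t(apply(rdirichlet(S, rep(1, G)), 1, norm_to_one, 1e-8))
    dimnames(phi) <- list(paste0("s", 1:S), paste0("G", 1:G))
    x <- as.integer(rmultinom(1, sample(5:20, 1), rep(1 / G, G)))
    exact <- exact_posterior_mu(x, phi, alpha = 1)
    ref <- structure(
      list(phi = phi, state_ids = rownames(phi), type_ids = "t",
           type_of_state = rep(1L, S), malignant_type = NA_integer_,
           gene_ids = colnames(phi), state_counts = phi, pseudo_min = 1e-8),
      class = "cell_state_reference")
    X <- matrix(x, 1, G, dimnames = list("n1", colnames(phi)))
    got <- run_gibbs(bulk_expression(X), ref,
                     gibbs_config(alpha = 1, chain_length = 20000,
                                  burn_in = 2000, seed = 900 + i))$mu_bar[1, ]
    worst <- max(worst, max(abs(got - exact)))
  }
  expect_lt(worst, 0.02)
})

test_that("the sampler is deterministic given a seed and stable across seeds", {
  tc <- tiny_cells()
  ref <- build_state_reference(tc$counts, tc$states, tc$types)
  X <- matrix(rpois(8, 2000), 2, 4,
              dimnames = list(c("n1", "n2"), paste0("g", 1:4)))
  bulk <- bulk_expression(X)
  r1 <- run_gibbs(bulk, ref, gibbs_config(seed = 7))
  r2 <- run_gibbs(bulk, ref, gibbs_config(seed = 7))
  expect_identical(r1$mu_bar, r2$mu_bar)   # bitwise reproducible
  expect_identical(r1$U_bar, r2$U_bar)
  r3 <- run_gibbs(bulk, ref, gibbs_config(seed = 8))
  expect_equal(r1$mu_bar, r3$mu_bar, tolerance = 0.01)  # MC error only
})

test_that("posterior means are consistent as depth grows", {
  set.seed(11)
  sim <- simulate_reference(n_types = 3, n_genes = 200, seed = 11,
                            malignant_type = NA)
  mu_star <- c(0.6, 0.3, 0.1)
  p <- as.numeric(mu_star %*% sim$ref$phi)
  X <- matrix(as.integer(rmultinom(1, 1e5, p)), 1,
              dimnames = list("n1", colnames(sim$ref$phi)))
  res <- run_gibbs(bulk_expression(X), sim$ref, gibbs_config(seed = 11))
  expect_equal(unname(res$mu_bar[1, ]), mu_star, tolerance = 0.01)
})

test_that("read conservation holds for the posterior mean assignments", {
  tc <- tiny_cells()
  ref <- build_state_reference(tc$counts, tc$states, tc$types)
  X <- matrix(rpois(8, 500), 2, 4,
              dimnames = list(c("n1", "n2"), paste0("g", 1:4)))
  bulk <- bulk_expression(X)
  res <- run_gibbs(bulk, ref, gibbs_config(chain_length = 100, burn_in = 20,
                                           seed = 1))
  expect_equal(apply(res$U_bar, c(1, 3), sum), bulk$X * 1.0,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(rowSums(res$mu_bar)), c(1, 1), tolerance = 1e-9)
})

test_that("zero-read samples are rejected by name", {
  X <- matrix(c(1L, 0L, 2L, 0L), 2, 2,
              dimnames = list(c("ok", "empty"), c("g1", "g2")))
  expect_error(bulk_expression(X), "empty")
})

test_that("aggregate_states sums fractions and reads over h", {
  tc <- tiny_cells()
  ref <- build_state_reference(tc$counts, tc$states, tc$types, "A")
  X <- matrix(rpois(4, 1000), 1, 4, dimnames = list("n1", paste0("g", 1:4)))
  bulk <- bulk_expression(X)
  res <- run_gibbs(bulk, ref, gibbs_config(chain_length = 100, burn_in = 20,
                                           seed = 2))
  est <- aggregate_states(res, ref)
  expect_equal(unname(est$theta0[1, "A"]),
               unname(res$mu_bar[1, "a1"] + res$mu_bar[1, "a2"]))
  # conservation carries through: sum over types recovers the bulk counts
  expect_equal(unname(apply(est$Z, c(1, 3), sum)[1, ]), unname(X[1, ]) * 1.0)
  expect_equal(unname(rowSums(est$theta0)), 1, tolerance = 1e-9)
})
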