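test_that("norm_to_one renormalizes and floors zeros", {
  expect_equal(norm_to_one(c(2, 2), 0.1), c(0.5, 0.5))
  # zeros become pseudo_min, nonzeros keep proportions, total is 1
  expect_equal(norm_to_one(c(1, 0, 1), 0.1), c(0.45, 0.1, 0.45))
  out <- norm_to_one(c(3, 0, 0, 1), 1e-3)
  expect_equal(sum(out), 1)
  expect_equal(out[2], 1e-3)
  expect_equal(out[1] / out[4], 3)
})

test_that("norm_to_one rejects degenerate input", {
  expect_error(norm_to_one(c(0, 0), 0.1), "all-zero")
  expect_error(norm_to_one(c(1, 0, 0), 0.6), "too large")
  expect_error(norm_to_one(c(-1, 2), 0.1), "negative")
})

test_that("norm_to_one is idempotent on strictly positive rows", {
  set.seed(1)
  for (i in 1:5) {
    x <- rexp(20)
    once <- norm_to_one(x, 1e-8)
    expect_equal(norm_to_one(once, 1e-8), once, tolerance = 1e-12)
  }
})

test_that("build_state_reference sums cells per state and normalizes", {
  counts <- rbind(c(1, 1), c(1, 3))
  colnames(counts) <- c("g1", "g2")
  ref <- build_state_reference(counts, c("s1", "s1"), c("A", "A"))
  expect_equal(unname(ref$phi[1, ]), c(1 / 3, 2 / 3))
  expect_equal(rowSums(ref$phi), c(s1 = 1), tolerance = 1e-12)
})

test_that("state/type bookkeeping records the surjection h", {
  counts <- matrix(1, 3, 2, dimnames = list(NULL, c("g1", "g2")))
  ref <- build_state_reference(counts, c("s1", "s1", "s2"), rep("A", 3))
  expect_length(ref$state_ids, 2L)
  expect_length(ref$type_ids, 1L)
  expect_equal(ref$type_of_state, c(1L, 1L))
})

test_that("invalid label structure is rejected", {
  counts <- matrix(1, 2, 2, dimnames = list(NULL, c("g1", "g2")))
  expect_error(
    build_state_reference(counts, c("s1", "s1"), c("A", "B")),
    "spans multiple")
  zero <- rbind(c(1, 1), c(0, 0))
  colnames(zero) <- c("g1", "g2")
  expect_error(
    build_state_reference(zero, c("s1", "s2"), c("A", "A")),
    "zero total")
})

test_that("TPM-like real-valued input is summed with a warning", {
  counts <- rbind(c(1.5, 0.5), c(0.5, 1.5))
  colnames(counts) <- c("g1", "g2")
  expect_warning(
    ref <- build_state_reference(counts, c("s1", "s1"), c("A", "A")),
    "non-integer")
  expect_equal(unname(ref$phi[1, ]), c(0.5, 0.5))
})

test_that("reference construction is invariant to cell order", {
  tc <- tiny_cells()
  ref1 <- build_state_reference(tc$counts, tc$states, tc$types, "A")
  perm <- c(3, 1, 6, 2, 5, 4)
  ref2 <- build_state_reference(tc$counts[perm, ], tc$states[perm],
                                tc$types[perm], "A")
  expect_equal(ref1$phi[ref2$state_ids, ], ref2$phi)
})

test_that("permuting gene columns permutes outputs consistently", {
  tc <- tiny_cells()
  ref1 <- build_state_reference(tc$counts, tc$states, tc$types)
  gperm <- c(3, 1, 4, 2)
  ref2 <- build_state_reference(tc$counts[, gperm], tc$states, tc$types)
  expect_equal(ref2$phi, ref1$phi[, gperm])
})

test_that("build_type_reference matches state reference when types = states", {
  tc <- tiny_cells()
  tref <- build_type_reference(tc$counts, tc$states)
  sref <- build_state_reference(tc$counts, tc$states, tc$states)
  expect_equal(tref$phi_prime, sref$phi)
  one <- build_type_reference(rbind(g = c(2, 1), h = c(1, 2)), c("A", "A"))
  expect_equal(unname(one$phi_prime[1, ]), c(0.5, 0.5))
})

test_that("collapse_to_types pools counts over states of a type", {
  tc <- tiny_cells()
  sref <- build_state_reference(tc$counts, tc$states, tc$types)
  tref1 <- collapse_to_types(sref)
  tref2 <- build_type_reference(tc$counts, tc$types)
  expect_equal(tref1$phi_prime, tref2$phi_prime)
})

test_that("duplicated gene ids are rejected, ids are case-normalized", {
  counts <- matrix(1, 2, 2, dimnames = list(NULL, c("abc", "ABC")))
  expect_error(build_state_reference(counts, c("s", "s"), c("A", "A")),
               "duplicated")
  counts2 <- matrix(1, 1, 2, dimnames = list(NULL, c("abc", "xyz")))
  ref <- build_state_reference(counts2, "s", "A")
  expect_equal(ref$gene_ids, c("ABC", "XYZ"))
})

test_that("outlier genes are removed by the strict share rule", {
  # 10 samples; gene "hot" takes 2% of reads in 3 of them (3/10 > 10%)
  set.seed(5)
  G <- 300
  X <- matrix(rpois(10 * G, 100), 10, G)
  colnames(X) <- paste0("g", seq_len(G))
  X[, 1] <- round(rowSums(X[, -1]) * 0.005 / (1 - 0.005))  # 0.5% everywhere
  X[1:3, 2] <- round(rowSums(X[1:3, -2]) * 0.025)          # ~2.4% in 3 samples
  bulk <- bulk_expression(X)
  kept <- filter_genes(bulk, colnames(X), annotation = NULL,
                       drop_categories = "outliers")
  expect_true("G1" %in% kept)    # below threshold everywhere
  expect_false("G2" %in% kept)   # >1% in >10% of samples
})

test_that("annotation-driven categories are removed", {
  X <- matrix(10, 4, 5,
              dimnames = list(NULL, c("FOO", "BAR", "RPL3", "BAZ", "QUX")))
  bulk <- bulk_expression(X)
  ann <- gene_annotation(colnames(X),
                         chromosome = c("chr1", "chrY", "chr2", "chrM", "chr3"),
                         biotype = c("protein_coding", "protein_coding",
                                     "protein_coding", "protein_coding",
                                     "lincRNA"))
  cats <- c("sex_chromosomes", "mitochondrial", "ribosomal")
  kept <- filter_genes(bulk, colnames(X), ann, drop_categories = cats)
  expect_false("BAR" %in% kept)   # chrY
  expect_false("BAZ" %in% kept)   # chrM
  expect_false("RPL3" %in% kept)  # ribosomal-protein symbol prefix
  expect_true(all(c("FOO", "QUX") %in% kept))
  pc <- filter_genes(bulk, colnames(X), ann, drop_categories = cats,
                     protein_coding_only = TRUE)
  expect_false("QUX" %in% pc)
})

test_that("missing annotation skips chromosome filters with a warning", {
  X <- matrix(10, 3, 3, dimnames = list(NULL, c("A1", "A2", "RPS9")))
  bulk <- bulk_expression(X)
  expect_warning(
    kept <- filter_genes(bulk, colnames(X), NULL,
                         drop_categories = c("sex_chromosomes", "ribosomal")),
    "skipped")
  expect_false("RPS9" %in% kept)  # prefix rule still applies
  expect_error(
    suppressWarnings(filter_genes(bulk, c("NOPE1", "NOPE2"), NULL)),
    "no gene ids")
})
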