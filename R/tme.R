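#' Spearman correlation between malignant expression and a cell fraction
#'
#' For every gene, computes the Spearman rank correlation (average ranks
#' for ties) between its per-sample normalized malignant expression and the
#' fraction of a query nonmalignant cell type. Genes with zero variance are
#' flagged and get `NA` rather than being dropped.
#'
#' @param Z_mal_norm N x G matrix of per-sample normalized malignant
#'   expression (each row the sample's malignant reads as fractions).
#' @param theta_query Length-N query cell type fractions.
#' @return Data frame with `gene`, `rho`, `rank` (descending by rho;
#'   `NA` rho ranked last) and `zero_variance`.
#' @export
rank_correlation <- function(Z_mal_norm, theta_query) {
  Z <- as.matrix(Z_mal_norm)
  stopifnot(length(theta_query) == nrow(Z), nrow(Z) >= 3L)
  ry <- rank(theta_query)
  const <- apply(Z, 2L, function(col) max(col) == min(col)) |
    (max(ry) == min(ry))
  rho <- rep(NA_real_, ncol(Z))
  if (!all(const)) {
    rx <- apply(Z[, !const, drop = FALSE], 2L, rank)
    rho[!const] <- suppressWarnings(as.numeric(stats::cor(rx, ry)))
  }
  genes <- colnames(Z)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(Z)))
  out <- data.frame(gene = genes, rho = rho,
                    zero_variance = const, stringsAsFactors = FALSE)
  out$rank <- rank(-out$rho, na.last = "keep")
  out$rank[is.na(out$rank)] <- sum(!is.na(out$rho)) + seq_len(sum(is.na(out$rho)))
  out[order(out$rank), , drop = FALSE]
}

# RSS of an OLS fit y ~ design (with intercept already in design); NA if
# the design is rank deficient
ols_rss <- function(y, design) {
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) return(NA_real_)
  res <- stats::lm.fit(design, y)$residuals
  sum(res^2)
}

#' Likelihood-ratio regress-out filter
#'
#' Tests, per gene, the null hypothesis that the gene's expression in the
#' query cell type alone explains the variation in the query cell fraction.
#' Two nested Gaussian linear models are compared — null:
#' `fraction ~ query expression`; alternative adds the malignant
#' expression — and `2 * delta log-likelihood = N * log(RSS0 / RSS1)` is
#' referred to a chi-squared distribution with one degree of freedom.
#' Genes with `p < alpha_level` pass: their malignant expression carries
#' information about the fraction beyond the query cell's own expression.
#' Rank-deficient designs give `p = 1` and are flagged.
#'
#' @param theta_query Length-N query cell fractions.
#' @param expr_query N-vector or N x G matrix of query-cell expression.
#' @param expr_mal N-vector or N x G matrix of malignant expression
#'   (same genes).
#' @param alpha_level Pass threshold (default 0.01).
#' @return Data frame with `gene`, `p_value`, `pass`, `degenerate`.
#' @export
regress_out_filter <- function(theta_query, expr_query, expr_mal,
                               alpha_level = 0.01) {
  eq <- as.matrix(expr_query)
  em <- as.matrix(expr_mal)
  stopifnot(nrow(eq) == length(theta_query), all(dim(eq) == dim(em)))
  N <- length(theta_query)
  G <- ncol(eq)
  p <- numeric(G)
  degenerate <- logical(G)
  for (g in seq_len(G)) {
    rss0 <- ols_rss(theta_query, cbind(1, eq[, g]))
    rss1 <- ols_rss(theta_query, cbind(1, eq[, g], em[, g]))
    if (is.na(rss0) || is.na(rss1) || rss1 <= 0) {
      p[g] <- 1
      degenerate[g] <- TRUE
    } else {
      lrt <- N * log(rss0 / rss1)
      p[g] <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    }
  }
  genes <- colnames(eq)
  if (is.null(genes)) genes <- paste0("gene", seq_len(G))
  data.frame(gene = genes, p_value = p, pass = p < alpha_level,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

# one-sided two-proportion z-test that x1/n1 > x2/n2
prop_z_pvalue <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pmax(pp * (1 - pp) * (1 / n1 + 1 / n2), 0))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Malignant-specificity gene filter
#'
#' Flags genes that are intrinsic to malignant cells: expressed at a
#' significantly higher level in at least one malignant cell state than in
#' every nonmalignant cell type. For each malignant state and nonmalignant
#' type the raw count sums underlying the reference are compared by a
#' one-sided two-proportion z-test with a fold-change floor; a gene's
#' p-value is the best (over malignant states) worst-case (over
#' nonmalignant types) p, and Benjamini-Hochberg correction is applied
#' across genes.
#'
#' @param ref A `cell_state_reference` with a designated malignant type.
#' @param fold_threshold Required fold change of the malignant state's
#'   profile over each nonmalignant type's profile (default 1.5).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return Data frame with `gene`, `p_value`, `p_adjusted`, `fold_ok`,
#'   `pass`.
#' @export
malignant_specificity_filter <- function(ref, fold_threshold = 1.5,
                                         alpha = 0.05) {
  stopifnot(inherits(ref, "cell_state_reference"))
  if (is.na(ref$malignant_type)) stop("no malignant type designated")
  type_ref <- collapse_to_types(ref)
  mal_states <- which(ref$type_of_state == ref$malignant_type)
  env_types <- setdiff(seq_along(ref$type_ids), ref$malignant_type)
  if (length(env_types) == 0L) stop("no nonmalignant types in the reference")

  G <- length(ref$gene_ids)
  n_state <- rowSums(ref$state_counts)
  n_type <- rowSums(type_ref$type_counts)

  best_p <- rep(1, G)
  fold_ok <- rep(FALSE, G)
  for (s in mal_states) {
    worst_p <- rep(0, G)
    ok <- rep(TRUE, G)
    for (t in env_types) {
      pvals <- prop_z_pvalue(ref$state_counts[s, ], n_state[s],
                             type_ref$type_counts[t, ], n_type[t])
      worst_p <- pmax(worst_p, pvals)
      ok <- ok & (ref$phi[s, ] > fold_threshold * type_ref$phi_prime[t, ])
    }
    sel <- ok & (!fold_ok | worst_p < best_p)
    best_p[sel] <- worst_p[sel]
    fold_ok <- fold_ok | ok
  }
  p_adj <- stats::p.adjust(best_p, method = "BH")
  data.frame(gene = ref$gene_ids, p_value = best_p, p_adjusted = p_adj,
             fold_ok = fold_ok, pass = fold_ok & p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Score deconvolved expression against signature profiles
#'
#' Restricts to samples whose query cell fraction exceeds `min_fraction`,
#' depth-normalizes and log2-transforms the deconvolved expression, and
#' computes the Pearson correlation of each sample against each signature
#' profile over a marker gene set.
#'
#' @param expr_deconv N x G deconvolved expression (counts or count-scale
#'   values) for the cell type of interest.
#' @param signatures Named list of signature profiles (gene-named numeric
#'   vectors) or an L x G matrix with rownames.
#' @param markers Character vector of marker gene ids.
#' @param theta Length-N fractions of the cell type (filtering).
#' @param min_fraction Minimum fraction for a sample to be scored
#'   (default 0.05, strict `>`).
#' @param transform `"log2cpm"` (default: log2 of counts-per-million + 1)
#'   or `"none"`.
#' @return Data frame of per-sample scores, one column per signature, with
#'   the transformation recorded in `attr(, "transform")`.
#' @export
signature_score <- function(expr_deconv, signatures, markers, theta,
                            min_fraction = 0.05, transform = c("log2cpm", "none")) {
  transform <- match.arg(transform)
  E <- as.matrix(expr_deconv)
  stopifnot(length(theta) == nrow(E))
  if (is.matrix(signatures)) {
    signatures <- stats::setNames(
      lapply(seq_len(nrow(signatures)), function(i) signatures[i, ]),
      rownames(signatures))
  }
  markers <- normalize_gene_ids(markers)
  genes <- normalize_gene_ids(colnames(E))
  colnames(E) <- genes
  markers <- intersect(markers, genes)
  for (sg in signatures) {
    markers <- intersect(markers, normalize_gene_ids(names(sg)))
  }
  if (length(markers) < 3L) stop("fewer than 3 marker genes shared by ",
                                 "expression and all signatures")
  keep <- which(theta > min_fraction)
  if (length(keep) == 0L) stop("no samples pass the fraction filter")

  tf <- function(v) {
    if (transform == "none") return(v)
    log2(v / sum(v) * 1e6 + 1)
  }
  scores <- matrix(NA_real_, length(keep), length(signatures),
                   dimnames = list(rownames(E)[keep], names(signatures)))
  sig_t <- lapply(signatures, function(sg) {
    sg <- sg[match(markers, normalize_gene_ids(names(sg)))]
    tf(as.numeric(sg))
  })
  for (i in seq_along(keep)) {
    e <- tf(E[keep[i], ])[match(markers, genes)]
    for (j in seq_along(sig_t)) {
      scores[i, j] <- stats::cor(e, sig_t[[j]])
    }
  }
  out <- as.data.frame(scores)
  out <- cbind(data.frame(sample = rownames(scores),
                          fraction = theta[keep],
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  attr(out, "transform") <- transform
  out
}
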