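#' Renormalize an expression profile with a pseudo-count floor
#'
#' Rescales a nonnegative profile so that it sums to one, replacing exact
#' zeros by a small floor `pseudo_min`. Nonzero entries keep their mutual
#' proportions and absorb the mass given to the zeros, so the result still
#' sums to one. Profiles with no zeros are simply divided by their sum, which
#' makes the operation idempotent for strictly positive rows.
#'
#' @param x Numeric vector of nonnegative values, at least one positive.
#' @param pseudo_min Positive floor given to zero entries after
#'   renormalization (default `1e-8`).
#' @return Numeric vector of positive values summing to 1.
#' @examples
#' norm_to_one(c(1, 0, 1), pseudo_min = 0.1)
#' @export
norm_to_one <- function(x, pseudo_min = 1e-8) {
  stopifnot(is.numeric(x), length(x) >= 1L, pseudo_min > 0)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("profile contains negative or non-finite entries")
  }
  zero <- x == 0
  if (all(zero)) stop("cannot normalize an all-zero profile")
  n_zero <- sum(zero)
  if (pseudo_min * n_zero >= 1) {
    stop("pseudo_min = ", pseudo_min, " is too large for ", n_zero,
         " zero entries (mass assigned to zeros must stay below 1)")
  }
  out <- x * ((1 - pseudo_min * n_zero) / sum(x))
  out[zero] <- pseudo_min
  out
}

#' Build a cell-state reference from labelled single-cell counts
#'
#' Sums raw counts (or TPM-like nonnegative values) over the cells of each
#' cell state and renormalizes each state profile to the simplex with
#' [norm_to_one()]. Each state must belong to exactly one cell type; the
#' state-to-type map is recorded so that downstream posterior summaries can
#' be aggregated from states to types.
#'
#' @param counts Cells x genes matrix of nonnegative values; column names
#'   are gene ids, row names (optional) cell ids.
#' @param state_labels Character/factor vector, one cell state label per cell.
#' @param type_labels Character/factor vector, one cell type label per cell.
#' @param malignant_type Label of the malignant cell type, or `NULL` for
#'   non-tumor use. At most one type may be designated.
#' @param pseudo_min Pseudo-count floor passed to [norm_to_one()].
#' @return An object of class `cell_state_reference` with elements:
#'   \describe{
#'     \item{phi}{S x G row-stochastic matrix of state profiles.}
#'     \item{state_ids, type_ids, gene_ids}{Label vectors.}
#'     \item{type_of_state}{Integer vector mapping each state to its type.}
#'     \item{malignant_type}{Integer index into `type_ids`, or `NA`.}
#'     \item{state_counts}{Raw per-state gene totals (used by count-based
#'       filters).}
#'     \item{pseudo_min}{The floor used.}
#'   }
#' @export
build_state_reference <- function(counts, state_labels, type_labels,
                                  malignant_type = NULL, pseudo_min = 1e-8) {
  counts <- as_count_matrix(counts, what = "single-cell matrix")
  if (length(state_labels) != nrow(counts) ||
      length(type_labels) != nrow(counts)) {
    stop("state_labels and type_labels must have one entry per cell")
  }
  state_labels <- as.character(state_labels)
  type_labels <- as.character(type_labels)
  if (anyNA(state_labels) || anyNA(type_labels)) {
    stop("every cell needs a state and a type label")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != floor(counts))) {
    warning("non-integer single-cell input: values are summed as-is; ",
            "the multinomial model is being applied to non-integer sums")
  }

  state_ids <- unique(state_labels)
  # each state must sit inside exactly one type
  type_of <- character(length(state_ids))
  for (i in seq_along(state_ids)) {
    tt <- unique(type_labels[state_labels == state_ids[i]])
    if (length(tt) != 1L) {
      stop("cell state '", state_ids[i], "' spans multiple cell types: ",
           paste(tt, collapse = ", "))
    }
    type_of[i] <- tt
  }
  type_ids <- unique(type_of)

  S <- length(state_ids)
  G <- ncol(counts)
  agg <- matrix(0, S, G, dimnames = list(state_ids, colnames(counts)))
  for (i in seq_len(S)) {
    rows <- which(state_labels == state_ids[i])
    agg[i, ] <- if (length(rows) == 1L) counts[rows, ] else colSums(counts[rows, , drop = FALSE])
  }
  tot <- rowSums(agg)
  if (any(tot == 0)) {
    stop("cell state(s) with zero total counts: ",
         paste(state_ids[tot == 0], collapse = ", "))
  }
  phi <- t(apply(agg, 1L, norm_to_one, pseudo_min = pseudo_min))
  dimnames(phi) <- dimnames(agg)

  mal <- NA_integer_
  if (!is.null(malignant_type) && !is.na(malignant_type)) {
    mal <- match(as.character(malignant_type), type_ids)
    if (is.na(mal)) {
      stop("malignant_type '", malignant_type, "' is not among the type labels")
    }
  }

  structure(
    list(phi = phi,
         state_ids = state_ids,
         type_ids = type_ids,
         type_of_state = match(type_of, type_ids),
         malignant_type = mal,
         gene_ids = colnames(counts),
         state_counts = agg,
         pseudo_min = pseudo_min),
    class = "cell_state_reference")
}

#' Build a cell-type reference from labelled single-cell counts
#'
#' Identical arithmetic to [build_state_reference()] with cell types in
#' place of cell states: counts are summed per type and each type profile is
#' renormalized with the pseudo-count floor. The per-type matrix is the
#' prior center for the pooled nonmalignant reference update.
#'
#' @inheritParams build_state_reference
#' @return An object of class `cell_type_reference` with elements
#'   `phi_prime` (T x G row-stochastic), `type_ids`, `gene_ids`,
#'   `type_counts`, `pseudo_min`.
#' @export
build_type_reference <- function(counts, type_labels, pseudo_min = 1e-8) {
  ref <- build_state_reference(counts, state_labels = type_labels,
                               type_labels = type_labels,
                               malignant_type = NULL,
                               pseudo_min = pseudo_min)
  structure(
    list(phi_prime = ref$phi,
         type_ids = ref$type_ids,
         gene_ids = ref$gene_ids,
         type_counts = ref$state_counts,
         pseudo_min = pseudo_min),
    class = "cell_type_reference")
}

#' Collapse a cell-state reference to its cell-type reference
#'
#' Pools the raw per-state count totals over the states of each type and
#' renormalizes, giving the same result as [build_type_reference()] on the
#' original cells.
#'
#' @param ref A `cell_state_reference`.
#' @return A `cell_type_reference`.
#' @export
collapse_to_types <- function(ref) {
  stopifnot(inherits(ref, "cell_state_reference"))
  Tn <- length(ref$type_ids)
  agg <- matrix(0, Tn, length(ref$gene_ids),
                dimnames = list(ref$type_ids, ref$gene_ids))
  for (t in seq_len(Tn)) {
    rows <- which(ref$type_of_state == t)
    agg[t, ] <- colSums(ref$state_counts[rows, , drop = FALSE])
  }
  phi_prime <- t(apply(agg, 1L, norm_to_one, pseudo_min = ref$pseudo_min))
  dimnames(phi_prime) <- dimnames(agg)
  structure(
    list(phi_prime = phi_prime,
         type_ids = ref$type_ids,
         gene_ids = ref$gene_ids,
         type_counts = agg,
         pseudo_min = ref$pseudo_min),
    class = "cell_type_reference")
}

#' Restrict a reference to a gene subset
#'
#' Subsets the stored raw count totals to `genes` and re-applies the
#' pseudo-count normalization, so profiles are renormalized over the kept
#' genes. Filtering therefore happens on counts first and the floor is
#' applied after.
#'
#' @param ref A `cell_state_reference` or `cell_type_reference`.
#' @param genes Character vector of gene ids to keep (order respected).
#' @return An object of the same class restricted to `genes`.
#' @export
subset_reference <- function(ref, genes) {
  genes <- as.character(genes)
  if (!all(genes %in% ref$gene_ids)) {
    stop("unknown gene id(s): ",
         paste(utils::head(setdiff(genes, ref$gene_ids), 5L), collapse = ", "))
  }
  if (inherits(ref, "cell_state_reference")) {
    agg <- ref$state_counts[, genes, drop = FALSE]
    phi <- t(apply(agg, 1L, norm_to_one, pseudo_min = ref$pseudo_min))
    dimnames(phi) <- dimnames(agg)
    ref$phi <- phi
    ref$state_counts <- agg
    ref$gene_ids <- genes
    ref
  } else if (inherits(ref, "cell_type_reference")) {
    agg <- ref$type_counts[, genes, drop = FALSE]
    phi_prime <- t(apply(agg, 1L, norm_to_one, pseudo_min = ref$pseudo_min))
    dimnames(phi_prime) <- dimnames(agg)
    ref$phi_prime <- phi_prime
    ref$type_counts <- agg
    ref$gene_ids <- genes
    ref
  } else {
    stop("not a reference object")
  }
}

#' @export
print.cell_state_reference <- function(x, ...) {
  cat("Cell-state reference:", nrow(x$phi), "states /",
      length(x$type_ids), "types x", ncol(x$phi), "genes\n")
  if (!is.na(x$malignant_type)) {
    cat("Malignant type:", x$type_ids[x$malignant_type], "\n")
  }
  invisible(x)
}

#' @export
print.cell_type_reference <- function(x, ...) {
  cat("Cell-type reference:", nrow(x$phi_prime), "types x",
      ncol(x$phi_prime), "genes\n")
  invisible(x)
}

# coerce input to a plain dense matrix with gene column names, checking ids
as_count_matrix <- function(x, what = "matrix") {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix")
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("gene", seq_len(ncol(x)))
  }
  cn <- normalize_gene_ids(colnames(x))
  if (anyDuplicated(cn)) {
    stop("duplicated gene ids in ", what, ": ",
         paste(utils::head(unique(cn[duplicated(cn)]), 5L), collapse = ", "))
  }
  colnames(x) <- cn
  x
}

# gene ids are matched case-insensitively by upper-casing once on entry
normalize_gene_ids <- function(ids) toupper(trimws(as.character(ids)))
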