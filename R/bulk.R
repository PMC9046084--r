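#' Construct a bulk expression object
#'
#' Wraps a samples x genes matrix of raw counts with ids and per-sample
#' totals. Real-valued input (e.g. TPM) is rounded to the nearest integer
#' with a warning, since the generative model is defined on read counts.
#'
#' @param X Samples x genes matrix of nonnegative counts; column names are
#'   gene ids, row names sample ids.
#' @return An object of class `bulk_expression` with elements `X` (integer
#'   matrix), `R` (per-sample totals), `sample_ids`, `gene_ids`.
#' @export
bulk_expression <- function(X) {
  X <- as_count_matrix(X, what = "bulk matrix")
  if (any(X < 0)) stop("bulk counts must be nonnegative")
  if (any(X != floor(X))) {
    warning("non-integer bulk input rounded to counts; ",
            "the model is defined on raw read counts")
    X <- round(X)
  }
  if (is.null(rownames(X))) rownames(X) <- paste0("sample", seq_len(nrow(X)))
  R <- rowSums(X)
  if (any(R == 0)) {
    stop("bulk sample(s) with zero total reads: ",
         paste(rownames(X)[R == 0], collapse = ", "))
  }
  structure(
    list(X = X, R = R,
         sample_ids = rownames(X), gene_ids = colnames(X)),
    class = "bulk_expression")
}

#' @export
print.bulk_expression <- function(x, ...) {
  cat("Bulk expression:", nrow(x$X), "samples x", ncol(x$X), "genes;",
      "median depth", stats::median(x$R), "\n")
  invisible(x)
}

#' Align a bulk matrix and a reference on a shared gene set
#'
#' Subsets both objects to `genes` (default: their intersection, in
#' reference order), so that downstream sampling can assume identical gene
#' order.
#'
#' @param bulk A `bulk_expression`.
#' @param ref A `cell_state_reference` or `cell_type_reference`.
#' @param genes Optional gene ids to use; defaults to the intersection.
#' @return List with elements `bulk` and `ref`, both restricted to `genes`.
#' @export
align_genes <- function(bulk, ref, genes = NULL) {
  stopifnot(inherits(bulk, "bulk_expression"))
  if (is.null(genes)) genes <- intersect(ref$gene_ids, bulk$gene_ids)
  genes <- normalize_gene_ids(genes)
  if (length(genes) == 0L) stop("bulk and reference share no gene ids")
  bulk <- bulk_expression(bulk$X[, genes, drop = FALSE])
  ref <- subset_reference(ref, genes)
  list(bulk = bulk, ref = ref)
}

#' Construct a gene annotation table
#'
#' Minimal per-gene annotation (chromosome and biotype) used by the gene
#' filter. Lookups of genes absent from the table return `"unknown"`.
#'
#' @param gene_ids Character vector of gene ids.
#' @param chromosome Chromosome labels (e.g. `"chr1"`, `"chrX"`); recycled
#'   `"unknown"` if omitted.
#' @param biotype Biotype labels (e.g. `"protein_coding"`,
#'   `"ribosomal_protein"`); `"unknown"` if omitted.
#' @return A `gene_annotation` data frame.
#' @export
gene_annotation <- function(gene_ids, chromosome = NULL, biotype = NULL) {
  gene_ids <- normalize_gene_ids(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids in annotation")
  n <- length(gene_ids)
  if (is.null(chromosome)) chromosome <- rep("unknown", n)
  if (is.null(biotype)) biotype <- rep("unknown", n)
  stopifnot(length(chromosome) == n, length(biotype) == n)
  structure(
    data.frame(gene_id = gene_ids,
               chromosome = as.character(chromosome),
               biotype = as.character(biotype),
               stringsAsFactors = FALSE),
    class = c("gene_annotation", "data.frame"))
}

annotation_lookup <- function(annotation, genes, field) {
  if (is.null(annotation)) return(rep("unknown", length(genes)))
  i <- match(genes, annotation$gene_id)
  out <- toupper(annotation[[field]][i])
  out[is.na(out)] <- "unknown"
  out
}

#' Select genes for deconvolution
#'
#' Intersects the bulk and reference gene sets and removes gene classes
#' known to carry batch effects or sex-specific signal, plus bulk outliers:
#' \itemize{
#'   \item genes on chrX, chrY or chrM (mitochondrial);
#'   \item ribosomal-protein genes (by biotype, or by the RPL/RPS symbol
#'     prefix when the annotation lacks biotypes);
#'   \item outlier genes taking more than `outlier_frac` of a sample's
#'     total reads in strictly more than `outlier_sample_frac` of samples;
#'   \item optionally, everything that is not protein-coding.
#' }
#'
#' @param bulk A `bulk_expression`.
#' @param reference_genes Character vector of reference gene ids.
#' @param annotation Optional [gene_annotation()]; when `NULL` the
#'   chromosome/biotype categories are skipped with a warning and only the
#'   symbol-prefix and outlier rules apply.
#' @param outlier_frac Per-sample read-share threshold (default 0.01,
#'   strict `>`).
#' @param outlier_sample_frac Fraction-of-samples threshold (default 0.10,
#'   strict `>`).
#' @param drop_categories Character subset of
#'   `c("sex_chromosomes", "mitochondrial", "ribosomal", "outliers")`.
#' @param protein_coding_only If `TRUE`, keep only genes annotated
#'   protein-coding.
#' @return Character vector of retained gene ids (reference order).
#' @export
filter_genes <- function(bulk, reference_genes, annotation = NULL,
                         outlier_frac = 0.01, outlier_sample_frac = 0.10,
                         drop_categories = c("sex_chromosomes",
                                             "mitochondrial",
                                             "ribosomal", "outliers"),
                         protein_coding_only = FALSE) {
  stopifnot(inherits(bulk, "bulk_expression"))
  drop_categories <- match.arg(drop_categories, several.ok = TRUE)
  reference_genes <- normalize_gene_ids(reference_genes)
  genes <- reference_genes[reference_genes %in% bulk$gene_ids]
  if (length(genes) == 0L) stop("bulk and reference share no gene ids")

  if (is.null(annotation) &&
      any(c("sex_chromosomes", "mitochondrial") %in% drop_categories)) {
    warning("no gene annotation supplied: chromosome-based filters skipped")
  }
  chrom <- annotation_lookup(annotation, genes, "chromosome")
  biotype <- annotation_lookup(annotation, genes, "biotype")

  drop <- rep(FALSE, length(genes))
  if ("sex_chromosomes" %in% drop_categories) {
    drop <- drop | chrom %in% c("CHRX", "CHRY", "X", "Y")
  }
  if ("mitochondrial" %in% drop_categories) {
    drop <- drop | chrom %in% c("CHRM", "CHRMT", "M", "MT")
  }
  if ("ribosomal" %in% drop_categories) {
    ribo <- biotype %in% c("RIBOSOMAL_PROTEIN", "RRNA")
    # fall back to symbol prefixes where the annotation is silent
    ribo <- ribo | grepl("^RP[LS]\\d", genes)
    drop <- drop | ribo
  }
  if ("outliers" %in% drop_categories) {
    share <- bulk$X[, genes, drop = FALSE] / bulk$R
    n_exceed <- colSums(share > outlier_frac)
    drop <- drop | (n_exceed / nrow(bulk$X) > outlier_sample_frac)
  }
  if (protein_coding_only) {
    drop <- drop | biotype != "PROTEIN_CODING"
  }
  kept <- genes[!drop]
  if (length(kept) == 0L) stop("no genes survive filtering")
  kept
}
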