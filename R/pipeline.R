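#' @keywords internal
"_PACKAGE"

#' Full deconvolution pipeline
#'
#' Convenience wrapper running the standard workflow: gene alignment,
#' first-pass Gibbs sampling at cell-state resolution, aggregation to cell
#' types, and (optionally) the reference update and the second-pass
#' re-estimation of fractions.
#'
#' @param bulk A `bulk_expression`.
#' @param ref A `cell_state_reference`.
#' @param cfg A [gibbs_config()].
#' @param update If `TRUE` (default), run [update_reference()] and
#'   [refit_theta()].
#' @param sigma Log-normal prior scale for the nonmalignant update.
#' @param cg_max_iter Conjugate-gradient iteration cap.
#' @param genes Optional gene subset (e.g. from [filter_genes()]).
#' @return A `deconvolution_result` with `summary` (state posterior),
#'   `estimate` (type-level `theta0`/`Z`), and, when `update = TRUE`,
#'   `updated` (the `updated_reference`) and `theta_f`.
#' @export
deconvolve <- function(bulk, ref, cfg = gibbs_config(), update = TRUE,
                       sigma = 2, cg_max_iter = 1e5, genes = NULL) {
  al <- align_genes(bulk, ref, genes)
  summary <- run_gibbs(al$bulk, al$ref, cfg)
  est <- aggregate_states(summary, al$ref)
  out <- list(summary = summary, estimate = est,
              bulk = al$bulk, ref = al$ref)
  if (update) {
    type_ref <- collapse_to_types(al$ref)
    out$updated <- update_reference(est, type_ref, sigma = sigma,
                                    cg_max_iter = cg_max_iter,
                                    pseudo_min = al$ref$pseudo_min)
    out$theta_f <- refit_theta(al$bulk, out$updated, cfg)
  }
  class(out) <- "deconvolution_result"
  out
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("Deconvolution of", nrow(x$estimate$theta0), "samples into",
      ncol(x$estimate$theta0), "cell types",
      if (!is.null(x$theta_f)) "(reference updated)\n" else "\n")
  invisible(x)
}
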