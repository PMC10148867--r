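#' Tidy the PSMs of a search run
#'
#' @param x A `tallysearch_run` object.
#' @param level `"rank1"` (default: filtered rank-1 PSMs with q-values),
#'   `"all"` (complete ranked table) or `"accepted"`.
#' @param ... Unused.
#' @return A tibble of PSMs.
#' @importFrom generics tidy
#' @export
tidy.tallysearch_run <- function(x, level = c("rank1", "all", "accepted"),
                                 ...) {
  level <- match.arg(level)
  switch(level,
    rank1 = x$psms_rank1,
    all = x$psms,
    accepted = x$psms_accepted
  )
}

#' One-row summary of a search run
#'
#' @param x A `tallysearch_run` object.
#' @param ... Unused.
#' @return A one-row tibble with spectrum, PSM, acceptance and protein
#'   counts plus the configured FDR threshold.
#' @importFrom generics glance
#' @export
glance.tallysearch_run <- function(x, ...) {
  tibble::tibble(
    n_spectra = x$counts$n_spectra,
    n_spectra_matched = x$counts$n_spectra_matched,
    n_rank1 = x$counts$n_rank1,
    n_accepted = x$counts$n_accepted,
    n_decoy_rank1 = sum(x$psms_rank1$is_decoy),
    n_protein_groups = x$counts$n_protein_groups,
    fdr_threshold = x$config$fdr_threshold,
    median_score = stats::median(x$psms_rank1$score),
    median_abs_prec_err_ppm = stats::median(abs(x$psms_rank1$prec_err_ppm))
  )
}

#' @exportS3Method base::print
print.tallysearch_run <- function(x, ...) {
  cat("<tallysearch_run>\n")
  cat("  spectra searched :", x$counts$n_spectra, "\n")
  cat("  rank-1 PSMs      :", x$counts$n_rank1,
      paste0("(", sum(x$psms_rank1$is_decoy), " decoys)"), "\n")
  cat("  accepted at q <=", x$config$fdr_threshold, ":",
      x$counts$n_accepted, "\n")
  cat("  protein groups   :", x$counts$n_protein_groups, "\n")
  invisible(x)
}

#' @export
generics::tidy

#' @export
generics::glance
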