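# ggplot2 views of spectra and search results.

#' Plot an annotated spectrum match
#'
#' Draws the peak profile of one spectrum and highlights the peaks matched
#' by a peptide's primary b/y ions (and, optionally, its satellites).
#'
#' @param spectrum One row of a spectrum tibble.
#' @param sequence Peptide sequence to annotate with.
#' @param lookup `aa_lookup` for the peptide's modification set.
#' @param mod_positions,mod_titles,nterm_title,cterm_title Site assignment.
#' @param tol Product tolerance (ppm).
#' @return A ggplot object.
#' @export
plot_spectrum_match <- function(spectrum, sequence, lookup,
                                mod_positions = integer(),
                                mod_titles = character(),
                                nterm_title = NA_character_,
                                cterm_title = NA_character_,
                                tol = 20) {
  peaks <- spectrum$peaks[[1]]
  ions <- ion_series(sequence, lookup, mod_positions, mod_titles,
                     nterm_title, cterm_title,
                     charge = spectrum$charge, satellites = TRUE)
  prim <- ions[ions$primary, ]
  pm <- match_primary(peaks, prim, tol)
  used <- logical(nrow(peaks))
  used[pm[!is.na(pm)]] <- TRUE
  sm <- .match_ions(peaks, ions$mz[!ions$primary], tol, used)$match

  peaks$status <- "unmatched"
  peaks$status[stats::na.omit(sm)] <- "satellite"
  peaks$status[stats::na.omit(pm)] <- "primary"

  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                      y = 0, yend = .data$intensity,
                                      colour = .data$status)) +
    ggplot2::geom_segment(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(
      primary = "#D55E00", satellite = "#0072B2", unmatched = "grey65"
    )) +
    ggplot2::labs(
      x = "m/z", y = "intensity", colour = NULL,
      title = paste0(sequence, "  (", spectrum$file, " scan ",
                     spectrum$scan, ", ", spectrum$charge, "+)")
    ) +
    ggplot2::theme_minimal()
}

#' Score distributions of targets and decoys
#'
#' @param psms A rank-1 PSM tibble (e.g. `tidy(run)`).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(psms, bins = 30) {
  psms$class <- ifelse(psms$is_decoy, "decoy", "target")
  ggplot2::ggplot(psms, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::scale_fill_manual(values = c(target = "#0072B2",
                                          decoy = "#D55E00")) +
    ggplot2::labs(x = expression(-10 %.% log[10](P)), y = "PSMs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_score_distribution
#' @param object A `tallysearch_run`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.tallysearch_run <- function(object, ...) {
  plot_score_distribution(object$psms_rank1)
}

#' @export
ggplot2::autoplot
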