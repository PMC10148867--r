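# Two-stage matcher and scorer: primary b/y matching, satellite-intensity
# tally onto the primaries, and progressive hypergeometric enrichment.

#' Search configuration
#'
#' Builds the configuration list shared by the digestion, matching, scoring
#' and FDR stages. Unknown keys raise an error listing the valid ones.
#'
#' @param ... Overrides of the defaults: `precursor_tol` (ppm, 20),
#'   `product_tol` (ppm, 20), `top_n` (100), `min_primary` (6),
#'   `enzyme` ("trypsin/P"), `specificity` ("full"), `max_missed` (4),
#'   `len_range` (c(7, 40)), `mass_range` (c(700, 4500) Da),
#'   `max_sites` (5), `max_per_mod` (3), `max_perms` (64),
#'   `fdr_threshold` (0.01), `prec_err_filter` (ppm, 10),
#'   `decoy_tag` ("rev_").
#' @return A named list of class `search_config`.
#' @export
#' @examples
#' search_config(precursor_tol = 10)
search_config <- function(...) {
  defaults <- list(
    precursor_tol = 20, product_tol = 20, top_n = 100L, min_primary = 6L,
    enzyme = "trypsin/P", specificity = "full", max_missed = 4L,
    len_range = c(7L, 40L), mass_range = c(700, 4500),
    max_sites = 5L, max_per_mod = 3L, max_perms = 64L,
    fdr_threshold = 0.01, prec_err_filter = 10, decoy_tag = "rev_"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", "),
                 ". Valid keys: ", paste(names(defaults), collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  if (cfg$precursor_tol <= 0 || cfg$product_tol <= 0) {
    abort("Tolerances must be positive")
  }
  if (cfg$min_primary < 1L) abort("min_primary must be >= 1")
  class(cfg) <- c("search_config", "list")
  cfg
}

#' Write / read a search configuration as a key = value file
#'
#' @param config A `search_config` list.
#' @param path File path.
#' @export
write_search_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_search_config
#' @export
read_search_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  parsed <- lapply(vals, function(v) {
    parts <- stringr::str_split_1(v, ",")
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) parts else num
  })
  names(parsed) <- keys
  do.call(search_config, parsed)
}

#' Match theoretical primary ions to spectrum peaks
#'
#' Each theoretical ion is matched to the nearest peak in ppm within the
#' tolerance; each peak is usable by at most one ion. Ions are processed in
#' series order, and ties go to the lower peak index.
#'
#' @param peaks Peak tibble (`mz`, `intensity`), m/z ascending.
#' @param ions Ion tibble (rows of [ion_series()] output).
#' @param tol Product-ion tolerance in ppm.
#' @return Integer vector (length `nrow(ions)`) of matched peak indices,
#'   `NA` where unmatched.
#' @export
match_primary <- function(peaks, ions, tol = 20) {
  used <- logical(nrow(peaks))
  .match_ions(peaks, ions$mz, tol, used)$match
}

.match_ions <- function(peaks, mz_theo, tol, used) {
  match_idx <- rep(NA_integer_, length(mz_theo))
  if (nrow(peaks) == 0L) return(list(match = match_idx, used = used))
  for (i in seq_along(mz_theo)) {
    t <- mz_theo[i]
    err <- abs(peaks$mz - t) / t * 1e6
    ok <- which(err <= tol & !used)
    if (!length(ok)) next
    j <- ok[order(err[ok], ok)][1]
    match_idx[i] <- j
    used[j] <- TRUE
  }
  list(match = match_idx, used = used)
}

#' Tally satellite-ion intensities onto matched primaries
#'
#' Matches the satellite channels (neutral losses, doubly charged variants)
#' with the same ppm rule and adds their experimental intensities to the
#' intensity of the corresponding matched primary peak. Satellite matches
#' contribute only intensity — they are never counted as independent
#' matching evidence downstream.
#'
#' @param peaks Peak tibble.
#' @param ions Full ion tibble from [ion_series()].
#' @param primary_match Integer match vector for the primary rows of
#'   `ions` (as from [match_primary()] on the primary subset).
#' @param tol Product tolerance (ppm).
#' @return Numeric vector of boosted peak intensities (length
#'   `nrow(peaks)`): matched primary peaks carry their summed satellite
#'   intensities, all other peaks their raw intensity.
#' @export
tally_satellites <- function(peaks, ions, primary_match, tol = 20) {
  boosted <- peaks$intensity
  prim <- ions[ions$primary, ]
  sat <- ions[!ions$primary, ]
  if (nrow(sat) == 0L) return(boosted)
  used <- logical(nrow(peaks))
  used[primary_match[!is.na(primary_match)]] <- TRUE

  # parent peak index per satellite row
  key_p <- paste(prim$parent, prim$idx)
  parent_peak <- setNames(primary_match, key_p)
  sm <- .match_ions(peaks, sat$mz, tol, used)
  for (r in seq_len(nrow(sat))) {
    pk <- sm$match[r]
    if (is.na(pk)) next
    pp <- parent_peak[paste(sat$parent[r], sat$idx[r])]
    if (is.na(pp)) next
    boosted[pp] <- boosted[pp] + peaks$intensity[pk]
  }
  boosted
}

#' Progressive hypergeometric enrichment score
#'
#' Ranks the spectrum's retained features by (boosted) intensity, scans the
#' top-k prefixes for k = 1..N and evaluates at each step the upper-tail
#' hypergeometric probability of observing at least `x_k` matched primary
#' ions among k draws from N features of which K are matched. The best
#' (minimum) probability P yields the score -10·log10(P). With K = 0 or
#' K = N the enrichment is degenerate and the score is 0.
#'
#' @param intensity Boosted feature intensities (length N).
#' @param mz Feature m/z (tie-break: equal intensities rank by ascending
#'   m/z).
#' @param matched Logical; is the feature a matched primary ion?
#' @return A list with `trace` (tibble `k`, `x`, `p`), `P` and `score`.
#' @export
#' @examples
#' enrichment_score(c(10, 9, 8, 7, 6, 5), 1:6,
#'                  c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
enrichment_score <- function(intensity, mz, matched) {
  N <- length(intensity)
  K <- sum(matched)
  if (N == 0L || K == 0L || K == N) {
    return(list(trace = tibble::tibble(k = integer(), x = integer(),
                                       p = numeric()),
                P = 1, score = 0))
  }
  ord <- order(-intensity, mz, method = "radix")
  x <- cumsum(matched[ord])
  k <- seq_len(N)
  p <- phyper(x - 1, K, N - K, k, lower.tail = FALSE)
  P <- min(p)
  list(trace = tibble::tibble(k = k, x = x, p = p),
       P = P, score = max(0, -10 * log10(P)))
}

#' Score one candidate assignment against one spectrum
#'
#' @keywords internal
.score_candidate <- function(peaks, sequence, lk, mod_positions, mod_titles,
                             nterm_title, cterm_title, charge, config) {
  ions <- ion_series(sequence, lk, mod_positions, mod_titles,
                     nterm_title, cterm_title, charge = charge,
                     satellites = TRUE)
  prim <- ions[ions$primary, ]
  pm <- match_primary(peaks, prim, config$product_tol)
  n_matched <- sum(!is.na(pm))
  if (n_matched < config$min_primary) return(NULL)

  boosted <- tally_satellites(peaks, ions, pm, config$product_tol)
  matched_flag <- logical(nrow(peaks))
  matched_flag[pm[!is.na(pm)]] <- TRUE
  sc <- enrichment_score(boosted, peaks$mz, matched_flag)

  mp <- pm[!is.na(pm)]
  list(
    n_matched = n_matched,
    score = sc$score,
    P = sc$P,
    boost_ratio = mean(boosted[mp] / peaks$intensity[mp])
  )
}

#' Search one spectrum against binned candidates
#'
#' Collects every site assignment whose neutral mass lies within the
#' precursor tolerance of the observed precursor neutral mass, scores each
#' by the two-stage tally + enrichment procedure, discards assignments with
#' fewer than `min_primary` matched primary ions, deduplicates identical
#' annotated peptides across modification sets (best score kept) and ranks
#' the rest by score (ties by absolute precursor error).
#'
#' @param spectrum One row of a spectrum tibble (preprocessed).
#' @param binned `binned_assignments` from [bin_candidates()].
#' @param lks List of prepared lookups indexed by set index (internal
#'   representation; see [search_spectra()] for the user entry point).
#' @param config A [search_config()] list.
#' @return A tibble of ranked match results (possibly empty).
#' @export
search_spectrum <- function(spectrum, binned, lks, config = search_config()) {
  neutral <- (spectrum$premz - PROTON_MASS) * spectrum$charge
  if (neutral < attr(binned, "mass_range")[1] ||
      neutral > attr(binned, "mass_range")[2]) {
    return(NULL)
  }
  cands <- query_candidates(binned, neutral, config$precursor_tol)
  if (nrow(cands) == 0L) return(NULL)
  peaks <- spectrum$peaks[[1]]

  rows <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    a <- cands[i, ]
    res <- .score_candidate(
      peaks, a$sequence, lks[[a$set_index]],
      a$mod_positions[[1]], a$mod_titles[[1]],
      a$nterm_title, a$cterm_title, spectrum$charge, config
    )
    if (is.null(res)) next
    rows[[i]] <- tibble::tibble(
      file = spectrum$file, scan = spectrum$scan,
      premz = spectrum$premz, charge = spectrum$charge,
      pep = a$pep, sequence = a$sequence, set_index = a$set_index,
      protein_refs = a$protein_refs,
      is_decoy = a$is_decoy,
      n_matched = res$n_matched,
      score = res$score, P = res$P,
      prec_err_ppm = ppm_error(neutral, a$neutral_mass),
      boost_ratio = res$boost_ratio
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(NULL)
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$score), abs(.data$prec_err_ppm),
                   .data$set_index) |>
    dplyr::distinct(.data$pep, .keep_all = TRUE)
  out$rank <- seq_len(nrow(out))
  out
}

#' Search a spectrum table against a candidate index
#'
#' The main matching loop: preprocesses each spectrum to its top-N peaks
#' and applies [search_spectrum()]. Returns the complete ranked PSM table
#' (targets and decoys).
#'
#' @param spectra Spectrum tibble from [read_peaklist()].
#' @param binned Binned assignments from [bin_candidates()].
#' @param sets `mod_sets` used to build the assignments.
#' @param config A [search_config()] list.
#' @return A tibble of ranked PSMs across all spectra.
#' @export
search_spectra <- function(spectra, binned, sets, config = search_config()) {
  spectra <- preprocess_spectra(spectra, config$top_n)
  lks <- list()
  for (si in sets$set_index) {
    lks[[si]] <- .lookup_env(build_aa_lookup(sets, si))
  }
  out <- vector("list", nrow(spectra))
  for (i in seq_len(nrow(spectra))) {
    out[[i]] <- search_spectrum(spectra[i, ], binned, lks, config)
  }
  dplyr::bind_rows(out)
}
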