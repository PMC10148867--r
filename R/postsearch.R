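# Target-decoy FDR with subclass calibration/transfer, counting-statistic
# site localization, protein grouping, entrapment evaluation.

#' Target-decoy q-values with subclass calibration and transfer
#'
#' Estimates FDR within the subclass of results (keyed by modification-set
#' index) that yields the most rank-1 matches: at each score threshold,
#' FDR = #decoys / max(1, #targets) among PSMs at or above the threshold,
#' monotonized from high score downward into q-values. The calibrated
#' score-to-q mapping is then transferred to every PSM in all subclasses by
#' step-function lookup. With no decoys in the calibration subclass all
#' q-values are 0 and a warning is emitted.
#'
#' @param psms Rank-1 PSM tibble with columns `score`, `is_decoy` and
#'   `set_index` (the subclass key).
#' @return `psms` with a `q_value` column; the calibration table (score,
#'   decoy flag, raw FDR, q) is attached as attribute `"calibration"`.
#' @export
#' @examples
#' psms <- tibble::tibble(score = c(10, 9, 8, 7, 6),
#'                        is_decoy = c(FALSE, TRUE, FALSE, FALSE, TRUE),
#'                        set_index = 1L)
#' compute_fdr(psms)
compute_fdr <- function(psms) {
  if (nrow(psms) == 0L) {
    psms$q_value <- numeric(0)
    return(psms)
  }
  sizes <- table(psms$set_index)
  cal_key <- as.integer(names(sizes)[which.max(sizes)])
  cal <- psms[psms$set_index == cal_key, ]
  o <- order(-cal$score, method = "radix")
  cal <- cal[o, ]

  if (!any(cal$is_decoy)) {
    warn("No decoys in the calibration subclass; all q-values set to 0")
    psms$q_value <- 0
    attr(psms, "calibration") <- tibble::tibble(
      score = cal$score, is_decoy = cal$is_decoy,
      fdr = 0, q = 0
    )
    return(psms)
  }

  fdr <- cumsum(cal$is_decoy) / pmax(1L, cumsum(!cal$is_decoy))
  q <- rev(cummin(rev(fdr)))

  # step-function transfer: a score s maps to the q of the acceptance set
  # {calibration score >= s}
  neg_sorted <- sort(-cal$score)
  idx <- findInterval(-psms$score, neg_sorted)
  psms$q_value <- q[pmax(1L, idx)]
  attr(psms, "calibration") <- tibble::tibble(
    score = cal$score, is_decoy = cal$is_decoy, fdr = fdr, q = q
  )
  attr(psms, "calibration_subclass") <- cal_key
  psms
}

#' Counting-statistic localization probability
#'
#' The probability of the leading site configuration given matched
#' site-determining ion counts: `n_lead / (n_lead + n_alt)`. A competitor
#' count of 0 gives probability 1 regardless of the leader's count (1:0 and
#' 2:0 are equivalent); 0:0 is undefined and reported as 0.5 per assignment.
#'
#' @param n_lead,n_alt Non-negative matched site-determining ion counts.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' localization_probability(2, 1)  # 0.67
#' localization_probability(1, 0)  # 1
localization_probability <- function(n_lead, n_alt) {
  tot <- n_lead + n_alt
  ifelse(tot == 0, 0.5, n_lead / tot)
}

#' Localize a variable modification among alternative site assignments
#'
#' For two or more assignments of the same peptide differing only in the
#' positions of one modification, counts per assignment the matched
#' site-determining primary ions (ions whose m/z occur in that assignment's
#' series but in no competing assignment's) and converts the counts into
#' probabilities `n_i / sum(n)`. When no site-determining ion is matched at
#' all, probabilities default to `1/n_assignments` and `undefined` is set.
#'
#' @param peaks Peak tibble of the (preprocessed) spectrum.
#' @param sequence Peptide sequence.
#' @param lookup `aa_lookup` for the assignment's modification set.
#' @param assignments Tibble with list columns `mod_positions`,
#'   `mod_titles` and columns `nterm_title`, `cterm_title` (one row per
#'   alternative; the first row is the leading assignment).
#' @param charge Precursor charge.
#' @param tol Product tolerance (ppm).
#' @return The `assignments` tibble with columns `n_site_ions`,
#'   `localization_prob` and `undefined`.
#' @export
localize_sites <- function(peaks, sequence, lookup, assignments,
                           charge = 2L, tol = 20) {
  stopifnot(nrow(assignments) >= 2L)
  lk <- if (is.list(lookup) && !is.data.frame(lookup)) lookup
        else .lookup_env(lookup)
  series <- purrr::map(seq_len(nrow(assignments)), function(i) {
    io <- ion_series(sequence, lk,
                     assignments$mod_positions[[i]],
                     assignments$mod_titles[[i]],
                     assignments$nterm_title[i], assignments$cterm_title[i],
                     charge = charge, satellites = FALSE)
    io$mz
  })
  counts <- vapply(seq_along(series), function(i) {
    others <- unlist(series[-i])
    own <- series[[i]]
    # site-determining: not reproduced by any competitor within 1e-3 Da
    det <- own[vapply(own, function(mz) all(abs(others - mz) > 1e-3),
                      logical(1))]
    if (!length(det)) return(0L)
    m <- .match_ions(peaks, det, tol, logical(nrow(peaks)))$match
    sum(!is.na(m))
  }, integer(1))

  tot <- sum(counts)
  assignments$n_site_ions <- counts
  assignments$undefined <- tot == 0
  assignments$localization_prob <-
    if (tot == 0) rep(1 / length(counts), length(counts)) else counts / tot
  assignments
}

#' Group proteins by shared peptides and pick essential members
#'
#' Builds the sparse peptide-by-protein incidence structure, separates
#' unique (r1) from shared (r2) peptide rows and proteins with (c1) and
#' without (c2) shared peptides; c2 proteins each form their own group.
#' On the c1 x r2 block, the pairwise protein distance is 0 when two
#' proteins share any peptide and 1 otherwise; single-link agglomeration cut
#' at any height above 0 turns shared-peptide connectivity into groups.
#' Within each group, essential proteins are chosen by greedy set cover over
#' the group's peptides (repeatedly take the protein covering the most
#' uncovered peptides; ties to the protein with more total peptides, then
#' lexicographically smaller accession).
#'
#' @param peptide_protein Tibble with columns `peptide` and `accession`
#'   (one row per incidence).
#' @return A tibble with columns `accession`, `group_id`, `essential`,
#'   `n_peptides` and `peptides` (list column).
#' @export
#' @examples
#' group_proteins(tibble::tibble(
#'   peptide = c("pep1", "pep2", "pep2", "pep3"),
#'   accession = c("P1", "P1", "P2", "P2")
#' ))
group_proteins <- function(peptide_protein) {
  pp <- dplyr::distinct(peptide_protein, .data$peptide, .data$accession)
  if (nrow(pp) == 0L) {
    return(tibble::tibble(accession = character(), group_id = integer(),
                          essential = logical(), n_peptides = integer(),
                          peptides = list()))
  }
  peps <- sort(unique(pp$peptide))
  prots <- sort(unique(pp$accession))
  M <- Matrix::sparseMatrix(
    i = match(pp$peptide, peps),
    j = match(pp$accession, prots),
    x = 1,
    dims = c(length(peps), length(prots)),
    dimnames = list(peps, prots)
  )
  shared_row <- Matrix::rowSums(M > 0) >= 2          # r2
  c1 <- Matrix::colSums(M[shared_row, , drop = FALSE] > 0) > 0
  comp <- integer(length(prots))

  if (any(c1)) {
    sub <- M[shared_row, c1, drop = FALSE]
    A <- Matrix::crossprod(sub) > 0                  # share any peptide
    d <- 1 - as.matrix(A)
    if (nrow(d) > 1L) {
      hc <- hclust(as.dist(d), method = "single")
      comp_c1 <- cutree(hc, h = 0.5)
    } else {
      comp_c1 <- 1L
    }
    comp[c1] <- comp_c1
  }
  # c2 proteins: singleton groups
  n_used <- if (any(c1)) max(comp[c1]) else 0L
  comp[!c1] <- n_used + seq_len(sum(!c1))

  prot_peps <- lapply(seq_along(prots),
                      function(j) peps[M[, j] > 0])
  names(prot_peps) <- prots

  out <- tibble::tibble(
    accession = prots,
    group_id = comp,
    n_peptides = lengths(prot_peps),
    peptides = unname(prot_peps)
  )
  out$essential <- FALSE
  for (g in unique(out$group_id)) {
    members <- which(out$group_id == g)
    ess <- .greedy_cover(prot_peps[out$accession[members]])
    out$essential[members[out$accession[members] %in% ess]] <- TRUE
  }
  out <- dplyr::arrange(out, .data$group_id, dplyr::desc(.data$essential),
                        .data$accession)
  out[, c("accession", "group_id", "essential", "n_peptides", "peptides")]
}

# greedy set cover over a named list of peptide sets; returns accession
# names of the chosen cover
.greedy_cover <- function(sets) {
  uncovered <- unique(unlist(sets))
  totals <- lengths(sets)
  chosen <- character(0)
  remaining <- names(sets)
  while (length(uncovered) && length(remaining)) {
    gain <- vapply(remaining,
                   function(a) sum(sets[[a]] %in% uncovered), integer(1))
    best <- remaining[order(-gain, -totals[remaining], remaining,
                            method = "radix")][1]
    if (gain[best] == 0L) break
    chosen <- c(chosen, best)
    uncovered <- setdiff(uncovered, sets[[best]])
    remaining <- setdiff(remaining, best)
  }
  chosen
}

#' Entrapment rate among accepted PSMs
#'
#' The fraction of accepted target PSMs (q at or below the threshold,
#' decoys excluded) that originate from the entrapment database.
#'
#' @param psms PSM tibble with `q_value`, `is_decoy` and a logical
#'   `is_entrapment` column.
#' @param threshold q-value acceptance threshold.
#' @return A list with `rate` (0 with `undefined = TRUE` when nothing is
#'   accepted), `n_accepted`, `n_entrapment` and `curve`, the cumulative
#'   entrapment fraction along decreasing score.
#' @export
entrapment_rate <- function(psms, threshold = 0.01) {
  acc <- psms[!psms$is_decoy & psms$q_value <= threshold, ]
  rate <- if (nrow(acc) == 0L) 0 else mean(acc$is_entrapment)
  tgt <- psms[!psms$is_decoy, ]
  tgt <- tgt[order(-tgt$score, method = "radix"), ]
  curve <- tibble::tibble(
    score = tgt$score,
    n_accepted = seq_len(nrow(tgt)),
    entrapment_frac = cumsum(tgt$is_entrapment) / seq_len(nrow(tgt))
  )
  list(rate = rate, undefined = nrow(acc) == 0L,
       n_accepted = nrow(acc), n_entrapment = sum(acc$is_entrapment),
       curve = curve)
}
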