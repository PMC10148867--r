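# FASTA ingestion, in-silico digestion, decoy generation.

#' Read a protein FASTA database
#'
#' Loads a (possibly line-wrapped) FASTA file into a protein table. The
#' accession is the first whitespace-delimited token of the header line.
#' Duplicate accessions are deduplicated keeping the first occurrence, with
#' a warning.
#'
#' @param path Path(s) to FASTA files; several files (e.g. a target database
#'   plus a cRAP-style contaminant database) are concatenated.
#' @return A tibble with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  recs <- dplyr::bind_rows(lapply(path, .read_fasta_one))
  dup <- duplicated(recs$accession)
  if (any(dup)) {
    warn(paste0("Dropping ", sum(dup), " duplicate accession(s): ",
                paste(unique(recs$accession[dup]), collapse = ", ")))
    recs <- recs[!dup, ]
  }
  recs
}

.read_fasta_one <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("Malformed FASTA '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0L) abort(paste0("Empty FASTA file: ", path))
  headers <- names(set)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    abort(paste0("FASTA '", path, "' has entries with empty sequences: ",
                 paste(headers[!nzchar(seqs)], collapse = ", ")))
  }
  tibble::tibble(
    accession = stringr::word(headers, 1),
    description = ifelse(
      stringr::str_detect(headers, "\\s"),
      stringr::str_trim(stringr::str_remove(headers, "^\\S+\\s*")),
      ""
    ),
    sequence = unname(seqs)
  )
}

#' Write a protein table to FASTA
#'
#' @param proteins Protein tibble as from [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  lines <- unlist(purrr::pmap(proteins, function(accession, description,
                                                 sequence, ...) {
    hdr <- paste0(">", accession,
                  if (nzchar(description)) paste0(" ", description) else "")
    body <- substring(sequence,
                      seq(1, nchar(sequence), width),
                      pmin(seq(width, nchar(sequence) + width - 1, width),
                           nchar(sequence)))
    c(hdr, body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Generate reversed decoy proteins
#'
#' Each decoy is the full reversal of a target sequence, its accession
#' prefixed with a reserved tag. For entrapment searches, concatenate the
#' target and entrapment databases first and reverse the combined table.
#'
#' @param proteins Protein tibble.
#' @param tag Decoy accession prefix.
#' @return A tibble of decoy proteins (same columns).
#' @export
#' @examples
#' make_decoys(tibble::tibble(accession = "P1", description = "",
#'                            sequence = "PEPTIDEK"))
make_decoys <- function(proteins, tag = "rev_") {
  tibble::tibble(
    accession = paste0(tag, proteins$accession),
    description = proteins$description,
    sequence = stringi_rev(proteins$sequence),
    is_decoy = TRUE
  )
}

# base-R string reversal (vectorized)
stringi_rev <- function(x) {
  vapply(strsplit(x, NULL),
         function(s) paste(rev(s), collapse = ""),
         character(1))
}

.enzymes <- list(
  # trypsin/P: cleave C-terminal to K/R, no proline exception
  "trypsin/P" = "[KR]"
)

#' In-silico digestion of proteins
#'
#' Digests each protein at the configured enzymatic specificity. `full`
#' yields contiguous fragments bounded by cleavage sites or protein termini
#' with at most `max_missed` internal sites; `semi` requires one enzymatic
#' terminus; `none` yields all substrings within the length range (for semi
#' and none the missed-cleavage count is not constrained). Candidates are
#' deduplicated by (sequence, termini flags) with protein references merged.
#' Candidates starting at position 2 after an initiator methionine keep the
#' protein N-terminal flag, so protein N-terminal modifications remain
#' reachable on clipped N-termini.
#'
#' @param proteins Protein tibble (`accession`, `sequence`, optionally a
#'   logical `is_decoy` column).
#' @param enzyme Enzyme name (`"trypsin/P"`) or a regular expression matching
#'   the residue N-terminal to each cut site.
#' @param specificity One of `"full"`, `"semi"`, `"none"`.
#' @param max_missed Maximum missed cleavages (full specificity only).
#' @param len_range Length-2 integer vector, inclusive peptide length range.
#' @return A tibble with columns `sequence`, `protein_refs` (list),
#'   `missed_cleavages`, `is_protein_nterm`, `is_protein_cterm`, `is_decoy`.
#' @export
#' @examples
#' digest(tibble::tibble(accession = "P1", description = "",
#'                       sequence = "MAAKLLLRSSSK"),
#'        len_range = c(3, 10), max_missed = 1)
digest <- function(proteins, enzyme = "trypsin/P", specificity = "full",
                   max_missed = 4L, len_range = c(7L, 40L)) {
  specificity <- match.arg(specificity, c("full", "semi", "none"))
  pattern <- .enzymes[[enzyme]] %||% enzyme
  if (is.null(.enzymes[[enzyme]]) && !grepl("^\\[", enzyme)) {
    abort(paste0("Unknown enzyme '", enzyme, "'. Known: ",
                 paste(names(.enzymes), collapse = ", "),
                 " (or give a cut-site regex such as \"[KR]\")."))
  }
  if (!"is_decoy" %in% names(proteins)) proteins$is_decoy <- FALSE

  pieces <- purrr::pmap(
    list(proteins$accession, proteins$sequence, proteins$is_decoy),
    .digest_one,
    pattern = pattern, specificity = specificity,
    max_missed = max_missed, len_range = len_range
  )
  cand <- dplyr::bind_rows(pieces)
  if (nrow(cand) == 0L) {
    return(tibble::tibble(
      sequence = character(), protein_refs = list(),
      missed_cleavages = integer(), is_protein_nterm = logical(),
      is_protein_cterm = logical(), is_decoy = logical()
    ))
  }
  cand |>
    dplyr::group_by(.data$sequence, .data$is_protein_nterm,
                    .data$is_protein_cterm, .data$is_decoy) |>
    dplyr::summarise(
      protein_refs = list(sort(unique(.data$accession))),
      missed_cleavages = min(.data$missed_cleavages),
      .groups = "drop"
    ) |>
    dplyr::select("sequence", "protein_refs", "missed_cleavages",
                  "is_protein_nterm", "is_protein_cterm", "is_decoy") |>
    dplyr::arrange(.data$sequence)
}

.digest_one <- function(accession, sequence, is_decoy, pattern, specificity,
                        max_missed, len_range) {
  n <- nchar(sequence)
  res <- strsplit(sequence, NULL)[[1]]
  # cut positions: after residue i (i in cut) there is a cleavage site
  cut <- which(grepl(pattern, res))
  cut <- cut[cut < n]
  starts_full <- c(1L, cut + 1L)   # enzymatic start positions
  ends_full <- c(cut, n)           # enzymatic end positions

  emit <- function(st, en, mc) {
    keep <- (en - st + 1L) >= len_range[1] & (en - st + 1L) <= len_range[2]
    st <- st[keep]; en <- en[keep]; mc <- mc[keep]
    if (!length(st)) return(NULL)
    pep <- substring(sequence, st, en)
    nterm_flag <- st == 1L | (st == 2L & substr(sequence, 1L, 1L) == "M")
    tibble::tibble(
      accession = accession,
      sequence = pep,
      missed_cleavages = mc,
      is_protein_nterm = nterm_flag,
      is_protein_cterm = en == n,
      is_decoy = is_decoy
    )
  }

  if (specificity == "full") {
    out <- list()
    nb <- length(starts_full)
    for (i in seq_len(nb)) {
      jmax <- min(nb, i + max_missed)
      js <- i:jmax
      out[[i]] <- emit(rep(starts_full[i], length(js)), ends_full[js],
                       js - i)
    }
    # clipped initiator methionine: same windows shifted to position 2
    if (substr(sequence, 1L, 1L) == "M" && n > 1L) {
      jmax <- min(nb, 1L + max_missed)
      js <- 1L:jmax
      en2 <- ends_full[js]
      ok <- en2 >= 2L
      out[[length(out) + 1L]] <- emit(rep(2L, sum(ok)), en2[ok],
                                      js[ok] - 1L)
    }
    return(dplyr::bind_rows(out))
  }

  is_enz_start <- function(st) st == 1L | (st - 1L) %in% cut
  is_enz_end <- function(en) en == n | en %in% cut
  grid <- expand.grid(st = seq_len(n), len = len_range[1]:len_range[2])
  grid$en <- grid$st + grid$len - 1L
  grid <- grid[grid$en <= n, ]
  if (specificity == "semi") {
    grid <- grid[is_enz_start(grid$st) | is_enz_end(grid$en), ]
  }
  if (nrow(grid) == 0L) return(NULL)
  mc <- vapply(seq_len(nrow(grid)),
               function(i) sum(cut >= grid$st[i] & cut < grid$en[i]),
               integer(1))
  emit(grid$st, grid$en, mc)
}

#' Bin site assignments by neutral precursor mass
#'
#' Assigns each candidate site assignment to a constant-ppm mass bin so that
#' a precursor query with tolerance up to half the bin width touches at most
#' two adjacent bins. Assignments outside the closed `mass_range` are
#' dropped.
#'
#' @param assignments Assignment tibble with a `neutral_mass` column (see
#'   [build_assignments()]).
#' @param mass_range Closed interval of retained neutral masses (Da).
#' @param bin_width_ppm Bin width in ppm; use at least twice the precursor
#'   tolerance.
#' @return The filtered assignment tibble with a `mass_bin` integer column,
#'   carrying `mass_range`/`bin_width_ppm` as attributes, class
#'   `binned_assignments`.
#' @export
bin_candidates <- function(assignments, mass_range = c(700, 4500),
                           bin_width_ppm = 40) {
  if (bin_width_ppm <= 0) abort("bin_width_ppm must be positive")
  keep <- assignments$neutral_mass >= mass_range[1] &
    assignments$neutral_mass <= mass_range[2]
  out <- assignments[keep, , drop = FALSE]
  out$mass_bin <- .mass_bin_index(out$neutral_mass, mass_range[1],
                                  bin_width_ppm)
  attr(out, "mass_range") <- mass_range
  attr(out, "bin_width_ppm") <- bin_width_ppm
  class(out) <- unique(c("binned_assignments", class(out)))
  out
}

.mass_bin_index <- function(mass, lower, bin_width_ppm) {
  as.integer(floor(log(mass / lower) / log1p(bin_width_ppm * 1e-6)))
}

#' Query binned assignments around a precursor mass
#'
#' Returns all assignments whose neutral mass is within `tol_ppm` of
#' `neutral_mass`, using the bin index to restrict the scan before the exact
#' ppm filter.
#'
#' @param binned A `binned_assignments` tibble.
#' @param neutral_mass Query neutral mass (Da).
#' @param tol_ppm Tolerance in ppm (inclusive).
#' @return The matching subset of `binned`.
#' @export
query_candidates <- function(binned, neutral_mass, tol_ppm = 20) {
  lower <- attr(binned, "mass_range")[1]
  w <- attr(binned, "bin_width_ppm")
  lo <- neutral_mass * (1 - tol_ppm * 1e-6)
  hi <- neutral_mass * (1 + tol_ppm * 1e-6)
  b1 <- .mass_bin_index(max(lo, lower), lower, w)
  b2 <- .mass_bin_index(max(hi, lower), lower, w)
  hit <- binned[binned$mass_bin >= b1 & binned$mass_bin <= b2, , drop = FALSE]
  err <- (hit$neutral_mass - neutral_mass) / neutral_mass * 1e6
  hit[abs(err) <= tol_ppm, , drop = FALSE]
}
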