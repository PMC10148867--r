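# Orchestration: compile -> digest -> enumerate -> bin -> search -> filter
# -> FDR -> localize -> group -> write, with precursor-mass caching.

#' Run a complete closed search
#'
#' Executes the full pipeline: modification-set compilation, in-silico
#' digestion of targets (plus optional entrapment proteins) and reversed
#' decoys, site-assignment enumeration with precursor-mass caching,
#' precursor binning, two-stage spectrum matching with satellite tally and
#' enrichment scoring, post-search filters (minimum matched primaries,
#' precursor-error window), target-decoy FDR with subclass transfer, site
#' localization of rank-1 matches and protein grouping of the accepted
#' peptides.
#'
#' @param fasta Protein FASTA path(s) or a protein tibble.
#' @param peaklist Peak-list path(s) (MGF) or a spectrum tibble.
#' @param fixed,variable Modification specifications (see
#'   [parse_mod_spec()]).
#' @param config A [search_config()] list.
#' @param entrapment Optional FASTA path/tibble of entrapment (foreign
#'   species) proteins, appended to the target database before decoy
#'   reversal and tracked through to [entrapment_rate()].
#' @param registry Modification registry.
#' @param output_dir Optional directory; when given, psmC.txt, psmQ.txt,
#'   prot.txt and manifest.txt are written there.
#' @param cache_dir Optional directory for the precursor-mass
#'   (site-assignment) cache, keyed by database + modification sets +
#'   digestion settings; a warm cache never changes results.
#' @return An object of class `tallysearch_run`: a list with `psms`
#'   (complete ranked table), `psms_rank1` (filtered rank-1 PSMs with
#'   q-values and localization probabilities), `psms_accepted`
#'   (q <= threshold targets), `protein_groups`, `sets`, `config`,
#'   `counts` (per-stage tallies) and `manifest`.
#' @export
run_search <- function(fasta, peaklist,
                       fixed = character(), variable = character(),
                       config = search_config(),
                       entrapment = NULL,
                       registry = mod_registry(),
                       output_dir = NULL, cache_dir = NULL) {
  targets <- if (is.character(fasta)) read_fasta(fasta) else fasta
  targets$is_entrapment <- FALSE
  if (!is.null(entrapment)) {
    entr <- if (is.character(entrapment)) read_fasta(entrapment) else entrapment
    entr$is_entrapment <- TRUE
    targets <- dplyr::bind_rows(targets, entr)
  }
  decoys <- make_decoys(targets, tag = config$decoy_tag)
  proteins <- dplyr::bind_rows(
    dplyr::mutate(targets, is_decoy = FALSE),
    decoys
  )
  entrap_acc <- targets$accession[targets$is_entrapment]

  sets <- compile_mod_sets(fixed, variable, registry)

  asg <- .cached_assignments(proteins, sets, config, cache_dir)
  binned <- bin_candidates(asg, mass_range = config$mass_range,
                           bin_width_ppm = 2 * config$precursor_tol)

  spectra <- if (is.character(peaklist)) {
    dplyr::bind_rows(lapply(peaklist, read_peaklist))
  } else {
    peaklist
  }

  psms <- search_spectra(spectra, binned, sets, config)
  counts <- list(
    n_proteins = sum(!proteins$is_decoy),
    n_decoys = sum(proteins$is_decoy),
    n_sets = nrow(sets),
    n_assignments = nrow(asg),
    n_spectra = nrow(spectra),
    n_spectra_matched = length(unique(paste(psms$file, psms$scan)))
  )
  if (nrow(psms) == 0L) {
    abort("Search stage produced no PSMs; check tolerances and databases.")
  }

  rank1 <- psms[psms$rank == 1L &
                  abs(psms$prec_err_ppm) <= config$prec_err_filter, ]
  rank1 <- compute_fdr(rank1)
  calibration <- attr(rank1, "calibration")

  rank1 <- .localize_rank1(rank1, spectra, binned, sets, config)
  rank1$is_entrapment <- purrr::map_lgl(
    rank1$protein_refs, ~ length(.x) > 0 && all(.x %in% entrap_acc)
  )

  accepted <- rank1[!rank1$is_decoy & rank1$q_value <= config$fdr_threshold, ]
  groups <- group_proteins(.peptide_protein(accepted))
  counts$n_rank1 <- nrow(rank1)
  counts$n_accepted <- nrow(accepted)
  counts$n_protein_groups <- length(unique(groups$group_id))

  run <- structure(list(
    psms = psms, psms_rank1 = rank1, psms_accepted = accepted,
    protein_groups = groups, sets = sets, config = config,
    calibration = calibration, counts = counts,
    manifest = .manifest(fasta, peaklist, config, counts)
  ), class = "tallysearch_run")

  if (!is.null(output_dir)) write_psm_tables(run, dir = output_dir)
  run
}

.peptide_protein <- function(accepted) {
  if (nrow(accepted) == 0L) {
    return(tibble::tibble(peptide = character(), accession = character()))
  }
  tidyr::unnest(
    tibble::tibble(peptide = accepted$sequence,
                   accession = accepted$protein_refs),
    "accession"
  )
}

.cached_assignments <- function(proteins, sets, config, cache_dir) {
  caps <- list(max_sites = config$max_sites, max_per_mod = config$max_per_mod,
               max_perms = config$max_perms)
  build <- function() {
    cand <- digest(proteins, enzyme = config$enzyme,
                   specificity = config$specificity,
                   max_missed = config$max_missed,
                   len_range = config$len_range)
    build_assignments(cand, sets, caps)
  }
  if (is.null(cache_dir)) return(build())
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  key_obj <- list(sequences = proteins$sequence,
                  accessions = proteins$accession,
                  sets = sets$label, caps = caps,
                  enzyme = config$enzyme, specificity = config$specificity,
                  max_missed = config$max_missed,
                  len_range = config$len_range)
  tmp <- tempfile()
  saveRDS(key_obj, tmp)
  key <- unname(tools::md5sum(tmp))
  unlink(tmp)
  cache_file <- file.path(cache_dir, paste0("assignments-", key, ".rds"))
  if (file.exists(cache_file)) return(readRDS(cache_file))
  asg <- build()
  saveRDS(asg, cache_file)
  asg
}

# attach localization probabilities to rank-1 PSMs carrying positional
# variable modifications
.localize_rank1 <- function(rank1, spectra, binned, sets, config) {
  rank1$loc_prob <- NA_real_
  if (nrow(rank1) == 0L) return(rank1)
  spectra <- preprocess_spectra(spectra, config$top_n)
  spec_key <- paste(spectra$file, spectra$scan)
  lks <- list()
  for (si in sets$set_index) {
    lks[[si]] <- .lookup_env(build_aa_lookup(sets, si))
  }
  for (i in seq_len(nrow(rank1))) {
    r <- rank1[i, ]
    alt <- binned[binned$sequence == r$sequence &
                    binned$set_index == r$set_index &
                    binned$is_decoy == r$is_decoy, ]
    if (nrow(alt) < 2L) next
    self <- which(alt$pep == r$pep)
    if (!length(self)) next
    # positional isomers: same modification multiset, different placement
    key <- function(t) paste(sort(t), collapse = "+")
    self_key <- key(alt$mod_titles[[self[1]]])
    iso <- which(vapply(alt$mod_titles, key, character(1)) == self_key &
                   alt$pep != r$pep)
    if (!length(iso) || length(alt$mod_positions[[self[1]]]) == 0L) next
    sp <- match(paste(r$file, r$scan), spec_key)
    if (is.na(sp)) next
    asg <- alt[c(self[1], iso), c("mod_positions", "mod_titles",
                                  "nterm_title", "cterm_title")]
    loc <- localize_sites(spectra$peaks[[sp]], r$sequence,
                          lks[[r$set_index]], asg,
                          charge = r$charge, tol = config$product_tol)
    rank1$loc_prob[i] <- loc$localization_prob[1]
  }
  rank1
}

.manifest <- function(fasta, peaklist, config, counts) {
  hashes <- character(0)
  if (is.character(fasta)) hashes <- c(hashes, tools::md5sum(fasta))
  if (is.character(peaklist)) hashes <- c(hashes, tools::md5sum(peaklist))
  c(
    setNames(vapply(config, function(v) paste(v, collapse = ","),
                    character(1)),
             paste0("config.", names(config))),
    if (length(hashes)) {
      setNames(as.character(hashes), paste0("md5.", names(hashes)))
    } else {
      character(0)
    },
    setNames(vapply(counts, as.character, character(1)),
             paste0("count.", names(counts)))
  )
}

#' Write the PSM and protein tables of a search run
#'
#' `psmC.txt` holds the complete ranked list of PSMs (targets and decoys);
#' `psmQ.txt` the quality subset — rank-1 target PSMs passing the
#' precursor-error window and the FDR threshold; `prot.txt` the protein
#' groups with essential flags; `manifest.txt` the run manifest. All
#' tables are UTF-8, tab-delimited, single header row.
#'
#' @param run A `tallysearch_run` object.
#' @param dir Output directory (created if missing).
#' @param threshold FDR threshold for psmQ; defaults to the run's
#'   configured threshold.
#' @return The directory, invisibly.
#' @export
write_psm_tables <- function(run, dir, threshold = run$config$fdr_threshold) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- function(x) {
    x$proteins <- vapply(x$protein_refs, paste, character(1), collapse = ";")
    x$protein_refs <- NULL
    x
  }
  psmc <- flat(run$psms)
  q_map <- run$psms_rank1
  key <- paste(psmc$file, psmc$scan, psmc$pep)
  psmc$q_value <- q_map$q_value[match(key, paste(q_map$file, q_map$scan,
                                                 q_map$pep))]
  readr::write_tsv(psmc, file.path(dir, "psmC.txt"))

  psmq <- run$psms_rank1
  psmq <- psmq[!psmq$is_decoy & psmq$q_value <= threshold, ]
  readr::write_tsv(flat(psmq), file.path(dir, "psmQ.txt"))

  prot <- run$protein_groups
  prot$peptides <- vapply(prot$peptides, paste, character(1), collapse = ";")
  readr::write_tsv(prot, file.path(dir, "prot.txt"))

  writeLines(paste0(names(run$manifest), " = ", run$manifest),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
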