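# Seeded synthetic DDA MS2 generator: primary b/y ions of known (modified)
# peptides, satellites at configurable relative intensity, uniform noise
# peaks, Gaussian ppm jitter. Makes the whole engine testable offline.

#' Simulate DDA MS2 spectra with known ground truth
#'
#' Digests the given proteins, enumerates site assignments under the
#' modification sets, samples `n_peptides` assignments and emits one MS2
#' spectrum each: singly charged primary b/y ions with log-normal
#' intensities (y drawn brighter than b by `y_boost`), satellite ions at
#' `satellite_rel_intensity` times their primary's intensity for a random
#' `satellite_fraction` of the matched-to-be primaries, `n_noise` uniform
#' noise peaks, and Gaussian m/z jitter of `ppm_jitter` ppm on every peak
#' and on the precursor. Fully reproducible from `seed`.
#'
#' @param proteins Protein tibble (see [read_fasta()]).
#' @param sets Modification sets from [compile_mod_sets()]; default none.
#' @param n_peptides Number of spectra/peptides to plant.
#' @param charges Candidate precursor charge states, sampled uniformly.
#' @param satellite_fraction Fraction of primary ions that receive their
#'   satellite channels.
#' @param satellite_rel_intensity Satellite intensity relative to the
#'   parent primary intensity.
#' @param n_noise Number of uniform noise peaks per spectrum.
#' @param ppm_jitter Gaussian m/z jitter (ppm, 1 s.d.).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model of
#'   the primary ions.
#' @param y_boost Multiplicative intensity advantage of y over b ions.
#' @param seed Random seed.
#' @param config [search_config()] providing digestion parameters, length
#'   and mass ranges and permutation caps.
#' @param mgf_path Optional path; when given the spectra are also written
#'   as MGF.
#' @return A list with `spectra` (spectrum tibble) and `truth` (one row per
#'   spectrum: scan, pep, sequence, set_index, charge, neutral_mass, planted
#'   ion counts, seed).
#' @export
#' @examples
#' prots <- tibble::tibble(accession = "P1", description = "",
#'                         sequence = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQK")
#' sim <- synth_spectra(prots, n_peptides = 2, seed = 7)
#' sim$truth
synth_spectra <- function(proteins, sets = compile_mod_sets(),
                          n_peptides = 50L, charges = c(2L, 3L),
                          satellite_fraction = 0.5,
                          satellite_rel_intensity = 0.3,
                          n_noise = 30L, ppm_jitter = 3,
                          intensity_meanlog = log(1e5),
                          intensity_sdlog = 0.6,
                          y_boost = 1.5, seed = 1L,
                          config = search_config(),
                          mgf_path = NULL) {
  set.seed(seed)
  cand <- digest(proteins, enzyme = config$enzyme,
                 specificity = config$specificity,
                 max_missed = config$max_missed,
                 len_range = config$len_range)
  asg <- build_assignments(cand, sets,
                           caps = list(max_sites = config$max_sites,
                                       max_per_mod = config$max_per_mod,
                                       max_perms = config$max_perms))
  asg <- asg[!asg$is_decoy, , drop = FALSE]
  asg <- asg[asg$neutral_mass >= config$mass_range[1] &
               asg$neutral_mass <= config$mass_range[2], , drop = FALSE]
  asg <- dplyr::distinct(asg, .data$pep, .keep_all = TRUE)
  if (n_peptides > nrow(asg)) {
    abort(paste0("n_peptides = ", n_peptides, " exceeds the ", nrow(asg),
                 " available candidate assignments"))
  }
  pick <- asg[sample.int(nrow(asg), n_peptides), , drop = FALSE]

  spec_rows <- vector("list", n_peptides)
  truth_rows <- vector("list", n_peptides)
  for (i in seq_len(n_peptides)) {
    a <- pick[i, ]
    z <- if (length(charges) == 1L) charges else sample(charges, 1L)
    lookup <- build_aa_lookup(sets, a$set_index)
    ions <- ion_series(a$sequence, lookup,
                       a$mod_positions[[1]], a$mod_titles[[1]],
                       a$nterm_title, a$cterm_title,
                       charge = z, satellites = TRUE)
    prim <- ions[ions$primary, ]
    sat <- ions[!ions$primary, ]

    prim_int <- rlnorm(nrow(prim), intensity_meanlog, intensity_sdlog)
    prim_int[prim$channel == "y"] <- prim_int[prim$channel == "y"] * y_boost

    with_sat <- runif(nrow(prim)) < satellite_fraction
    sat_key <- paste(sat$parent, sat$idx)
    prim_key <- paste(prim$channel, prim$idx)
    keep_sat <- sat_key %in% prim_key[with_sat]
    sat <- sat[keep_sat, , drop = FALSE]
    sat_int <- satellite_rel_intensity *
      prim_int[match(paste(sat$parent, sat$idx), prim_key)]

    mz <- c(prim$mz, sat$mz)
    intensity <- c(prim_int, sat_int)
    if (n_noise > 0L) {
      lo <- 100
      hi <- max(mz) * 1.1
      mz <- c(mz, runif(n_noise, lo, hi))
      intensity <- c(intensity,
                     rlnorm(n_noise, intensity_meanlog - 1, intensity_sdlog))
    }
    mz <- mz * (1 + rnorm(length(mz), 0, ppm_jitter) * 1e-6)
    o <- order(mz)

    premz <- (a$neutral_mass + z * PROTON_MASS) / z
    premz <- premz * (1 + rnorm(1, 0, ppm_jitter) * 1e-6)

    spec_rows[[i]] <- tibble::tibble(
      file = "synthetic", scan = i,
      title = paste0("synthetic.", i, ".", i, ".", z),
      premz = premz, charge = z, rt = i * 10,
      n_peaks = length(mz),
      peaks = list(tibble::tibble(mz = mz[o], intensity = intensity[o]))
    )
    truth_rows[[i]] <- tibble::tibble(
      scan = i, pep = a$pep, sequence = a$sequence,
      set_index = a$set_index, charge = z,
      neutral_mass = a$neutral_mass,
      n_primary = nrow(prim), n_satellite = nrow(sat),
      n_noise = n_noise, seed = seed
    )
  }
  spectra <- dplyr::bind_rows(spec_rows)
  class(spectra) <- unique(c("spectra_tbl", class(spectra)))
  truth <- dplyr::bind_rows(truth_rows)
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  list(spectra = spectra, truth = truth)
}
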