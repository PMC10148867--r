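# Peptide neutral masses, variable-modification site assignments, and
# theoretical primary (b/y) and satellite product-ion series.

# fast access structures derived from an aa_lookup tibble
.lookup_env <- function(lookup) {
  base <- lookup[lookup$kind %in% c("residue", "fixed") &
                   lookup$key == lookup$site, ]
  res_mass <- setNames(base$mass, base$site)
  res_nl <- setNames(base$nl, base$site)
  res_losses <- setNames(base$neutral_losses, base$site)

  var_any <- lookup[lookup$kind == "variable" & lookup$position == "Anywhere", ]
  nterm_fixed <- sum(lookup$mass[lookup$kind == "fixed" &
                                   lookup$key == "N-term"])
  cterm_fixed <- sum(lookup$mass[lookup$kind == "fixed" &
                                   lookup$key == "C-term"])
  var_term <- lookup[lookup$kind == "variable" & lookup$position != "Anywhere", ]
  list(
    res_mass = res_mass, res_nl = res_nl, res_losses = res_losses,
    var_any = var_any, var_term = var_term,
    nterm_fixed = nterm_fixed, cterm_fixed = cterm_fixed
  )
}

.var_mass <- function(lk, title, site) {
  i <- which(lk$var_any$title == title & lk$var_any$site == site)
  if (!length(i)) {
    abort(paste0("Variable modification '", title, "' at site '", site,
                 "' is not in this lookup"))
  }
  lk$var_any$mass[i[1]]
}

.term_mod_mass <- function(lk, title) {
  i <- which(lk$var_term$title == title)
  if (!length(i)) abort(paste0("Terminal modification '", title,
                               "' is not in this lookup"))
  lk$var_term$mass[i[1]]
}

# per-position residue masses for one site assignment
.position_masses <- function(res, lk, mod_positions, mod_titles) {
  unknown <- !(res %in% names(lk$res_mass))
  if (any(unknown)) {
    abort(paste0("Unresolvable residue '", res[which(unknown)[1]],
                 "' at position ", which(unknown)[1]))
  }
  m <- unname(lk$res_mass[res])
  for (i in seq_along(mod_positions)) {
    p <- mod_positions[i]
    m[p] <- .var_mass(lk, mod_titles[i], res[p])
  }
  m
}

#' Neutral monoisotopic peptide mass
#'
#' @param sequence Peptide sequence (single string).
#' @param lookup An `aa_lookup` from [build_aa_lookup()]; fixed
#'   modifications in the lookup are applied automatically.
#' @param mod_positions,mod_titles Parallel vectors placing variable
#'   Anywhere modifications at 1-based positions.
#' @param nterm_title,cterm_title Optional variable terminal modification
#'   titles.
#' @return Neutral mass in Da.
#' @export
#' @examples
#' lk <- build_aa_lookup(compile_mod_sets(), 1)
#' peptide_mass("PEPTIDE", lk)
peptide_mass <- function(sequence, lookup,
                         mod_positions = integer(), mod_titles = character(),
                         nterm_title = NA_character_,
                         cterm_title = NA_character_) {
  lk <- if (is.list(lookup) && !is.data.frame(lookup)) lookup
        else .lookup_env(lookup)
  res <- strsplit(sequence, NULL)[[1]]
  m <- .position_masses(res, lk, mod_positions, mod_titles)
  total <- sum(m) + WATER_MASS + lk$nterm_fixed + lk$cterm_fixed
  if (!is.na(nterm_title)) total <- total + .term_mod_mass(lk, nterm_title)
  if (!is.na(cterm_title)) total <- total + .term_mod_mass(lk, cterm_title)
  total
}

#' Enumerate variable-modification site assignments for one candidate
#'
#' Generates all placements of the set's variable modifications on a peptide,
#' subject to the permutation caps: at most `max_sites` variably modified
#' positions, at most `max_per_mod` positions carrying the same
#' modification, and at most `max_perms` assignments per candidate (sorted
#' by fewest modified positions, then leftmost positions, before
#' truncation). The all-unmodified assignment is included.
#'
#' @param sequence Peptide sequence.
#' @param sets,set_index Modification sets and the set to instantiate.
#' @param is_protein_nterm,is_protein_cterm Protein-terminal flags of the
#'   candidate (gate `Protein N-term`/`Protein C-term` options).
#' @param caps Named list with `max_sites`, `max_per_mod`, `max_perms`.
#' @param lookup Optional pre-built lookup for the set.
#' @return A tibble with columns `mod_positions`, `mod_titles` (list
#'   columns), `nterm_title`, `cterm_title`, `neutral_mass`.
#' @export
#' @examples
#' sets <- compile_mod_sets(variable = "Oxidation (M)")
#' enumerate_assignments("MAMK", sets, 2)
enumerate_assignments <- function(sequence, sets, set_index,
                                  is_protein_nterm = FALSE,
                                  is_protein_cterm = FALSE,
                                  caps = list(max_sites = 5L,
                                              max_per_mod = 3L,
                                              max_perms = 64L),
                                  lookup = NULL) {
  if (is.null(lookup)) lookup <- build_aa_lookup(sets, set_index)
  lk <- .lookup_env(lookup)
  res <- strsplit(sequence, NULL)[[1]]
  n <- length(res)

  # Anywhere variable mods: per-mod position subsets up to max_per_mod
  mods <- unique(lk$var_any[, c("title", "site")])
  per_mod <- purrr::pmap(mods, function(title, site) {
    pos <- which(res == site)
    opts <- list(integer(0))
    for (sz in seq_len(min(length(pos), caps$max_per_mod))) {
      # combn() treats a scalar first argument as seq_len(n); guard it
      cmb <- if (length(pos) == 1L) list(pos)
             else utils::combn(pos, sz, simplify = FALSE)
      opts <- c(opts, cmb)
    }
    list(title = title, options = opts)
  })

  # cross product across mods, rejecting overlaps and cap violations
  combos <- list(list(positions = integer(), titles = character()))
  for (pm in per_mod) {
    combos <- unlist(lapply(combos, function(cm) {
      lapply(pm$options, function(opt) {
        if (length(intersect(cm$positions, opt))) return(NULL)
        if (length(cm$positions) + length(opt) > caps$max_sites) return(NULL)
        list(positions = c(cm$positions, opt),
             titles = c(cm$titles, rep(pm$title, length(opt))))
      })
    }), recursive = FALSE)
    combos <- combos[!vapply(combos, is.null, logical(1))]
  }

  # terminal options
  nt_opts <- NA_character_
  ct_opts <- NA_character_
  vt <- lk$var_term
  for (i in seq_len(nrow(vt))) {
    m <- vt[i, ]
    applicable <- .term_applicable(m, res, is_protein_nterm, is_protein_cterm)
    if (!applicable) next
    if (grepl("N-term", m$position)) nt_opts <- c(nt_opts, m$title)
    else ct_opts <- c(ct_opts, m$title)
  }

  grid <- expand.grid(ci = seq_along(combos), nt = nt_opts, ct = ct_opts,
                      stringsAsFactors = FALSE)
  out <- tibble::tibble(
    mod_positions = purrr::map(grid$ci, ~ {
      o <- order(combos[[.x]]$positions); combos[[.x]]$positions[o]
    }),
    mod_titles = purrr::map(grid$ci, ~ {
      o <- order(combos[[.x]]$positions); combos[[.x]]$titles[o]
    }),
    nterm_title = grid$nt,
    cterm_title = grid$ct
  )

  # deterministic truncation: simplest explanations first
  nmods <- lengths(out$mod_positions) +
    !is.na(out$nterm_title) + !is.na(out$cterm_title)
  poskey <- vapply(out$mod_positions,
                   function(p) paste(sprintf("%04d", p), collapse = ","),
                   character(1))
  ord <- order(nmods, poskey,
               ifelse(is.na(out$nterm_title), "", out$nterm_title),
               ifelse(is.na(out$cterm_title), "", out$cterm_title),
               method = "radix")
  out <- out[ord, , drop = FALSE]
  if (nrow(out) > caps$max_perms) {
    out <- out[seq_len(caps$max_perms), , drop = FALSE]
  }

  out$neutral_mass <- purrr::pmap_dbl(
    list(out$mod_positions, out$mod_titles, out$nterm_title, out$cterm_title),
    function(p, t, nt, ct) peptide_mass(sequence, lk, p, t, nt, ct)
  )
  out
}

.term_applicable <- function(m, res, is_protein_nterm, is_protein_cterm) {
  n <- length(res)
  if (grepl("N-term", m$position)) {
    site_ok <- m$site == "N-term" || res[1] == m$site
    pos_ok <- m$position == "Any N-term" || is_protein_nterm
  } else {
    site_ok <- m$site == "C-term" || res[n] == m$site
    pos_ok <- m$position == "Any C-term" || is_protein_cterm
  }
  site_ok && pos_ok
}

# does a candidate reach a set? every variable Anywhere mod needs its site
# present; a site-specific or protein-terminal variable terminal mod needs an
# applicable terminus
.dispatch_ok <- function(sequence, is_protein_nterm, is_protein_cterm, lk) {
  res <- strsplit(sequence, NULL)[[1]]
  va <- unique(lk$var_any[, c("title", "site")])
  for (s in va$site) if (!any(res == s)) return(FALSE)
  vt <- lk$var_term
  for (i in seq_len(nrow(vt))) {
    if (!.term_applicable(vt[i, ], res, is_protein_nterm, is_protein_cterm)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Expand peptide candidates into site assignments across modification sets
#'
#' Dispatches each candidate to the compatible modification sets (a set
#' whose variable modifications require a site the peptide lacks is
#' skipped), enumerates site assignments under the permutation caps and
#' computes neutral masses. Candidates containing residues without defined
#' masses (B/J/O/U/X/Z) are dropped, with a message reporting the count.
#'
#' @param candidates Candidate tibble from [digest()].
#' @param sets `mod_sets` tibble.
#' @param caps Permutation caps (see [enumerate_assignments()]).
#' @return Assignment tibble: candidate columns plus `set_index`,
#'   `mod_positions`, `mod_titles`, `nterm_title`, `cterm_title`,
#'   `neutral_mass` and an annotated `pep` string.
#' @export
build_assignments <- function(candidates, sets,
                              caps = list(max_sites = 5L, max_per_mod = 3L,
                                          max_perms = 64L)) {
  bad <- grepl("[BJOUXZ]", candidates$sequence)
  if (any(bad)) {
    inform(paste0("Dropping ", sum(bad),
                  " candidate(s) containing residues without defined masses"))
    candidates <- candidates[!bad, , drop = FALSE]
  }
  pieces <- list()
  for (si in sets$set_index) {
    lookup <- build_aa_lookup(sets, si)
    lk <- .lookup_env(lookup)
    for (ci in seq_len(nrow(candidates))) {
      cand <- candidates[ci, ]
      if (!.dispatch_ok(cand$sequence, cand$is_protein_nterm,
                        cand$is_protein_cterm, lk)) next
      asg <- enumerate_assignments(
        cand$sequence, sets, si,
        is_protein_nterm = cand$is_protein_nterm,
        is_protein_cterm = cand$is_protein_cterm,
        caps = caps, lookup = lookup
      )
      asg$set_index <- si
      asg$sequence <- cand$sequence
      asg$protein_refs <- rep(cand$protein_refs, nrow(asg))
      asg$missed_cleavages <- cand$missed_cleavages
      asg$is_protein_nterm <- cand$is_protein_nterm
      asg$is_protein_cterm <- cand$is_protein_cterm
      asg$is_decoy <- cand$is_decoy
      pieces[[length(pieces) + 1L]] <- asg
    }
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) return(out)
  out$pep <- annotate_sequence(out$sequence, out$mod_positions,
                               out$mod_titles, out$nterm_title,
                               out$cterm_title)
  out$assignment_id <- seq_len(nrow(out))
  out
}

#' Modification-annotated peptide string
#'
#' @param sequence,mod_positions,mod_titles,nterm_title,cterm_title
#'   Assignment fields (vectorized over parallel lists).
#' @return Character vector such as `"n[Acetyl]M[Oxidation]AMK"`.
#' @export
annotate_sequence <- function(sequence, mod_positions, mod_titles,
                              nterm_title = NA_character_,
                              cterm_title = NA_character_) {
  purrr::pmap_chr(
    list(sequence, mod_positions, mod_titles, nterm_title, cterm_title),
    function(s, p, t, nt, ct) {
      res <- strsplit(s, NULL)[[1]]
      for (i in seq_along(p)) {
        res[p[i]] <- paste0(res[p[i]], "[", t[i], "]")
      }
      paste0(
        if (!is.na(nt)) paste0("n[", nt, "]") else "",
        paste(res, collapse = ""),
        if (!is.na(ct)) paste0("c[", ct, "]") else ""
      )
    }
  )
}

#' Theoretical primary and satellite product-ion series
#'
#' Computes the singly charged primary b/y series and the satellite
#' channels: water loss (`b0`/`y0`, -18.010565), ammonia loss (`b*`/`y*`,
#' -17.026549), modification-specific neutral losses (e.g. phosphate,
#' -97.9769), and — for precursors of charge >= 3 — the doubly charged
#' variants of all of these. Loss channels are emitted only at fragment
#' indices whose residue content can support the loss: ammonia loss requires
#' R/K/N/Q, water loss requires S/T/E/D, a modification loss requires the
#' modified residue inside the fragment.
#'
#' @param sequence Peptide sequence.
#' @param lookup An `aa_lookup` (or prepared internal lookup).
#' @param mod_positions,mod_titles,nterm_title,cterm_title Site assignment.
#' @param charge Precursor charge (gates the doubly charged channels).
#' @param satellites Emit satellite channels (`FALSE` gives primaries only).
#' @return A tibble with columns `channel`, `idx`, `mz`, `primary`
#'   (logical), `parent` (parent primary channel, `"b"` or `"y"`).
#' @export
#' @examples
#' lk <- build_aa_lookup(compile_mod_sets(), 1)
#' ion_series("PEPTIDEK", lk, charge = 2)
ion_series <- function(sequence, lookup,
                       mod_positions = integer(), mod_titles = character(),
                       nterm_title = NA_character_,
                       cterm_title = NA_character_,
                       charge = 2L, satellites = TRUE) {
  lk <- if (is.list(lookup) && !is.data.frame(lookup)) lookup
        else .lookup_env(lookup)
  res <- strsplit(sequence, NULL)[[1]]
  n <- length(res)
  if (n < 2L) abort("Product ions need at least 2 residues")
  m <- .position_masses(res, lk, mod_positions, mod_titles)

  nterm_total <- lk$nterm_fixed +
    if (!is.na(nterm_title)) .term_mod_mass(lk, nterm_title) else 0
  cterm_total <- lk$cterm_fixed +
    if (!is.na(cterm_title)) .term_mod_mass(lk, cterm_title) else 0

  idx <- seq_len(n - 1L)
  b <- cumsum(m)[idx] + nterm_total + PROTON_MASS
  # y_j contains the last j residues
  y <- cumsum(rev(m))[idx] + WATER_MASS + cterm_total + PROTON_MASS

  out <- list(
    tibble::tibble(channel = "b", idx = idx, mz = b, primary = TRUE,
                   parent = "b"),
    tibble::tibble(channel = "y", idx = idx, mz = y, primary = TRUE,
                   parent = "y")
  )

  if (satellites) {
    nh3_ok_b <- cummax(res[idx] %in% c("R", "K", "N", "Q")) == 1
    h2o_ok_b <- cummax(res[idx] %in% c("S", "T", "E", "D")) == 1
    res_rev <- rev(res)
    nh3_ok_y <- cummax(res_rev[idx] %in% c("R", "K", "N", "Q")) == 1
    h2o_ok_y <- cummax(res_rev[idx] %in% c("S", "T", "E", "D")) == 1

    add <- function(channel, parent, keep, mz) {
      if (!any(keep)) return()
      out[[length(out) + 1L]] <<- tibble::tibble(
        channel = channel, idx = idx[keep], mz = mz[keep],
        primary = FALSE, parent = parent
      )
    }
    NH3 <- 17.0265491
    H2O <- 18.0105646
    add("b*", "b", nh3_ok_b, b - NH3)
    add("y*", "y", nh3_ok_y, y - NH3)
    add("b0", "b", h2o_ok_b, b - H2O)
    add("y0", "y", h2o_ok_y, y - H2O)

    # modification-specific neutral losses (lookup "nl" entries)
    for (i in seq_along(mod_positions)) {
      p <- mod_positions[i]
      v <- lk$var_any[lk$var_any$title == mod_titles[i] &
                        lk$var_any$site == res[p], ]
      losses <- if (nrow(v)) v$neutral_losses[[1]] else numeric(0)
      for (loss in losses) {
        keep_b <- idx >= p
        keep_y <- idx >= (n - p + 1L)
        tag <- as.character(round(loss))
        add(paste0("b-", tag), "b", keep_b, b - loss)
        add(paste0("y-", tag), "y", keep_y, y - loss)
      }
    }
    # fixed modifications with losses (applied at every matching residue)
    nl_sites <- names(lk$res_losses)[vapply(lk$res_losses, length,
                                            integer(1)) > 0]
    for (s in nl_sites) {
      pos <- which(res == s)
      if (!length(pos)) next
      for (loss in lk$res_losses[[s]]) {
        keep_b <- idx >= min(pos)
        keep_y <- idx >= (n - max(pos) + 1L)
        tag <- as.character(round(loss))
        add(paste0("b-", tag), "b", keep_b, b - loss)
        add(paste0("y-", tag), "y", keep_y, y - loss)
      }
    }

    if (charge >= 3L) {
      singly <- dplyr::bind_rows(out)
      doubly <- singly
      doubly$mz <- (singly$mz + PROTON_MASS) / 2
      doubly$channel <- paste0(singly$channel, "^2")
      doubly$primary <- FALSE
      out[[length(out) + 1L]] <- doubly
    }
  }

  dplyr::bind_rows(out)
}

#' Possible precursor masses for a peptide under a modification specification
#'
#' Mirrors a calculator-style utility: compiles the given fixed/variable
#' modifications, enumerates the site assignments of `sequence` in every
#' compatible set and tabulates the neutral (and charged) precursor masses.
#'
#' @param sequence Peptide sequence.
#' @param fixed,variable Modification specifications.
#' @param charges Charge states for m/z columns.
#' @inheritParams enumerate_assignments
#' @return A tibble with the assignment, its set, neutral mass and m/z per
#'   charge.
#' @export
#' @examples
#' calc_monopeptide("MAMK", variable = "Oxidation (M)")
calc_monopeptide <- function(sequence, fixed = character(),
                             variable = character(), charges = 2:3,
                             caps = list(max_sites = 5L, max_per_mod = 3L,
                                         max_perms = 64L)) {
  sets <- compile_mod_sets(fixed, variable)
  cand <- tibble::tibble(
    sequence = sequence, protein_refs = list(character()),
    missed_cleavages = 0L, is_protein_nterm = TRUE, is_protein_cterm = TRUE,
    is_decoy = FALSE
  )
  asg <- build_assignments(cand, sets, caps)
  for (z in charges) {
    asg[[paste0("mz_", z)]] <- (asg$neutral_mass + z * PROTON_MASS) / z
  }
  dplyr::select(asg, "pep", "set_index", "neutral_mass",
                dplyr::starts_with("mz_"))
}

#' Theoretical MS2 ion series for a peptide under a modification specification
#'
#' @inheritParams calc_monopeptide
#' @param charge Precursor charge.
#' @return A tibble of ions (one row per channel/index) for every site
#'   assignment, with the annotated peptide in `pep`.
#' @export
#' @examples
#' calc_ms2ionseries("MAMK", variable = "Oxidation (M)", charge = 2)
calc_ms2ionseries <- function(sequence, fixed = character(),
                              variable = character(), charge = 2L,
                              caps = list(max_sites = 5L, max_per_mod = 3L,
                                          max_perms = 64L)) {
  sets <- compile_mod_sets(fixed, variable)
  cand <- tibble::tibble(
    sequence = sequence, protein_refs = list(character()),
    missed_cleavages = 0L, is_protein_nterm = TRUE, is_protein_cterm = TRUE,
    is_decoy = FALSE
  )
  asg <- build_assignments(cand, sets, caps)
  purrr::map_dfr(seq_len(nrow(asg)), function(i) {
    lookup <- build_aa_lookup(sets, asg$set_index[i])
    ions <- ion_series(
      sequence, lookup,
      asg$mod_positions[[i]], asg$mod_titles[[i]],
      asg$nterm_title[i], asg$cterm_title[i], charge = charge
    )
    ions$pep <- asg$pep[i]
    ions$set_index <- asg$set_index[i]
    ions
  })
}
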