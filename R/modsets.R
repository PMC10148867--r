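# Compilation of fixed/variable modifications into minimal compatible sets.
#
# A user's fixed modification is "coerced" to the variable category when a
# variable modification targets the same site (or the same terminus, for
# terminal modifications): applying both masses to one residue would be
# chemically unsound. Coerced modifications re-enter the combinatorial
# enumeration and are reverted to fixed within any combination where the
# conflict has disappeared.

.mod_id <- function(mods) paste(mods$title, mods$site, sep = "@")
.is_nterm <- function(mods) {
  mods$position %in% c("Any N-term", "Protein N-term") | mods$site == "N-term"
}
.is_cterm <- function(mods) {
  mods$position %in% c("Any C-term", "Protein C-term") | mods$site == "C-term"
}
.is_anywhere <- function(mods) mods$position == "Anywhere"

# two modifications cannot co-occur on the same residue/terminus
.scope_conflict <- function(a, b) {
  (a$site == b$site && .is_anywhere(a) == .is_anywhere(b)) ||
    (.is_nterm(a) && .is_nterm(b)) ||
    (.is_cterm(a) && .is_cterm(b))
}

#' Compile fixed and variable modifications into compatible sets
#'
#' Implements the coercion/enumeration/minimization chain: (1) fixed
#' modifications whose site or terminus also carries a variable modification
#' are coerced to variable; (2) combinations of the variable pool are
#' enumerated; (3) combinations with more than one N-terminal (or C-terminal)
#' modification are removed; (4) combinations in which a coerced site or
#' terminus carries no modification at all are removed (with several coerced
#' Anywhere sites, all must be covered); (5) within each surviving
#' combination, coerced modifications are reverted to fixed when no site
#' conflict remains.
#'
#' @param fixed,variable Character vectors of specifications (see
#'   [parse_mod_spec()]) or tibbles of already-parsed definitions.
#' @param registry Modification registry tibble.
#' @return A tibble of class `mod_sets`, one row per combination, with
#'   columns `set_index`, `fixed`, `variable` (list columns of definition
#'   tibbles carrying a `coerced` flag) and `label`.
#' @export
#' @examples
#' compile_mod_sets(
#'   fixed = c("Carbamidomethyl (C)", "TMT10plex (N-term)", "TMT10plex (K)"),
#'   variable = c("Acetyl (Protein N-term)", "Gln->pyro-Glu (N-term = Q)",
#'                "Oxidation (M)", "Deamidated (N)")
#' )
compile_mod_sets <- function(fixed = character(), variable = character(),
                             registry = mod_registry()) {
  fx <- .as_mod_tbl(fixed, registry)
  vr <- .as_mod_tbl(variable, registry)
  fx <- dplyr::distinct(fx, .data$title, .data$site, .keep_all = TRUE)
  vr <- dplyr::distinct(vr, .data$title, .data$site, .keep_all = TRUE)

  both <- intersect(.mod_id(fx), .mod_id(vr))
  if (length(both)) {
    abort(paste0("Modification(s) specified as both fixed and variable: ",
                 paste(both, collapse = ", ")))
  }
  .validate_fixed(fx)

  # (1) coercion
  coerce <- vapply(seq_len(nrow(fx)), function(i) {
    f <- fx[i, ]
    any(vapply(seq_len(nrow(vr)),
               function(j) .scope_conflict(f, vr[j, ]), logical(1)))
  }, logical(1))
  if (nrow(fx) == 0L) coerce <- logical(0)

  fixed_keep <- fx[!coerce, , drop = FALSE]
  pool <- dplyr::bind_rows(
    dplyr::mutate(fx[coerce, , drop = FALSE], coerced = TRUE),
    dplyr::mutate(vr, coerced = FALSE)
  )
  fixed_keep$coerced <- rep(FALSE, nrow(fixed_keep))

  if (nrow(pool) > 0L) {
    # terminal options before Anywhere options, user order within each
    pool <- pool[order(.is_anywhere(pool), method = "radix"), , drop = FALSE]
  }
  n <- nrow(pool)
  if (n > 16L) {
    abort("More than 16 variable (incl. coerced) modifications; refusing to enumerate.")
  }

  masks <- seq_len(2^n) - 1L
  sets <- list()
  for (mask in masks) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    s <- pool[idx, , drop = FALSE]
    # (3) at most one modification per terminus
    if (sum(.is_nterm(s)) > 1L || sum(.is_cterm(s)) > 1L) next
    # (4) every coerced site/terminus must carry some modification
    ok <- TRUE
    for (i in which(pool$coerced)) {
      m <- pool[i, ]
      if (.is_anywhere(m)) {
        if (!any(.is_anywhere(s) & s$site == m$site)) ok <- FALSE
      } else if (.is_nterm(m)) {
        if (!any(.is_nterm(s))) ok <- FALSE
      } else if (.is_cterm(m)) {
        if (!any(.is_cterm(s))) ok <- FALSE
      }
    }
    if (!ok) next
    # (5) revert coerced members with no remaining conflict
    revert <- vapply(seq_len(nrow(s)), function(i) {
      if (!s$coerced[i]) return(FALSE)
      others <- s[-i, , drop = FALSE]
      !any(vapply(seq_len(nrow(others)),
                  function(j) .scope_conflict(s[i, ], others[j, ]),
                  logical(1)))
    }, logical(1))
    if (nrow(s) == 0L) revert <- logical(0)

    set_fixed <- dplyr::bind_rows(fixed_keep, s[revert, , drop = FALSE])
    set_var <- s[!revert, , drop = FALSE]
    sets[[length(sets) + 1L]] <- list(fixed = set_fixed, variable = set_var)
  }

  out <- tibble::tibble(
    set_index = seq_along(sets),
    fixed = purrr::map(sets, "fixed"),
    variable = purrr::map(sets, "variable")
  )
  out$label <- purrr::map2_chr(out$fixed, out$variable, function(f, v) {
    paste0(
      "fixed{", paste(.mod_id(f), collapse = ", "), "} ",
      "variable{", paste(.mod_id(v), collapse = ", "), "}"
    )
  })
  class(out) <- c("mod_sets", class(out))
  out
}

.as_mod_tbl <- function(x, registry) {
  if (is.character(x)) {
    if (length(x) == 0L) {
      return(registry[0, ])
    }
    return(parse_mod_spec(x, registry))
  }
  stopifnot(is.data.frame(x))
  x
}

.validate_fixed <- function(fx) {
  if (nrow(fx) < 2L) return(invisible())
  for (i in seq_len(nrow(fx) - 1L)) {
    for (j in seq(i + 1L, nrow(fx))) {
      if (.scope_conflict(fx[i, ], fx[j, ])) {
        abort(paste0("Contradictory fixed modifications: ",
                     .mod_id(fx[i, ]), " and ", .mod_id(fx[j, ]),
                     " target the same site or terminus."))
      }
    }
  }
  invisible()
}

#' Build the amino-acid mass look-up for one modification set
#'
#' Produces the per-set table mapping residues (and termini) with or without
#' modifications to monoisotopic masses. Fixed modification masses are
#' applied directly to their site's entry; variable modifications add
#' entries alongside the unmodified ones, so e.g. both `M` and
#' `Oxidation (M)` are resolvable. Neutral-loss flags (`nl`) mark entries
#' whose modification triggers loss-channel permutation in ion generation.
#'
#' @param sets A `mod_sets` tibble from [compile_mod_sets()].
#' @param set_index Which set to instantiate.
#' @return A tibble of class `aa_lookup` with columns `key`, `site`,
#'   `title`, `position`, `mass`, `kind` (`residue`/`fixed`/`variable`),
#'   `coerced`, `nl` and `neutral_losses`.
#' @export
#' @examples
#' sets <- compile_mod_sets(variable = "Oxidation (M)")
#' build_aa_lookup(sets, 1)
build_aa_lookup <- function(sets, set_index = 1L) {
  stopifnot(set_index >= 1L, set_index <= nrow(sets))
  fx <- sets$fixed[[set_index]]
  vr <- sets$variable[[set_index]]

  base <- tibble::tibble(
    key = names(.residue_mass_vec),
    site = names(.residue_mass_vec),
    title = NA_character_,
    position = "Anywhere",
    mass = unname(.residue_mass_vec),
    kind = "residue",
    coerced = FALSE,
    nl = FALSE,
    neutral_losses = list(numeric(0))
  )

  # fixed Anywhere modifications replace the residue mass
  for (i in seq_len(nrow(fx))) {
    m <- fx[i, ]
    if (!.is_anywhere(m)) next
    k <- which(base$site == m$site)
    if (!length(k)) next
    base$mass[k] <- base$mass[k] + m$mono_mass
    base$title[k] <- m$title
    base$kind[k] <- "fixed"
    base$coerced[k] <- isTRUE(m$coerced)
    base$neutral_losses[[k]] <- m$neutral_losses[[1]]
    base$nl[k] <- length(m$neutral_losses[[1]]) > 0L
  }

  term_rows <- function(m, kind) {
    tibble::tibble(
      key = if (kind == "fixed" && m$site %in% c("N-term", "C-term")) m$site
            else paste0(m$title, " (", .term_key(m), ")"),
      site = m$site,
      title = m$title,
      position = m$position,
      mass = m$mono_mass,
      kind = kind,
      coerced = isTRUE(m$coerced),
      nl = length(m$neutral_losses[[1]]) > 0L,
      neutral_losses = m$neutral_losses
    )
  }

  extra <- list()
  # variable Anywhere modifications coexist with the unmodified entries
  for (i in seq_len(nrow(vr))) {
    m <- vr[i, ]
    if (.is_anywhere(m)) {
      extra[[length(extra) + 1L]] <- tibble::tibble(
        key = paste0(m$title, " (", m$site, ")"),
        site = m$site,
        title = m$title,
        position = m$position,
        mass = .residue_mass_vec[[m$site]] + m$mono_mass,
        kind = "variable",
        coerced = isTRUE(m$coerced),
        nl = length(m$neutral_losses[[1]]) > 0L,
        neutral_losses = m$neutral_losses
      )
    } else {
      extra[[length(extra) + 1L]] <- term_rows(m, "variable")
    }
  }
  for (i in seq_len(nrow(fx))) {
    m <- fx[i, ]
    if (.is_anywhere(m)) next
    extra[[length(extra) + 1L]] <- term_rows(m, "fixed")
  }

  out <- dplyr::bind_rows(base, dplyr::bind_rows(extra))
  attr(out, "set_index") <- set_index
  class(out) <- c("aa_lookup", class(out))
  out
}

.term_key <- function(m) {
  if (m$site %in% c("N-term", "C-term")) {
    if (grepl("Protein", m$position)) m$position else m$site
  } else {
    paste0(sub("Any ", "", m$position), " = ", m$site)
  }
}
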