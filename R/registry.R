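#' Built-in modification registry
#'
#' A small Unimod-style registry of the modifications most commonly used in
#' TMT, phospho, acetylome, ubiquitylome and SILAC closed searches. Each row
#' records a title, a site (a residue letter, or `"N-term"`/`"C-term"`), a
#' position (`Anywhere`, `Any N-term`, `Any C-term`, `Protein N-term`,
#' `Protein C-term`), an elemental composition, its monoisotopic mass and any
#' neutral losses. Use [add_mod()] / [remove_mod()] to extend or prune it,
#' and [write_mod_registry()] / [read_mod_registry()] to persist it as a
#' plain-text table.
#'
#' @return A tibble with columns `title`, `site`, `position`, `composition`,
#'   `mono_mass` and `neutral_losses` (list column of numeric vectors, Da).
#' @export
#' @examples
#' mod_registry()
mod_registry <- function() {
  reg <- tibble::tribble(
    ~title,               ~site,    ~position,        ~composition,
    "Carbamidomethyl",    "C",      "Anywhere",       "H(3) C(2) N O",
    "Oxidation",          "M",      "Anywhere",       "O",
    "Acetyl",             "K",      "Anywhere",       "H(2) C(2) O",
    "Acetyl",             "N-term", "Protein N-term", "H(2) C(2) O",
    "Deamidated",         "N",      "Anywhere",       "H(-1) N(-1) O",
    "Deamidated",         "Q",      "Anywhere",       "H(-1) N(-1) O",
    "Gln->pyro-Glu",      "Q",      "Any N-term",     "H(-3) N(-1)",
    "TMT10plex",          "N-term", "Any N-term",     "H(20) C(8) 13C(4) N 15N O(2)",
    "TMT10plex",          "K",      "Anywhere",       "H(20) C(8) 13C(4) N 15N O(2)",
    "TMTzero",            "N-term", "Any N-term",     "H(20) C(12) N(2) O(2)",
    "TMTzero",            "K",      "Anywhere",       "H(20) C(12) N(2) O(2)",
    "Phospho",            "S",      "Anywhere",       "H O(3) P",
    "Phospho",            "T",      "Anywhere",       "H O(3) P",
    "Phospho",            "Y",      "Anywhere",       "H O(3) P",
    "GG",                 "K",      "Anywhere",       "H(6) C(4) N(2) O(2)",
    "Carbamyl",           "K",      "Anywhere",       "H C N O",
    "Carbamyl",           "N-term", "Any N-term",     "H C N O",
    "Label:13C(6)15N(2)", "K",      "Anywhere",       "C(-6) 13C(6) N(-2) 15N(2)",
    "Label:13C(6)15N(4)", "R",      "Anywhere",       "C(-6) 13C(6) N(-4) 15N(4)"
  )
  reg$mono_mass <- composition_mass(reg$composition)
  # H3PO4 loss from phosphorylated S/T; Y phosphate is retained
  reg$neutral_losses <- purrr::pmap(
    list(reg$title, reg$site),
    function(title, site) {
      if (title == "Phospho" && site %in% c("S", "T")) 97.9768968 else numeric(0)
    }
  )
  reg
}

MOD_POSITIONS <- c(
  "Anywhere", "Any N-term", "Any C-term", "Protein N-term", "Protein C-term"
)

#' Add or remove a registry entry
#'
#' `add_mod()` appends a modification definition (validating its composition
#' mass when `mono_mass` is given); passing several `composition` formulas
#' sums them, so composite entries such as an N-terminal label combined with
#' pyro-glutamate formation on one site can be built by addition.
#' `remove_mod()` drops entries by title (and optionally site).
#'
#' @param registry A registry tibble, as from [mod_registry()].
#' @param title,site,position,composition Fields of the new entry;
#'   `composition` may be a character vector whose formulas are summed.
#' @param neutral_losses Numeric vector of neutral-loss masses (Da).
#' @param mono_mass Optional expected mass; checked against the composition
#'   to 1e-4 Da.
#' @return The modified registry tibble.
#' @export
#' @examples
#' reg <- add_mod(mod_registry(), "TMT10plex+Gln->pyro-Glu", "Q", "Any N-term",
#'                c("H(20) C(8) 13C(4) N 15N O(2)", "H(-3) N(-1)"))
add_mod <- function(registry, title, site, position, composition,
                    neutral_losses = numeric(0), mono_mass = NULL) {
  if (!position %in% MOD_POSITIONS) {
    abort(paste0("Invalid position '", position, "'. Must be one of: ",
                 paste(MOD_POSITIONS, collapse = ", ")))
  }
  mass <- sum(composition_mass(composition))
  if (!is.null(mono_mass) && abs(mass - mono_mass) > 1e-4) {
    abort(sprintf(
      "Composition mass %.5f differs from the stated mono_mass %.5f by more than 1e-4 Da",
      mass, mono_mass))
  }
  if (any(registry$title == title & registry$site == site)) {
    abort(paste0("Registry already has '", title, "' at site '", site, "'"))
  }
  dplyr::bind_rows(registry, tibble::tibble(
    title = title, site = site, position = position,
    composition = paste(composition, collapse = " "),
    mono_mass = mass,
    neutral_losses = list(neutral_losses)
  ))
}

#' @rdname add_mod
#' @export
remove_mod <- function(registry, title, site = NULL) {
  keep <- registry$title != title
  if (!is.null(site)) keep <- keep | registry$site != site
  if (all(keep)) warn(paste0("No registry entry matched '", title, "'"))
  registry[keep, ]
}

#' Persist a modification registry as a plain-text table
#'
#' @param registry A registry tibble.
#' @param path File path of the tab-delimited table; neutral losses are
#'   stored semicolon-separated.
#' @export
write_mod_registry <- function(registry, path) {
  out <- registry
  out$neutral_losses <- vapply(
    registry$neutral_losses,
    function(x) paste(format(x, digits = 10), collapse = ";"),
    character(1)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_mod_registry
#' @export
read_mod_registry <- function(path) {
  reg <- readr::read_tsv(path, col_types = readr::cols(
    title = "c", site = "c", position = "c", composition = "c",
    mono_mass = "d", neutral_losses = "c"
  ))
  reg$neutral_losses <- purrr::map(reg$neutral_losses, function(x) {
    if (is.na(x) || x == "") numeric(0) else as.numeric(stringr::str_split_1(x, ";"))
  })
  bad <- abs(composition_mass(reg$composition) - reg$mono_mass) > 1e-4
  if (any(bad)) {
    abort(paste0("mono_mass disagrees with composition for: ",
                 paste(reg$title[bad], collapse = ", ")))
  }
  reg
}

#' Parse a modification specification
#'
#' Resolves a specification such as `"Oxidation (M)"`,
#' `"Acetyl (Protein N-term)"` or `"Gln->pyro-Glu (N-term = Q)"` against the
#' registry. The parenthesised part names a residue site, a terminal
#' position, or a `position = site` pair; `"N-term"` alone means position
#' `Any N-term`.
#'
#' @param spec Character vector of specification strings.
#' @param registry Registry tibble, defaults to [mod_registry()].
#' @return A tibble of resolved definitions (one row per spec) with the
#'   registry columns plus `spec`.
#' @export
#' @examples
#' parse_mod_spec(c("Oxidation (M)", "TMT10plex (N-term)"))
parse_mod_spec <- function(spec, registry = mod_registry()) {
  dplyr::bind_rows(lapply(spec, .parse_mod_spec_one, registry = registry))
}

.parse_mod_spec_one <- function(spec, registry) {
  m <- stringr::str_match(trimws(spec), "^(.*\\S)\\s*\\(([^)]+)\\)$")
  if (is.na(m[1, 1])) {
    abort(paste0("Cannot parse modification specification '", spec,
                 "'. Expected \"Title (site-or-position [= site])\"."))
  }
  title <- m[1, 2]
  inner <- trimws(m[1, 3])

  if (grepl("=", inner, fixed = TRUE)) {
    parts <- trimws(stringr::str_split_1(inner, "="))
    pos_txt <- parts[1]
    site <- parts[2]
    position <- switch(pos_txt,
      "N-term" = "Any N-term",
      "C-term" = "Any C-term",
      pos_txt
    )
  } else if (inner %in% c("N-term", "C-term")) {
    site <- inner
    position <- paste("Any", inner)
  } else if (inner %in% c("Protein N-term", "Protein C-term",
                          "Any N-term", "Any C-term")) {
    site <- if (grepl("N-term", inner)) "N-term" else "C-term"
    position <- inner
  } else {
    site <- inner
    position <- "Anywhere"
  }
  if (!position %in% MOD_POSITIONS) {
    abort(paste0("Unknown position '", position, "' in spec '", spec, "'"))
  }

  hit <- registry[registry$title == title & registry$site == site, ]
  if (nrow(hit) == 0L) {
    if (!any(registry$title == title)) {
      abort(paste0("Unknown modification title '", title, "'"))
    }
    abort(paste0("Modification '", title, "' has no registry entry at site '",
                 site, "'"))
  }
  hit <- hit[1, ]
  if (hit$position != position) {
    abort(paste0("Modification '", title, "' at site '", site,
                 "' is registered at position '", hit$position,
                 "', not '", position, "'"))
  }
  out <- hit
  out$spec <- spec
  out
}
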