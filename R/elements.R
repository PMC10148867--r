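#' Monoisotopic element masses
#'
#' Returns the built-in table of monoisotopic element masses used for all
#' composition arithmetic, including the isotope labels (`2H`, `13C`, `15N`,
#' `18O`) that isobaric and SILAC reagents are built from.
#'
#' @return A tibble with columns `element` and `mass` (Da).
#' @export
#' @examples
#' element_masses()
element_masses <- function() {
  tibble::tibble(
    element = names(.element_mass_vec),
    mass = unname(.element_mass_vec)
  )
}

.element_mass_vec <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151,
  `2H` = 2.0141017780,
  `13C` = 13.0033548378,
  `15N` = 15.0001088984,
  `18O` = 17.9991604
)

WATER_MASS <- 2 * 1.0078250319 + 15.9949146221

#' Monoisotopic mass of an elemental composition
#'
#' Computes the monoisotopic mass of a chemical composition written in the
#' Unimod style, e.g. `"H(3) C(2) N O"` or `"H(20) C(8) 13C(4) N 15N O(2)"`.
#' Counts may be negative for loss formulas such as `"H(-3) N(-1)"`.
#'
#' @param composition Character vector of composition strings. An empty
#'   string is the empty sum and evaluates to 0.
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' composition_mass("H(2) O")   # water
#' composition_mass("H(-1) N(-1) O")  # deamidation
composition_mass <- function(composition) {
  vapply(composition, .composition_mass_one, numeric(1), USE.NAMES = FALSE)
}

.composition_mass_one <- function(composition) {
  stopifnot(is.character(composition), length(composition) == 1L)
  comp <- trimws(composition)
  if (is.na(comp) || comp == "") {
    return(0)
  }
  tokens <- stringr::str_split_1(comp, "\\s+")
  m <- stringr::str_match(tokens, "^([0-9]*[A-Z][a-z]?)(?:\\((-?[0-9]+)\\))?$")
  if (anyNA(m[, 1])) {
    abort(paste0(
      "Cannot parse composition token(s): ",
      paste(tokens[is.na(m[, 1])], collapse = ", ")
    ))
  }
  syms <- m[, 2]
  counts <- ifelse(is.na(m[, 3]), 1L, as.integer(m[, 3]))
  unknown <- setdiff(syms, names(.element_mass_vec))
  if (length(unknown)) {
    abort(paste0("Unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  sum(.element_mass_vec[syms] * counts)
}

# Elemental compositions of the 20 canonical amino-acid residues
.residue_compositions <- c(
  G = "C(2) H(3) N O",
  A = "C(3) H(5) N O",
  S = "C(3) H(5) N O(2)",
  P = "C(5) H(7) N O",
  V = "C(5) H(9) N O",
  T = "C(4) H(7) N O(2)",
  C = "C(3) H(5) N O S",
  L = "C(6) H(11) N O",
  I = "C(6) H(11) N O",
  N = "C(4) H(6) N(2) O(2)",
  D = "C(4) H(5) N O(3)",
  Q = "C(5) H(8) N(2) O(2)",
  K = "C(6) H(12) N(2) O",
  E = "C(5) H(7) N O(3)",
  M = "C(5) H(9) N O S",
  H = "C(6) H(7) N(3) O",
  F = "C(9) H(9) N O",
  R = "C(6) H(12) N(4) O",
  Y = "C(9) H(9) N O(2)",
  W = "C(11) H(10) N(2) O"
)

.residue_mass_vec <- local({
  v <- vapply(.residue_compositions, .composition_mass_one, numeric(1))
  names(v) <- names(.residue_compositions)
  v
})

#' Monoisotopic residue masses
#'
#' @return A tibble with columns `residue` and `mass` (Da) for the 20
#'   canonical amino acids (residue masses, i.e. without terminal H/OH).
#' @export
residue_masses <- function() {
  tibble::tibble(
    residue = names(.residue_mass_vec),
    mass = unname(.residue_mass_vec)
  )
}
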