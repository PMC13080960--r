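# Periodic-table data used for element guessing, bond perception and
# valence bookkeeping.

#' @keywords internal
PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U"
)

# Covalent radii in Angstrom (single-bond values as commonly tabulated).
# Only elements plausibly seen in protein-ligand systems are listed; an
# atom of an unlisted element is excluded from distance-based bond
# perception with a warning.
COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, K = 2.03, Ca = 1.76, Mn = 1.39, Fe = 1.32, Co = 1.26,
  Ni = 1.24, Cu = 1.32, Zn = 1.22, Se = 1.20, Br = 1.20, I = 1.39
)

# Standard neutral valences used by the formal-charge bookkeeping and the
# built-in protonation backend.  S and P accept several hypervalent
# states; those are handled explicitly in compute_formal_charge().
STANDARD_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, Se = 2
)

METAL_ELEMENTS <- c("Na", "Mg", "Al", "K", "Ca", "Mn", "Fe", "Co",
                    "Ni", "Cu", "Zn")

#' Canonicalize an element symbol
#'
#' Upper-cases the first letter, lower-cases the rest, and returns ""
#' when the result is not a known periodic-table symbol.
#'
#' @param x character vector of candidate symbols.
#' @return character vector of canonical symbols ("" where unknown).
#' @keywords internal
canonical_element <- function(x) {
  x <- trimws(x)
  out <- ifelse(
    nchar(x) == 0, "",
    paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  )
  out[!(out %in% PERIODIC_SYMBOLS)] <- ""
  out
}

is_valid_element <- function(x) {
  nzchar(x) & x %in% PERIODIC_SYMBOLS
}
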