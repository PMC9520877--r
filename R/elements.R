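# Periodic table, elements 1 (H) through 118 (Og).
# Symbol matching throughout the package is case-sensitive ("H" != "h").
PERIODIC_TABLE <- c(
  "H", "He",
  "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe",
  "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy",
  "Ho", "Er", "Tm", "Yb", "Lu",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi",
  "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr",
  "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds", "Rg", "Cn", "Nh", "Fl", "Mc",
  "Lv", "Ts", "Og"
)

#' Convert an element symbol to its atomic number
#'
#' Maps IUPAC element symbols to atomic numbers for elements 1 (H) through
#' 118 (Og). Matching is case-sensitive: `"Pt"` is platinum, `"pt"` is an
#' error. The star pseudo-atom `"*"` used by some drawing tools for
#' multi-center attachment is rejected with a dedicated message, since the
#' identifier requires every bond endpoint to be a real atom.
#'
#' @param symbol Character vector of element symbols.
#' @return Integer vector of atomic numbers (1--118).
#' @examples
#' element_to_atomic_number(c("H", "C", "Pt", "Og"))
#' @export
element_to_atomic_number <- function(symbol) {
  if (any(symbol == "*")) {
    stop("the star (\"*\") pseudo-atom is not supported; ",
         "specify every bond to a real atom explicitly", call. = FALSE)
  }
  z <- match(symbol, PERIODIC_TABLE)
  if (anyNA(z)) {
    bad <- unique(symbol[is.na(z)])
    stop("unknown element symbol(s): ", paste(sQuote(bad), collapse = ", "),
         "; expected an IUPAC symbol for elements 1 (H) to 118 (Og)",
         call. = FALSE)
  }
  as.integer(z)
}

#' Convert an atomic number to its element symbol
#'
#' @param z Integer vector of atomic numbers in 1--118.
#' @return Character vector of IUPAC element symbols.
#' @examples
#' atomic_number_to_element(c(1, 78))
#' @export
atomic_number_to_element <- function(z) {
  z <- as.integer(z)
  if (any(is.na(z) | z < 1L | z > 118L)) {
    stop("atomic numbers must lie in 1..118", call. = FALSE)
  }
  PERIODIC_TABLE[z]
}
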