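# Per-element parameters used across the package.
# Covalent radii: Cordero et al.; van der Waals radii: Bondi.
# lj_eps are the well depths (kcal/mol) of the package force field.

.element_table <- tibble::tribble(
  ~element, ~rcov, ~rvdw, ~lj_eps, ~valence, ~mass,
  "H",  0.31, 1.20, 0.020, 1L,   1.008,
  "C",  0.76, 1.70, 0.100, 4L,  12.011,
  "N",  0.71, 1.55, 0.120, 3L,  14.007,
  "O",  0.66, 1.52, 0.150, 2L,  15.999,
  "F",  0.57, 1.47, 0.090, 1L,  18.998,
  "P",  1.07, 1.80, 0.200, 3L,  30.974,
  "S",  1.05, 1.80, 0.250, 2L,  32.06,
  "Cl", 1.02, 1.75, 0.250, 1L,  35.45,
  "Br", 1.20, 1.85, 0.300, 1L,  79.904,
  "I",  1.39, 1.98, 0.350, 1L, 126.904,
  "Se", 1.20, 1.90, 0.290, 2L,  78.971,
  "B",  0.84, 1.92, 0.095, 3L,  10.81,
  "Si", 1.11, 2.10, 0.200, 4L,  28.085
)

.norm_element <- function(x) {
  x <- gsub("[^A-Za-z]", "", x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' Look up a per-element parameter
#'
#' @param element character vector of element symbols.
#' @param what one of `"rcov"` (covalent radius, Angstrom), `"rvdw"`
#'   (van der Waals radius, Angstrom), `"lj_eps"` (Lennard-Jones well depth,
#'   kcal/mol), `"valence"`, `"mass"`.
#' @return numeric vector, same length as `element`.
#' @export
element_param <- function(element, what = c("rcov", "rvdw", "lj_eps", "valence", "mass")) {
  what <- match.arg(what)
  el <- .norm_element(element)
  i <- match(el, .element_table$element)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(el[is.na(i)]), collapse = ", "))
  }
  .element_table[[what]][i]
}

is_valid_element <- function(element) {
  .norm_element(element) %in% .element_table$element
}

# Ideal bond length (Angstrom) for an element pair and bond order:
# sum of covalent radii, shortened for multiple bonds.
ideal_bond_length <- function(el_i, el_j, order = 1) {
  element_param(el_i, "rcov") + element_param(el_j, "rcov") -
    0.12 * (pmin(order, 3) - 1)
}
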