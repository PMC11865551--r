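## Physical constants and element data. All internal quantities are atomic
## units (hartree, bohr, electron mass, hbar/E_h time); conversions happen at
## I/O boundaries only.

#' Physical constants used throughout the package
#'
#' A named list of conversion factors and constants (CODATA values):
#' \describe{
#'   \item{bohr_per_angstrom}{1.8897259886 bohr per Angstrom}
#'   \item{fs_per_au_time}{0.02418884254 fs per atomic time unit (hbar/E_h)}
#'   \item{kboltz_hartree}{Boltzmann constant, 3.166811563e-6 hartree/K}
#'   \item{emass_per_amu}{1822.888486209 electron masses per unified amu}
#' }
#' @export
evcont_constants <- list(
  bohr_per_angstrom = 1.8897259886,
  fs_per_au_time    = 0.02418884254,
  kboltz_hartree    = 3.166811563e-6,
  emass_per_amu     = 1822.888486209
)

## Elements supported by the built-in machinery (H plus first row; heavier
## symbols recognised for geometry I/O even if no built-in basis exists).
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"
)

## Standard atomic weights (amu).
.element_masses <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948
)

#' Map element symbols to atomic numbers
#' @param symbols character vector of element symbols (case sensitive, e.g. "H", "O")
#' @return integer vector of atomic numbers
#' @export
element_number <- function(symbols) {
  z <- match(symbols, .element_symbols)
  if (anyNA(z)) {
    bad <- symbols[is.na(z)]
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  }
  as.integer(z)
}

#' Map atomic numbers to element symbols
#' @param z integer vector of atomic numbers
#' @return character vector
#' @export
element_symbol <- function(z) {
  if (any(z < 1L | z > length(.element_symbols))) {
    stop("atomic number out of supported range 1..", length(.element_symbols))
  }
  .element_symbols[z]
}

#' Standard atomic masses (amu) for atomic numbers
#' @param z integer vector of atomic numbers
#' @return numeric vector of masses in unified atomic mass units
#' @export
element_mass <- function(z) {
  if (any(z < 1L | z > length(.element_masses))) {
    stop("atomic number out of supported range 1..", length(.element_masses))
  }
  .element_masses[z]
}
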