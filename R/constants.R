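#' Physical constants (CODATA 2018)
#'
#' Fundamental constants used by the thermochemistry and ensemble machinery,
#' in SI units unless noted. Energies are carried internally in hartree;
#' published-unit output uses the conversion factors below.
#'
#' @format A named list:
#' \describe{
#'   \item{h}{Planck constant, J s}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{c_cm}{speed of light, cm/s (for wavenumber conversions)}
#'   \item{R}{molar gas constant, J/(mol K)}
#'   \item{amu}{atomic mass constant, kg}
#'   \item{hartree_J}{1 hartree in J}
#'   \item{kB_hartree}{Boltzmann constant, hartree/K}
#'   \item{atm_Pa}{1 atm in Pa}
#'   \item{hartree_kcal}{1 hartree in kcal/mol}
#'   \item{hartree_kJ}{1 hartree in kJ/mol}
#'   \item{bohr_A}{1 bohr in Angstrom}
#' }
#' @export
codata2018 <- list(
  h          = 6.62607015e-34,
  kB         = 1.380649e-23,
  N_A        = 6.02214076e23,
  c_cm       = 2.99792458e10,
  R          = 8.31446261815324,
  amu        = 1.66053906660e-27,
  hartree_J  = 4.3597447222071e-18,
  kB_hartree = 1.380649e-23 / 4.3597447222071e-18,
  atm_Pa     = 101325,
  hartree_kcal = 627.5094740631,
  hartree_kJ   = 2625.4996394799,
  bohr_A     = 0.529177210903
)

#' Convert energies between the units used in this package
#'
#' Cluster energetics are conventionally reported in kcal/mol, hydration
#' thermodynamics in kJ/mol, and electronic-structure energies in hartree;
#' this helper converts between the three.
#'
#' @param x numeric vector of energies.
#' @param from,to one of `"hartree"`, `"kcal/mol"`, `"kJ/mol"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(1, "hartree", "kcal/mol")  # 627.5095
#' @export
convert_energy <- function(x, from = "hartree", to = "kcal/mol") {
  units <- c("hartree" = 1,
             "kcal/mol" = codata2018$hartree_kcal,
             "kJ/mol"   = codata2018$hartree_kJ)
  from <- match.arg(from, names(units))
  to   <- match.arg(to, names(units))
  x * units[[to]] / units[[from]]
}

# standard atomic masses (u), most abundant isotopic composition
.atomic_masses <- c(H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994,
                    Ar = 39.948, He = 4.002602, Ne = 20.1797)

# covalent radii (Angstrom), Cordero et al. consensus values
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66,
                     Ar = 0.96, He = 0.28, Ne = 0.58)

#' Atomic masses for the elements handled by the package
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses in unified atomic mass units.
#' @export
atomic_mass <- function(elements) {
  m <- .atomic_masses[elements]
  if (anyNA(m)) {
    stop("no mass tabulated for element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
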