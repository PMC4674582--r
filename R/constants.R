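#' Physical constants and unit conversions
#'
#' Returns the CODATA constants and unit-conversion factors used by the
#' thermodynamic routines.  Partition functions are evaluated internally in
#' SI units; energies cross the interface in kcal/mol, lengths in Angstrom,
#' masses in amu and temperatures in Kelvin.
#'
#' @return A named list with components:
#'   \describe{
#'     \item{kB_kcal}{Boltzmann constant expressed per mole, kcal/(mol K).}
#'     \item{kB_J}{Boltzmann constant, J/K.}
#'     \item{h_J, hbar_J}{Planck constant and reduced Planck constant, J s.}
#'     \item{NA_mol}{Avogadro constant, 1/mol.}
#'     \item{amu_kg}{Atomic mass unit, kg.}
#'     \item{angstrom_m}{Angstrom, m.}
#'     \item{kcalmol_J}{One kcal/mol expressed in J per molecule.}
#'     \item{euler_e}{Euler's number e, the prefactor of the standard-state
#'       translational partition function.}
#'     \item{rho_standard}{Standard concentration 1 mol/L in molecules/m^3.}
#'     \item{coulomb_kcal}{Coulomb prefactor, kcal mol^-1 A e^-2.}
#'   }
#' @export
physical_constants <- function() {
  NA_mol <- 6.02214076e23
  kB_J <- 1.380649e-23
  h_J <- 6.62607015e-34
  list(
    kB_kcal = kB_J * NA_mol / 4184,   # 1.987204e-3 kcal/(mol K)
    kB_J = kB_J,
    h_J = h_J,
    hbar_J = h_J / (2 * pi),
    NA_mol = NA_mol,
    amu_kg = 1.66053906892e-27,
    angstrom_m = 1e-10,
    kcalmol_J = 4184 / NA_mol,
    euler_e = exp(1),
    rho_standard = NA_mol * 1e3,      # 1 mol/L = 6.022e26 m^-3
    coulomb_kcal = 332.0637
  )
}

# Standard atomic masses (amu) for the elements this package handles.
.element_masses <- c(
  H = 1.00794, He = 4.002602, B = 10.811, C = 12.0107, N = 14.0067,
  O = 15.9994, F = 18.9984032, Na = 22.98977, Mg = 24.305, Si = 28.0855,
  P = 30.973762, S = 32.065, Cl = 35.453, K = 39.0983, Ca = 40.078,
  Fe = 55.845, Zn = 65.409, Se = 78.96, Br = 79.904, I = 126.90447
)

# Generic per-element Lennard-Jones parameters for the built-in toy field:
# sigma (A) and epsilon (kcal/mol).  These are deliberately simple,
# UFF-flavoured values; the toy field exists to make the search machinery
# testable, not to model chemistry accurately.
.element_vdw <- list(
  H  = c(sigma = 2.57, epsilon = 0.022),
  C  = c(sigma = 3.43, epsilon = 0.105),
  N  = c(sigma = 3.26, epsilon = 0.069),
  O  = c(sigma = 3.12, epsilon = 0.060),
  F  = c(sigma = 3.00, epsilon = 0.050),
  P  = c(sigma = 3.70, epsilon = 0.305),
  S  = c(sigma = 3.59, epsilon = 0.274),
  Cl = c(sigma = 3.52, epsilon = 0.227),
  Br = c(sigma = 3.73, epsilon = 0.251),
  I  = c(sigma = 4.01, epsilon = 0.339)
)
.default_vdw <- c(sigma = 3.5, epsilon = 0.1)

element_mass <- function(element) {
  m <- .element_masses[element]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

element_vdw <- function(element) {
  out <- t(vapply(element, function(e) {
    p <- .element_vdw[[e]]
    if (is.null(p)) .default_vdw else p
  }, numeric(2)))
  colnames(out) <- c("sigma", "epsilon")
  rownames(out) <- NULL
  out
}
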