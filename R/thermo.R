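# Multiwell-approximation binding free energy: Hessian normal modes,
# harmonic vibrational partition functions, ideal-gas translational and
# rigid-rotor rotational factors, the multiwell configuration-integral sum
# and the binding decomposition.
#
# The configuration integral of a species is approximated as a sum over
# its distinct low-energy wells i:
#   Z = sum_i exp(-E0_i / kT) * Zv_i * Zt * Zr,   G = -kT ln Z,
# where E0_i is the well-bottom potential energy, Zv_i the harmonic
# vibrational factor of the well, and Zt, Zr the whole-body translational
# and rotational factors of the species.  All partition functions are
# evaluated in SI units; energies cross the interface in kcal/mol.

#' Describe one harmonic energy well
#'
#' @param E0 Well-bottom potential energy, kcal/mol.
#' @param frequencies Angular normal-mode frequencies omega, rad/s, all
#'   positive after rigid-mode filtering.
#' @param n_vibrating_atoms Number of vibrating atoms n.
#' @param species `"complex"` (ligand vibrating in the rigid receptor's
#'   field: all 3n modes) or `"free-ligand"` (3n - 6 modes, or 3n - 5 for
#'   a linear molecule, after removing rigid translations/rotations).
#' @return An object of class `well_descriptor`.
#' @export
well_descriptor <- function(E0, frequencies, n_vibrating_atoms,
                            species = c("complex", "free-ligand")) {
  species <- match.arg(species)
  frequencies <- as.numeric(frequencies)
  if (any(frequencies <= 0)) stop("all well frequencies must be positive")
  n <- as.integer(n_vibrating_atoms)
  expected <- switch(species, complex = 3L * n,
                     `free-ligand` = c(3L * n - 6L, 3L * n - 5L))
  if (!length(frequencies) %in% pmax(expected, 0L))
    stop("well has ", length(frequencies), " modes; expected ",
         paste(pmax(expected, 0L), collapse = " or "), " for species '",
         species, "'")
  structure(list(E0 = E0, frequencies = frequencies,
                 n_vibrating_atoms = n, species = species),
            class = "well_descriptor")
}

#' Principal moments of inertia
#'
#' @param conf Conformation, n x 3 A.
#' @param masses Atomic masses, amu.
#' @return Sorted ascending principal moments, amu A^2.
#' @export
inertia_moments <- function(conf, masses) {
  conf <- as_conformation(conf)
  stopifnot(length(masses) == nrow(conf), all(masses > 0))
  com <- colSums(conf * masses) / sum(masses)
  r <- sweep(conf, 2L, com)
  r2 <- rowSums(r * r)
  I <- diag(c(sum(masses * r2), sum(masses * r2), sum(masses * r2))) -
    t(r) %*% (r * masses)
  sort(eigen(I, symmetric = TRUE)$values)
}

#' Species-level thermodynamic inputs
#'
#' @param total_mass Overall mass M of the species, amu.
#' @param moments Principal moments of inertia, amu A^2 (length 3), or
#'   `NULL` for a species without rotational degrees of freedom (a single
#'   atom).
#' @param temperature Temperature, K (default 310).
#' @param density Concentration rho, molecules/m^3 (default the standard
#'   state 1 mol/L).
#' @return An object of class `species_thermo`.
#' @export
species_thermo <- function(total_mass, moments = NULL, temperature = 310,
                           density = physical_constants()$rho_standard) {
  stopifnot(total_mass > 0, temperature > 0, density > 0)
  if (!is.null(moments)) {
    moments <- sort(as.numeric(moments))
    stopifnot(length(moments) == 3L, all(moments >= 0))
  }
  structure(list(total_mass = total_mass, moments = moments,
                 temperature = temperature, density = density),
            class = "species_thermo")
}

#' Vibrational partition function of a well
#'
#' The quantum harmonic-oscillator product over the retained modes,
#' `prod_l exp(-hbar w_l / 2kT) / (1 - exp(-hbar w_l / kT))`, zero of
#' energy at the well bottom.  An empty mode list gives 1.
#'
#' @param well A [well_descriptor()] (or bare numeric vector of angular
#'   frequencies, rad/s).
#' @param temperature Temperature, K.
#' @return The partition function value (use [log_vibrational_partition()]
#'   for many/stiff modes).
#' @export
vibrational_partition <- function(well, temperature = 310) {
  exp(log_vibrational_partition(well, temperature))
}

#' @rdname vibrational_partition
#' @export
log_vibrational_partition <- function(well, temperature = 310) {
  w <- if (inherits(well, "well_descriptor")) well$frequencies
       else as.numeric(well)
  stopifnot(temperature > 0)
  if (length(w) == 0L) return(0)
  if (any(w <= 0)) stop("all frequencies must be positive")
  pc <- physical_constants()
  x <- pc$hbar_J * w / (pc$kB_J * temperature)
  sum(-x / 2 - log1p(-exp(-x)))
}

#' Translational partition function
#'
#' The standard-state ideal-gas factor
#' `Zt = e (2 pi M k T)^{3/2} / (h^3 rho)`, with the Euler-number
#' prefactor and rho the standard concentration (1 mol/L) unless
#' overridden.
#'
#' @param sp A [species_thermo()].
#' @return Zt (dimensionless).
#' @export
translational_partition <- function(sp) {
  exp(log_translational_partition(sp))
}

#' @rdname translational_partition
#' @export
log_translational_partition <- function(sp) {
  stopifnot(inherits(sp, "species_thermo"))
  pc <- physical_constants()
  M <- sp$total_mass * pc$amu_kg
  kT <- pc$kB_J * sp$temperature
  1 + 1.5 * log(2 * pi * M * kT) - 3 * log(pc$h_J) - log(sp$density)
}

#' Rotational partition function
#'
#' The classical rigid-rotor factor
#' `Zr = (8 pi^2 k T)^{3/2} / h^3 * sqrt(pi I_A I_B I_C)` from the
#' principal moments of inertia of the given geometry.
#'
#' @param conf Conformation, n x 3 A (at least 3 non-collinear atoms).
#' @param masses Atomic masses, amu.
#' @param temperature Temperature, K.
#' @return Zr (dimensionless).
#' @export
rotational_partition <- function(conf, masses, temperature = 310) {
  moments <- inertia_moments(conf, masses)
  if (moments[1L] < 1e-8 * max(moments[3L], 1))
    stop("unsupported geometry: collinear (or single-atom) molecule has ",
         "no three independent rotational axes")
  exp(log_rotational_partition_moments(moments, temperature))
}

# moments in amu A^2; NULL -> no rotational degrees of freedom (log Zr = 0)
log_rotational_partition_moments <- function(moments, temperature) {
  if (is.null(moments)) return(0)
  pc <- physical_constants()
  I_SI <- moments * pc$amu_kg * pc$angstrom_m^2
  kT <- pc$kB_J * temperature
  1.5 * log(8 * pi^2 * kT) - 3 * log(pc$h_J) + 0.5 * log(pi * prod(I_SI))
}

#' Normal-mode frequencies of a well
#'
#' Builds the mass-weighted Hessian over the ligand Cartesian coordinates
#' by central finite differences of the analytic gradient (step `fd_step`,
#' symmetrized), and converts its eigenvalues to angular frequencies.  For
#' a free ligand the 6 rigid-body modes (5 for a linear molecule) are
#' removed; for the ligand-in-receptor complex the external field breaks
#' translational/rotational invariance and all 3n modes are retained.
#' Slightly negative eigenvalues (below 1 cm^-1 equivalent in magnitude)
#' are dropped with a warning; larger negative curvature means the input
#' is not a minimum and is an error.
#'
#' @param model An [energy_model()].
#' @param receptor A [rigid_receptor()] for `species = "complex"`, `NULL`
#'   for a free ligand.
#' @param ligand A [flexible_ligand()].
#' @param minimum Conformation at a local minimum of the model.
#' @param species `"complex"` or `"free-ligand"`.
#' @param fd_step Finite-difference step, A (default 1e-4).
#' @return A [well_descriptor()] with `E0` set to the model energy at
#'   `minimum`.
#' @export
normal_mode_frequencies <- function(model, receptor, ligand, minimum,
                                    species = c("complex", "free-ligand"),
                                    fd_step = 1e-4) {
  species <- match.arg(species)
  minimum <- as_conformation(minimum, n_atoms = nrow(ligand$atoms))
  if (species == "free-ligand") receptor <- NULL
  n <- nrow(minimum)
  at <- evaluate_model(model, receptor, ligand, minimum)
  gmax <- max(abs(at$gradient))
  if (gmax > 1e-3)
    warning("input pose has max gradient ", format(gmax, digits = 3),
            " kcal/mol/A; frequencies assume a converged minimum")
  dof <- 3L * n
  H <- matrix(0, dof, dof)
  x0 <- as.numeric(minimum)
  for (a in seq_len(dof)) {
    xp <- x0; xp[a] <- xp[a] + fd_step
    xm <- x0; xm[a] <- xm[a] - fd_step
    gp <- as.numeric(evaluate_model(model, receptor, ligand,
                                    matrix(xp, ncol = 3L))$gradient)
    gm <- as.numeric(evaluate_model(model, receptor, ligand,
                                    matrix(xm, ncol = 3L))$gradient)
    H[, a] <- (gp - gm) / (2 * fd_step)
  }
  H <- (H + t(H)) / 2
  # note: coordinates flatten column-major as (x1..xn, y1..yn, z1..zn)
  m3 <- rep(ligand$atoms$mass, times = 3L)
  Hmw <- H / sqrt(outer(m3, m3))
  lambda <- eigen(Hmw, symmetric = TRUE, only.values = TRUE)$values
  pc <- physical_constants()
  # (kcal/mol/A^2)/amu  ->  1/s^2
  to_si <- pc$kcalmol_J / pc$angstrom_m^2 / pc$amu_kg
  lambda_si <- lambda * to_si
  if (species == "free-ligand") {
    moments <- inertia_moments(minimum, ligand$atoms$mass)
    linear <- n >= 2L && moments[1L] < 1e-8 * max(moments[3L], 1)
    n_rigid <- if (n == 1L) 3L else if (linear) 5L else 6L
    drop_idx <- order(abs(lambda_si))[seq_len(min(n_rigid, length(lambda_si)))]
    kept <- lambda_si[-drop_idx]
    if (length(kept) > 0L &&
        max(abs(lambda_si[drop_idx])) > 1e-6 * max(kept))
      warning("removed rigid-body modes are not well separated from the ",
              "vibrational spectrum")
    lambda_si <- kept
  }
  # tolerance: |omega| of 1 cm^-1
  omega_tol <- 2 * pi * 2.99792458e10  # rad/s
  lam_tol <- omega_tol^2
  if (any(lambda_si < -lam_tol))
    stop("negative curvature at input pose: not a local minimum ",
         "(saddle point?)")
  small <- lambda_si <= 0
  if (any(small)) {
    warning(sum(small), " near-zero mode(s) dropped from the well")
    lambda_si <- lambda_si[!small]
  }
  freq <- sqrt(lambda_si)
  if (species == "free-ligand" && n == 1L) {
    # a free atom has no vibrations; represent as an empty complex-type
    # well with zero modes
    return(structure(list(E0 = at$energy, frequencies = numeric(0),
                          n_vibrating_atoms = n, species = species),
                     class = "well_descriptor"))
  }
  well_descriptor(E0 = at$energy, frequencies = sort(freq),
                  n_vibrating_atoms = n, species = species)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Multiwell free energy of a species
#'
#' `G = -kT ln sum_i exp(-E0_i/kT) Zv_i Zt Zr`, summed in log space.
#' Wells must be distinct physical minima (deduplication happens upstream
#' in the minima set).
#'
#' @param wells Non-empty list of [well_descriptor()]s.
#' @param sp A [species_thermo()] providing M, the principal moments and
#'   the temperature.
#' @return Free energy G, kcal/mol.
#' @export
multiwell_free_energy <- function(wells, sp) {
  if (inherits(wells, "well_descriptor")) wells <- list(wells)
  if (length(wells) == 0L) stop("at least one well is required")
  stopifnot(inherits(sp, "species_thermo"))
  pc <- physical_constants()
  kT <- pc$kB_kcal * sp$temperature
  logZt <- log_translational_partition(sp)
  logZr <- log_rotational_partition_moments(sp$moments, sp$temperature)
  logZ_i <- vapply(wells, function(w) {
    -w$E0 / kT + log_vibrational_partition(w, sp$temperature) +
      logZt + logZr
  }, 0)
  -kT * log_sum_exp(logZ_i)
}

#' Binding free energy decomposition
#'
#' Assembles `dG_bind = G(PL) - G(P) - G(L)` in the multiwell
#' approximation and splits it into the additive components reported per
#' complex: the global-minimum potential-energy difference `dE`, the
#' vibrational, translational and rotational corrections `dG_v`, `dG_t`,
#' `dG_r` evaluated at the global minima, and the multiple-minima
#' correction `dG_all` (multiwell binding free energy minus the
#' global-minima-only one).  The identity
#' `dG_bind = dE + dG_v + dG_t + dG_r + dG_all` holds by construction.
#' The protein is rigid: it contributes a potential energy and (in the
#' default three-species convention) whole-body translation and rotation,
#' but no vibrations.
#'
#' @param complex_wells Non-empty list of [well_descriptor()]s of the
#'   protein-ligand complex (sorted or not; sorted internally by E0).
#' @param ligand_wells Non-empty list of [well_descriptor()]s of the free
#'   ligand.
#' @param protein_energy Potential energy of the rigid protein, kcal/mol.
#' @param sp_complex,sp_ligand,sp_protein [species_thermo()] objects for
#'   the three species (equal temperatures required).
#' @param translation_rotation `"three-species"` (default: PL, P and L
#'   each contribute Zt and Zr) or `"ligand-only"` (complex and protein
#'   factors assumed to cancel; only the ligand's loss counts).
#' @param dG_exp Optional experimental binding free energy to carry along.
#' @return An object of class `binding_breakdown` with fields `dE`,
#'   `dG_v`, `dG_t`, `dG_r`, `dG_all`, `dG_bind`, `dG_exp`.
#' @export
binding_breakdown <- function(complex_wells, ligand_wells, protein_energy,
                              sp_complex, sp_ligand, sp_protein,
                              translation_rotation = c("three-species",
                                                       "ligand-only"),
                              dG_exp = NA_real_) {
  translation_rotation <- match.arg(translation_rotation)
  if (inherits(complex_wells, "well_descriptor"))
    complex_wells <- list(complex_wells)
  if (inherits(ligand_wells, "well_descriptor"))
    ligand_wells <- list(ligand_wells)
  stopifnot(length(complex_wells) >= 1L, length(ligand_wells) >= 1L)
  Ts <- c(sp_complex$temperature, sp_ligand$temperature,
          sp_protein$temperature)
  if (max(Ts) - min(Ts) > 1e-9)
    stop("inconsistent temperatures across species")
  temp <- Ts[1L]
  kT <- physical_constants()$kB_kcal * temp
  complex_wells <- complex_wells[order(vapply(complex_wells, `[[`, 0, "E0"))]
  ligand_wells <- ligand_wells[order(vapply(ligand_wells, `[[`, 0, "E0"))]

  dE <- complex_wells[[1L]]$E0 - protein_energy - ligand_wells[[1L]]$E0
  dG_v <- -kT * (log_vibrational_partition(complex_wells[[1L]], temp) -
                 log_vibrational_partition(ligand_wells[[1L]], temp))
  if (translation_rotation == "three-species") {
    dG_t <- -kT * (log_translational_partition(sp_complex) -
                   log_translational_partition(sp_protein) -
                   log_translational_partition(sp_ligand))
    dG_r <- -kT * (log_rotational_partition_moments(sp_complex$moments, temp) -
                   log_rotational_partition_moments(sp_protein$moments, temp) -
                   log_rotational_partition_moments(sp_ligand$moments, temp))
  } else {
    dG_t <- kT * log_translational_partition(sp_ligand)
    dG_r <- kT * log_rotational_partition_moments(sp_ligand$moments, temp)
  }
  # multiwell correction: species-level Zt, Zr cancel between the multiwell
  # and global-minimum-only binding free energies
  multi_gain <- function(wells) {
    logw <- vapply(wells, function(w)
      -w$E0 / kT + log_vibrational_partition(w, temp), 0)
    -kT * log_sum_exp(logw) - (-kT * logw[1L])
  }
  dG_all <- multi_gain(complex_wells) - multi_gain(ligand_wells)
  structure(list(
    dE = dE, dG_v = dG_v, dG_t = dG_t, dG_r = dG_r, dG_all = dG_all,
    dG_bind = dE + dG_v + dG_t + dG_r + dG_all, dG_exp = dG_exp
  ), class = "binding_breakdown")
}

#' @export
print.binding_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<binding_breakdown> dG_bind = %.2f kcal/mol ",
                     "(dE %.2f, dG_v %.2f, dG_t %.2f, dG_r %.2f, ",
                     "dG_all %.2f)\n"),
              x$dG_bind, x$dE, x$dG_v, x$dG_t, x$dG_r, x$dG_all))
  invisible(x)
}

#' Experimental binding free energy from an inhibition constant
#'
#' `dG_exp = kT ln Ki`, with Ki in mol/L.
#'
#' @param Ki Inhibition (binding) constant, mol/L; must be positive.
#' @param temperature Temperature, K (default 310).
#' @return Binding free energy, kcal/mol.
#' @export
dG_from_Ki <- function(Ki, temperature = 310) {
  if (any(Ki <= 0)) stop("Ki must be positive")
  physical_constants()$kB_kcal * temperature * log(Ki)
}
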