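# Deterministic synthetic systems with analytically known minima, and the
# packaged benchmark tables.
#
# The toy pockets are built so that the number and location of the
# interior minima of the probe-pocket energy are known by construction:
# the double-well pocket has exactly two minima, on its symmetry axis
# between the two attractive sites; the spherical cavity (an icosahedral
# shell tighter than the contact distance) pins a probe at its center.

# Lennard-Jones parameters shared by the toy pockets and the single-atom
# probe: contact minimum at 3.0 A, well depth 0.2 kcal/mol.
.pocket_sigma <- 3 / 2^(1 / 6)
.pocket_epsilon <- 0.2
.pocket_site_x <- 5          # double-well site positions (+/- site_x, 0, 0)
.cavity_radius <- 2.6        # spherical-cavity shell radius, A

#' Specify a toy system
#'
#' @param pocket_kind `"double-well"`, `"spherical-cavity"` or `"none"`.
#' @param ligand_size Number of ligand atoms.
#' @param n_torsions Number of rotatable torsions the ligand must have.
#' @param seed Integer seed (kept with the spec so every fixture is
#'   reproducible from the pair).
#' @param field_params [toy_field_params()] used with the system.
#' @return A list of class `toy_system_spec`.
#' @export
toy_system_spec <- function(pocket_kind = c("double-well",
                                            "spherical-cavity", "none"),
                            ligand_size = 1L, n_torsions = 0L, seed = 1L,
                            field_params = toy_field_params()) {
  pocket_kind <- match.arg(pocket_kind)
  stopifnot(ligand_size >= 1L, n_torsions >= 0L)
  structure(list(pocket_kind = pocket_kind,
                 ligand_size = as.integer(ligand_size),
                 n_torsions = as.integer(n_torsions),
                 seed = as.integer(seed), field_params = field_params),
            class = "toy_system_spec")
}

# 12 icosahedron vertices on the unit sphere
icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  v / sqrt(1 + phi^2)
}

#' Build a toy pocket receptor
#'
#' `"double-well"`: two attractive Lennard-Jones sites at
#' (+/-5, 0, 0) whose summed field has exactly two interior minima, on the
#' x axis near (+/-2, 0, 0) (each site's contact shell, tilted toward the
#' other site).  `"spherical-cavity"`: an icosahedral shell of radius
#' 2.6 A, inside the 3.0 A contact distance, so a probe is pressed to the
#' exact center by symmetry.  `"none"`: an empty receptor is not
#' meaningful, so this returns `NULL`.
#'
#' @param spec A [toy_system_spec()].
#' @return A [rigid_receptor()] (or `NULL` for `"none"`).
#' @export
make_toy_pocket <- function(spec) {
  stopifnot(inherits(spec, "toy_system_spec"))
  vdw <- cbind(sigma = .pocket_sigma, epsilon = .pocket_epsilon)
  switch(spec$pocket_kind,
    "double-well" = rigid_receptor(
      element = c("C", "C"),
      coords = rbind(c(-.pocket_site_x, 0, 0), c(.pocket_site_x, 0, 0)),
      source_id = "toy-double-well",
      vdw = vdw
    ),
    "spherical-cavity" = rigid_receptor(
      element = rep("C", 12L),
      coords = icosahedron_vertices() * .cavity_radius,
      source_id = "toy-spherical-cavity",
      vdw = vdw
    ),
    "none" = NULL
  )
}

#' Build a toy flexible ligand
#'
#' A carbon chain with `n_torsions + 3` heavy atoms (bond length 1.526 A,
#' bend angle 112 degrees) carrying exactly the requested number of
#' rotatable torsions; any remaining atom budget is spent on hydrogens
#' bonded to the chain ends, which add no torsions.  A single-atom spec
#' gives the Lennard-Jones probe matched to the toy pockets (contact
#' minimum 3.0 A, well depth 0.2 kcal/mol against a pocket site).
#'
#' @param spec A [toy_system_spec()].
#' @return List with `ligand` (a [flexible_ligand()]) and `conf` (its
#'   reference conformation).
#' @export
make_toy_ligand <- function(spec) {
  stopifnot(inherits(spec, "toy_system_spec"))
  n <- spec$ligand_size
  k <- spec$n_torsions
  n_heavy <- if (k > 0L) k + 3L else min(n, k + 3L)
  if (n < n_heavy)
    stop("infeasible toy ligand: ", k, " torsion(s) need at least ",
         k + 3L, " atoms")
  b <- 1.526
  half <- (112 * pi / 180) / 2
  idx <- seq_len(n_heavy) - 1L
  coords <- cbind(idx * b * sin(half), (idx %% 2L) * b * cos(half), 0)
  element <- rep("C", n_heavy)
  bonds <- if (n_heavy > 1L)
    data.frame(i = seq_len(n_heavy - 1L), j = seq_len(n_heavy - 1L) + 1L,
               order = 1L)
  else data.frame(i = integer(0), j = integer(0), order = integer(0))
  n_h <- n - n_heavy
  if (n_h > 0L) {
    if (n_heavy < 2L)
      stop("infeasible toy ligand: cannot attach hydrogens to a bare atom")
    for (h in seq_len(n_h)) {
      parent <- if (h %% 2L == 1L) 1L else n_heavy
      ang <- pi / 3 + h   # deterministic spread around the chain axis
      pos <- coords[parent, ] + 1.09 * c(0, cos(ang), sin(ang)) *
        (if (parent == 1L) 1 else -1)
      coords <- rbind(coords, pos)
      element <- c(element, "H")
      bonds <- rbind(bonds,
                     data.frame(i = parent, j = nrow(coords), order = 1L))
    }
  }
  vdw <- if (n == 1L) cbind(sigma = .pocket_sigma,
                            epsilon = .pocket_epsilon) else NULL
  lig <- flexible_ligand(element = element, coords = coords, bonds = bonds,
                         vdw = vdw)
  if (length(lig$torsions) != k)
    stop("internal error: toy ligand has ", length(lig$torsions),
         " torsions, wanted ", k)
  list(ligand = lig, conf = lig$ref_conf)
}

#' Grid-scan oracle for the double-well pocket
#'
#' By symmetry the two minima of the double-well pocket probed with a
#' single atom lie on the x axis, so an exhaustive 1-D lattice scan of
#' the on-axis energy locates them to grid precision.  This is the
#' independent reference the Monte Carlo search is checked against.
#'
#' @param receptor The double-well [rigid_receptor()].
#' @param ligand The single-atom probe [flexible_ligand()].
#' @param model An [energy_model()].
#' @param xlim Scan interval on the axis, A.
#' @param step Lattice spacing, A (default 1e-3).
#' @return Data frame with one row per grid-local minimum: `x`, `energy`.
#' @export
double_well_axis_scan <- function(receptor, ligand, model,
                                  xlim = c(-4, 4), step = 1e-3) {
  stopifnot(nrow(ligand$atoms) == 1L)
  xs <- seq(xlim[1L], xlim[2L], by = step)
  es <- vapply(xs, function(x)
    evaluate_model(model, receptor, ligand, cbind(x, 0, 0))$energy, 0)
  k <- seq(2L, length(es) - 1L)
  is_min <- k[es[k] < es[k - 1L] & es[k] < es[k + 1L]]
  data.frame(x = xs[is_min], energy = es[is_min])
}

#' Reference minima of a toy system
#'
#' The analytically known minima of a toy pocket probed with the
#' single-atom ligand: the two axial minima of the double well (located by
#' the lattice-scan oracle) or the exact center of the spherical cavity.
#'
#' @param spec A [toy_system_spec()] with `ligand_size = 1`.
#' @param model An [energy_model()] (default: toy field from the spec).
#' @param step Lattice spacing for the double-well scan, A.
#' @return Data frame with columns `x`, `y`, `z`, `energy`.
#' @export
expected_minima <- function(spec, model = toy_energy_model(spec$field_params),
                            step = 1e-3) {
  stopifnot(spec$ligand_size == 1L)
  receptor <- make_toy_pocket(spec)
  probe <- make_toy_ligand(spec)$ligand
  if (spec$pocket_kind == "double-well") {
    sc <- double_well_axis_scan(receptor, probe, model, step = step)
    data.frame(x = sc$x, y = 0, z = 0, energy = sc$energy)
  } else if (spec$pocket_kind == "spherical-cavity") {
    e <- evaluate_model(model, receptor, probe, cbind(0, 0, 0))$energy
    data.frame(x = 0, y = 0, z = 0, energy = e)
  } else {
    stop("no reference minima for pocket kind 'none'")
  }
}

# -- packaged benchmark tables ----------------------------------------------

.table_checksums <- c(
  table4_binding_components.csv = "5a5df28a418a3b0233e61033e28157b9",
  table5_binding_energies.csv = "d89a4620a8461fca9c617efeaf870794"
)

.table5_labels <- c(
  f1_mmff94 = "{1}MMFF94", f1_mmff94_pcm = "{1}MMFF94 + PCM",
  f1_pm7 = "{1}PM7", f1_pm7_cosmo = "{1}PM7 + COSMO",
  f2_mmff94 = "{2}MMFF94", f2_mmff94_pcm = "{2}MMFF94 + PCM",
  f2_mmff94_sgb = "{2}MMFF94 + SGB",
  sol_score = "SOL score", autodock_score = "Autodock score"
)

#' Load the packaged benchmark tables
#'
#' Two fixture tables transcribed from the published 16-complex benchmark:
#' the per-complex binding free energy decomposition (`table4`: `dG_exp`,
#' `dG_bind`, `dE`, `dG_v`, `dG_t`, `dG_r`, `dG_all`, kcal/mol) and the
#' per-complex calculated binding energies of seven target functions plus
#' two docking scoring functions (`table5`).  Files are checksummed to
#' guard against silent corruption.
#'
#' @return List with data frames `table4` and `table5`; `table5` carries
#'   a `"labels"` attribute mapping column names to the conventional
#'   target-function labels (e.g. `"{1}MMFF94 + PCM"`).
#' @export
load_benchmark_tables <- function() {
  dir <- system.file("extdata", package = "dockminima", mustWork = TRUE)
  out <- list()
  for (f in names(.table_checksums)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing fixture file: ", f)
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, unname(.table_checksums[[f]])))
      stop("fixture corruption: checksum mismatch for ", f)
  }
  table4 <- utils::read.csv(file.path(dir, "table4_binding_components.csv"),
                            stringsAsFactors = FALSE)
  table5 <- utils::read.csv(file.path(dir, "table5_binding_energies.csv"),
                            stringsAsFactors = FALSE)
  attr(table5, "labels") <- .table5_labels
  list(table4 = table4, table5 = table5)
}
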