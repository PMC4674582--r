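# Shared builders for the test suite: small molecules, analytic energy
# models, and hand-made minima/minima-set objects.

# n-butane with explicit hydrogens (14 atoms, 4 heavy, 1 rotatable torsion)
butane_sdf <- function() {
  path <- tempfile(fileext = ".sdf")
  writeLines(c(
    "n-butane", "  fixture", "",
    " 14 13  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0533    1.4520    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.5933    1.4520    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.3633   -0.5133    0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.3633   -0.5133   -0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.3633    1.0267    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.9033   -0.5133    0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.9033   -0.5133   -0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.6900    1.9653    0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.6900    1.9653   -0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.9567    0.9387    0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.9567    0.9387   -0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.9567    2.4787    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  1  5  1  0", "  1  6  1  0", "  1  7  1  0",
    "  2  3  1  0", "  2  8  1  0", "  2  9  1  0", "  3  4  1  0",
    "  3 10  1  0", "  3 11  1  0", "  4 12  1  0", "  4 13  1  0",
    "  4 14  1  0",
    "M  END", "$$$$"
  ), path)
  path
}

# benzene with explicit hydrogens (12 atoms, all bonds in the ring or
# terminal C-H: zero rotatable torsions)
benzene_sdf <- function() {
  path <- tempfile(fileext = ".sdf")
  ang <- (0:5) * pi / 3
  cc <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  hh <- cbind(2.47 * cos(ang), 2.47 * sin(ang), 0)
  atoms <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    c(cc[, 1], hh[, 1]), c(cc[, 2], hh[, 2]), c(cc[, 3], hh[, 3]),
    c(rep("C", 6), rep("H", 6))
  )
  ring <- cbind(1:6, c(2:6, 1), rep(c(2L, 1L), 3))
  ch <- cbind(1:6, 7:12, 1L)
  bonds <- sprintf("%3d%3d%3d  0", rbind(ring, ch)[, 1],
                   rbind(ring, ch)[, 2], rbind(ring, ch)[, 3])
  writeLines(c("benzene", "  fixture", "",
               " 12 12  0  0  0  0  0  0  0  0999 V2000",
               atoms, bonds, "M  END", "$$$$"), path)
  path
}

# ethane: both rotors carry hydrogens only -> no rotatable torsion
ethane_ligand <- function() {
  coords <- rbind(
    c(0, 0, 0), c(1.54, 0, 0),
    c(-0.36, 1.03, 0), c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89),
    c(1.90, -1.03, 0), c(1.90, 0.51, 0.89), c(1.90, 0.51, -0.89)
  )
  flexible_ligand(
    element = c("C", "C", rep("H", 6)),
    coords = coords,
    bonds = data.frame(i = c(1, 1, 1, 1, 2, 2, 2),
                       j = c(2, 3, 4, 5, 6, 7, 8), order = 1L)
  )
}

cyclohexane_ligand <- function() {
  ang <- (0:5) * pi / 3
  flexible_ligand(
    element = rep("C", 6),
    coords = cbind(1.54 * cos(ang), 1.54 * sin(ang), c(0.25, -0.25)),
    bonds = data.frame(i = 1:6, j = c(2:6, 1), order = 1L)
  )
}

# single-atom probe ligand (heavy) for set/metric tests
probe_ligand <- function() {
  make_toy_ligand(toy_system_spec("none", ligand_size = 1))$ligand
}

# hand-made local minimum: single-atom pose at (x, y, z)
mk_min <- function(x, energy, y = 0, z = 0) {
  structure(list(conf = as_conformation(c(x, y, z)), energy = energy,
                 n_optimizer_steps = 0L, origin_trial_index = NA_integer_),
            class = "local_minimum")
}

# minima set filled from (position, energy) pairs, inserted in given order
mk_set <- function(xs, energies, ligand = probe_ligand(),
                   capacity = 1024L, dedup_rmsd = 0.1) {
  set <- minima_set(capacity = capacity, dedup_rmsd = dedup_rmsd)
  for (k in seq_along(xs))
    set <- minima_set_insert(set, mk_min(xs[k], energies[k]), ligand)$set
  set
}

# isotropic quadratic well: E = k/2 * ||conf - target||^2
quadratic_model <- function(target, k = 1, name = "quadratic") {
  force(target); force(k)
  energy_model(name, function(receptor, ligand, conf) {
    d <- conf - target
    list(energy = 0.5 * k * sum(d * d), gradient = k * d)
  })
}

# 1-D double well on the x coordinate of a single atom:
# E = a (x^2 - b^2)^2 + tilt * x  (+ stiff restraints on y, z)
double_well_1d_model <- function(a = 1, b = 1, tilt = 0.1, kyz = 50) {
  energy_model("double-well-1d", function(receptor, ligand, conf) {
    x <- conf[1, 1]; y <- conf[1, 2]; z <- conf[1, 3]
    list(
      energy = a * (x^2 - b^2)^2 + tilt * x + 0.5 * kyz * (y^2 + z^2),
      gradient = cbind(4 * a * x * (x^2 - b^2) + tilt, kyz * y, kyz * z)
    )
  })
}

# absolute-difference comparison (printed-value checks)
expect_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}

default_cfg <- function(...) {
  search_config(sphere_center = c(0, 0, 0), sphere_radius = 10, ...)
}
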