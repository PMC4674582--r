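# Energy-model contract, the built-in toy force field, and rescoring /
# reoptimization of minima sets under alternate models.
#
# A docking target function here is any callable honouring the contract
# (receptor, ligand, conformation) -> (energy kcal/mol, gradient
# kcal/mol/A over ligand Cartesian coordinates).  Production target
# functions (MMFF94, PM7, implicit-solvent rescorers) plug in through this
# contract; the shipped toy field exists so the search, metrics and
# thermodynamics are fully testable on systems with known minima.

#' Define an energy model
#'
#' @param name Model label, used as the provenance tag of minima sets
#'   produced or rescored under this model (e.g. `"toy"`,
#'   `"mmff94-adapter"`).
#' @param evaluate Function `(receptor, ligand, conf)` returning a list
#'   with `energy` (scalar, kcal/mol) and `gradient` (n x 3 matrix,
#'   kcal/mol/A, over ligand atoms).  Must be pure: identical inputs give
#'   identical outputs.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(name, evaluate) {
  stopifnot(is.character(name), length(name) == 1L, is.function(evaluate))
  structure(list(name = name, evaluate = evaluate), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model>", x$name, "\n")
  invisible(x)
}

#' Evaluate an energy model
#'
#' @param model An [energy_model()].
#' @param receptor A [rigid_receptor()] or `NULL` for a free ligand.
#' @param ligand A [flexible_ligand()].
#' @param conf Conformation of the ligand.
#' @return List with `energy` and `gradient`.
#' @export
evaluate_model <- function(model, receptor, ligand, conf) {
  conf <- as_conformation(conf, n_atoms = nrow(ligand$atoms))
  out <- model$evaluate(receptor, ligand, conf)
  if (!is.finite(out$energy)) stop("model '", model$name,
                                   "' returned non-finite energy")
  out$gradient <- matrix(out$gradient, ncol = 3L)
  out
}

# -- model registry ----------------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Register / retrieve energy models by name
#'
#' Adapters for external target functions are discovered through a simple
#' named registry.  The name `"toy"` is always available and resolves to
#' the built-in toy field with default parameters.
#'
#' @param name Model name.
#' @param model An [energy_model()].
#' @return `get_energy_model` returns the registered [energy_model()].
#' @export
register_energy_model <- function(name, model) {
  stopifnot(inherits(model, "energy_model"))
  assign(name, model, envir = .model_registry)
  invisible(model)
}

#' @rdname register_energy_model
#' @export
get_energy_model <- function(name) {
  if (exists(name, envir = .model_registry, inherits = FALSE))
    return(get(name, envir = .model_registry, inherits = FALSE))
  if (name == "toy") {
    m <- toy_energy_model()
    register_energy_model("toy", m)
    return(m)
  }
  stop("no energy model registered under name '", name, "'")
}

# -- toy force field ---------------------------------------------------------

#' Parameters of the built-in toy force field
#'
#' Harmonic bonds and angles, a cosine torsion series, and Lennard-Jones
#' plus Coulomb nonbonded terms.  Bond and angle rest values default to the
#' ligand's reference conformation, so any loaded ligand starts near its own
#' intramolecular minimum.  1-2 and 1-3 ligand pairs are excluded from the
#' nonbonded sum; 1-4 pairs enter at full weight.
#'
#' @param bond_k Bond force constant, kcal/mol/A^2 (energy `k/2 (r-r0)^2`).
#' @param angle_k Angle force constant, kcal/mol/rad^2.
#' @param torsion_series Cosine coefficients `c_m`, kcal/mol; each rotatable
#'   torsion contributes `sum_m c_m (1 + cos(m * phi))`.
#' @param dielectric Relative dielectric for the Coulomb term.
#' @param cutoff Optional nonbonded distance cutoff, A (default none).
#' @return A list of class `toy_field_params`.
#' @export
toy_field_params <- function(bond_k = 300, angle_k = 60,
                             torsion_series = c(0, 0, 0.3),
                             dielectric = 1, cutoff = NULL) {
  stopifnot(bond_k > 0, angle_k > 0, dielectric > 0)
  structure(list(bond_k = bond_k, angle_k = angle_k,
                 torsion_series = torsion_series,
                 dielectric = dielectric, cutoff = cutoff),
            class = "toy_field_params")
}

#' The built-in toy energy model
#'
#' @param params A [toy_field_params()].
#' @return An [energy_model()] named `"toy"`.
#' @export
toy_energy_model <- function(params = toy_field_params()) {
  force(params)
  energy_model("toy", function(receptor, ligand, conf) {
    toy_energy_gradient(receptor, ligand, conf, params)
  })
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Toy-field energy and analytic gradient
#'
#' @param receptor A [rigid_receptor()] or `NULL` (free ligand).
#' @param ligand A [flexible_ligand()].
#' @param conf Ligand conformation, n x 3 A.
#' @param params A [toy_field_params()].
#' @return List with `energy` (kcal/mol) and `gradient` (n x 3 matrix of
#'   derivatives with respect to the ligand Cartesian coordinates,
#'   kcal/mol/A).  Receptor atoms are fixed and carry no gradient.
#' @export
toy_energy_gradient <- function(receptor, ligand, conf,
                                params = toy_field_params()) {
  conf <- as_conformation(conf, n_atoms = nrow(ligand$atoms))
  n <- nrow(conf)
  energy <- 0
  grad <- matrix(0, n, 3L)
  ref <- ligand$ref_conf

  # bonds: k/2 (r - r0)^2, rest length from the reference conformation
  if (nrow(ligand$bonds) > 0L) {
    bi <- ligand$bonds$i; bj <- ligand$bonds$j
    d <- conf[bi, , drop = FALSE] - conf[bj, , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    if (any(r < 1e-6)) stop("singular geometry: coincident bonded atoms")
    d0 <- ref[bi, , drop = FALSE] - ref[bj, , drop = FALSE]
    r0 <- sqrt(rowSums(d0 * d0))
    energy <- energy + sum(0.5 * params$bond_k * (r - r0)^2)
    f <- params$bond_k * (r - r0) / r     # dE/dr / r
    gvec <- d * f
    for (k in seq_along(bi)) {
      grad[bi[k], ] <- grad[bi[k], ] + gvec[k, ]
      grad[bj[k], ] <- grad[bj[k], ] - gvec[k, ]
    }
  }

  # angles: k/2 (theta - theta0)^2, rest angle from the reference
  if (nrow(ligand$angles) > 0L) {
    for (a in seq_len(nrow(ligand$angles))) {
      i <- ligand$angles[a, "i"]; j <- ligand$angles[a, "j"]
      k <- ligand$angles[a, "k"]
      th <- bend_angle(conf[i, ], conf[j, ], conf[k, ])
      th0 <- bend_angle(ref[i, ], ref[j, ], ref[k, ])
      dth <- th$theta - th0$theta
      energy <- energy + 0.5 * params$angle_k * dth^2
      coef <- params$angle_k * dth
      grad[i, ] <- grad[i, ] + coef * th$d_i
      grad[j, ] <- grad[j, ] + coef * th$d_j
      grad[k, ] <- grad[k, ] + coef * th$d_k
    }
  }

  # torsion cosine series over the rotatable torsions
  cs <- params$torsion_series
  if (length(ligand$torsions) > 0L && any(cs != 0)) {
    mm <- seq_along(cs)
    for (tor in ligand$torsions) {
      q <- tor$quad
      dh <- dihedral_angle(conf[q[1L], ], conf[q[2L], ],
                           conf[q[3L], ], conf[q[4L], ])
      energy <- energy + sum(cs * (1 + cos(mm * dh$phi)))
      dVdphi <- -sum(cs * mm * sin(mm * dh$phi))
      grad[q[1L], ] <- grad[q[1L], ] + dVdphi * dh$d1
      grad[q[2L], ] <- grad[q[2L], ] + dVdphi * dh$d2
      grad[q[3L], ] <- grad[q[3L], ] + dVdphi * dh$d3
      grad[q[4L], ] <- grad[q[4L], ] + dVdphi * dh$d4
    }
  }

  # nonbonded, ligand-ligand (1-2/1-3 excluded)
  lj_sigma <- ligand$atoms$vdw_sigma
  lj_eps <- ligand$atoms$vdw_epsilon
  qs <- ligand$atoms$partial_charge
  kel <- physical_constants()$coulomb_kcal / params$dielectric
  pr <- ligand$nonbonded_pairs
  if (nrow(pr) > 0L) {
    i <- pr[, 1L]; j <- pr[, 2L]
    d <- conf[i, , drop = FALSE] - conf[j, , drop = FALSE]
    r2 <- rowSums(d * d)
    if (any(r2 < 1e-12)) stop("singular geometry: coincident atoms")
    r <- sqrt(r2)
    sig <- (lj_sigma[i] + lj_sigma[j]) / 2
    eps <- sqrt(lj_eps[i] * lj_eps[j])
    qq <- kel * qs[i] * qs[j]
    keep <- if (is.null(params$cutoff)) rep(TRUE, length(r)) else r <= params$cutoff
    if (any(keep)) {
      s6 <- (sig[keep] / r[keep])^6
      e_lj <- 4 * eps[keep] * (s6 * s6 - s6)
      e_q <- qq[keep] / r[keep]
      energy <- energy + sum(e_lj) + sum(e_q)
      # dE/dr
      dEdr <- (-24 * eps[keep] * (2 * s6 * s6 - s6) - e_q) / r[keep]
      gvec <- d[keep, , drop = FALSE] * (dEdr / r[keep])
      ik <- i[keep]; jk <- j[keep]
      for (k in seq_along(ik)) {
        grad[ik[k], ] <- grad[ik[k], ] + gvec[k, ]
        grad[jk[k], ] <- grad[jk[k], ] - gvec[k, ]
      }
    }
  }

  # nonbonded, receptor-ligand
  if (!is.null(receptor) && nrow(receptor$atoms) > 0L) {
    rc <- receptor$coords
    rsig <- receptor$atoms$vdw_sigma
    reps <- receptor$atoms$vdw_epsilon
    rq <- receptor$atoms$partial_charge
    for (a in seq_len(n)) {
      d <- matrix(conf[a, ], nrow(rc), 3L, byrow = TRUE) - rc
      r2 <- rowSums(d * d)
      if (any(r2 < 1e-12)) stop("singular geometry: coincident atoms")
      r <- sqrt(r2)
      keep <- if (is.null(params$cutoff)) rep(TRUE, length(r)) else r <= params$cutoff
      if (!any(keep)) next
      sig <- (rsig[keep] + lj_sigma[a]) / 2
      eps <- sqrt(reps[keep] * lj_eps[a])
      qq <- kel * rq[keep] * qs[a]
      s6 <- (sig / r[keep])^6
      e_lj <- 4 * eps * (s6 * s6 - s6)
      e_q <- qq / r[keep]
      energy <- energy + sum(e_lj) + sum(e_q)
      dEdr <- (-24 * eps * (2 * s6 * s6 - s6) - e_q) / r[keep]
      grad[a, ] <- grad[a, ] + colSums(d[keep, , drop = FALSE] * (dEdr / r[keep]))
    }
  }

  list(energy = energy, gradient = grad)
}

# bend angle theta at j and its gradient with respect to the three atoms
bend_angle <- function(ri, rj, rk) {
  u <- ri - rj; v <- rk - rj
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  cth <- sum(u * v) / (nu * nv)
  cth <- max(-1, min(1, cth))
  theta <- acos(cth)
  sth <- sqrt(max(1 - cth * cth, 1e-12))
  d_i <- -(v / nv - cth * u / nu) / (nu * sth)
  d_k <- -(u / nu - cth * v / nv) / (nv * sth)
  list(theta = theta, d_i = d_i, d_k = d_k, d_j = -(d_i + d_k))
}

# dihedral phi for atoms 1-2-3-4 and its gradient (standard MD formulation)
dihedral_angle <- function(r1, r2, r3, r4) {
  b1 <- r2 - r1; b2 <- r3 - r2; b3 <- r4 - r3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2 * b2))
  phi <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
  n1sq <- sum(n1 * n1); n2sq <- sum(n2 * n2)
  if (n1sq < 1e-12 || n2sq < 1e-12)
    stop("degenerate dihedral (collinear atoms)")
  d1 <- -nb2 / n1sq * n1
  d4 <- nb2 / n2sq * n2
  c12 <- sum(b1 * b2) / (nb2 * nb2)
  c32 <- sum(b3 * b2) / (nb2 * nb2)
  d2 <- -(1 + c12) * d1 + c32 * d4
  d3 <- c12 * d1 - (1 + c32) * d4
  list(phi = phi, d1 = d1, d2 = d2, d3 = d3, d4 = d4)
}

# -- rescoring / reoptimization ---------------------------------------------

#' Rescore a minima set under another energy model
#'
#' Geometries are untouched: every member's energy is recomputed with the
#' new model at the same pose (single-point evaluation), the set is
#' re-sorted ascending, and the model tag of the new model is recorded.
#' This is the "same geometries, new target function" operation used to
#' turn an in-vacuo minima spectrum into an implicit-solvent one.
#'
#' @param set A [minima_set()].
#' @param model The rescoring [energy_model()].
#' @param receptor,ligand The structures the set was computed on.
#' @return The rescored [minima_set()]; members on which the model failed
#'   are dropped from the ranking and returned in the `"flagged"` attribute,
#'   with their count in attribute `"n_failed"`.
#' @export
rescore_set <- function(set, model, receptor, ligand) {
  stopifnot(inherits(set, "minima_set"))
  out <- set
  out$members <- list()
  out$model_tag <- model$name
  flagged <- list()
  for (m in set$members) {
    e <- tryCatch(evaluate_model(model, receptor, ligand, m$conf)$energy,
                  error = function(err) NA_real_)
    if (is.na(e)) {
      flagged[[length(flagged) + 1L]] <- m
    } else {
      m$energy <- e
      out$members[[length(out$members) + 1L]] <- m
    }
  }
  out$members <- out$members[order(vapply(out$members, `[[`, 0, "energy"))]
  attr(out, "flagged") <- flagged
  attr(out, "n_failed") <- length(flagged)
  out
}

#' Reoptimize a minima set under another energy model
#'
#' Each member is locally minimized under the new model starting from its
#' current geometry (the "local reoptimization" pattern used to carry a
#' minima spectrum from one target function to a related one), after which
#' the RMSD deduplication rule is re-applied: members that relax into the
#' same basin of the new model collapse to one.
#'
#' @param set A [minima_set()].
#' @param model The new [energy_model()].
#' @param receptor,ligand The structures.
#' @param grad_tol Convergence tolerance, max gradient component,
#'   kcal/mol/A.
#' @param max_iter Optimizer iteration cap.
#' @return A new [minima_set()] under the new model.  Attribute
#'   `"displacement"` holds each input member's heavy-atom RMSD between its
#'   old and reoptimized geometry; members whose optimization failed are
#'   retained unoptimized (rescored only) with a warning and listed in
#'   attribute `"failed_members"`.
#' @export
reoptimize_set <- function(set, model, receptor, ligand,
                           grad_tol = 1e-5, max_iter = 10000) {
  stopifnot(inherits(set, "minima_set"))
  cfg <- search_config(seed = 1L, grad_tol = grad_tol, max_iter = max_iter,
                       capacity = set$capacity, dedup_rmsd = set$dedup_rmsd)
  out <- minima_set(capacity = set$capacity, dedup_rmsd = set$dedup_rmsd,
                    model_tag = model$name)
  displacement <- numeric(length(set$members))
  failed <- integer(0)
  for (k in seq_along(set$members)) {
    m <- set$members[[k]]
    res <- local_minimize(model, receptor, ligand, m$conf, cfg)
    if (inherits(res, "minimize_failure")) {
      failed <- c(failed, k)
      res <- m
      res$energy <- tryCatch(
        evaluate_model(model, receptor, ligand, m$conf)$energy,
        error = function(e) m$energy
      )
    }
    displacement[k] <- heavy_atom_rmsd(m$conf, res$conf, ligand$heavy_indices)
    res$origin_trial_index <- m$origin_trial_index
    out <- minima_set_insert(out, res, ligand)$set
  }
  if (length(failed) > 0L)
    warning(length(failed), " member(s) failed to reoptimize; ",
            "retained at their previous geometry")
  attr(out, "displacement") <- displacement
  attr(out, "failed_members") <- failed
  out
}
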