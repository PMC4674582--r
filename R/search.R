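# The minima-search core: random trial poses, clash filtering, local
# L-BFGS minimization, and maintenance of the capacity-bounded,
# RMSD-deduplicated low-energy minima set.

#' Search configuration
#'
#' @param sphere_center Center of the spherical search area, A.  `NULL`
#'   (default) means "use the geometric center of the native pose", set at
#'   search time.
#' @param sphere_radius Radius of the search sphere, A (default 8).
#' @param clash_cutoff Minimum allowed atom-atom separation for a trial
#'   pose, A (default 0.5); a pair exactly at the cutoff is rejected.
#' @param grad_tol Optimizer convergence criterion: maximum gradient
#'   component, kcal/mol/A (default 1e-5).
#' @param capacity Maximum number of stored minima (default 1024).
#' @param dedup_rmsd Two minima are distinct only if their heavy-atom RMSD
#'   exceeds this value, A (default 0.1).
#' @param seed Integer seed for the trial-pose stream.
#' @param max_test_optimizations Number of Monte Carlo trials to run.
#' @param time_budget Optional wall-clock halt, seconds (default off;
#'   `max_test_optimizations` is the reproducible stop).
#' @param worker_count Number of logical workers (contract only: results
#'   are defined to equal the serial reference ordering).
#' @param max_iter Optimizer iteration cap per local minimization.
#' @return A validated list of class `search_config`.
#' @export
search_config <- function(sphere_center = NULL, sphere_radius = 8,
                          clash_cutoff = 0.5, grad_tol = 1e-5,
                          capacity = 1024, dedup_rmsd = 0.1, seed = 1L,
                          max_test_optimizations = 1000L,
                          time_budget = NULL, worker_count = 1L,
                          max_iter = 10000L) {
  stopifnot(sphere_radius > 0, capacity >= 1, dedup_rmsd > 0, grad_tol > 0,
            clash_cutoff > 0, max_iter >= 1, worker_count >= 1)
  if (!is.null(sphere_center)) {
    sphere_center <- as.numeric(sphere_center)
    stopifnot(length(sphere_center) == 3L, all(is.finite(sphere_center)))
  }
  structure(list(
    sphere_center = sphere_center, sphere_radius = sphere_radius,
    clash_cutoff = clash_cutoff, grad_tol = grad_tol,
    capacity = as.integer(capacity), dedup_rmsd = dedup_rmsd,
    seed = as.integer(seed),
    max_test_optimizations = as.integer(max_test_optimizations),
    time_budget = time_budget, worker_count = as.integer(worker_count),
    max_iter = as.integer(max_iter)
  ), class = "search_config")
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis * axis))
  c_ <- cos(angle); s <- sin(angle); t <- 1 - c_
  matrix(c(
    t * a[1]^2 + c_,        t * a[1] * a[2] - s * a[3], t * a[1] * a[3] + s * a[2],
    t * a[1] * a[2] + s * a[3], t * a[2]^2 + c_,        t * a[2] * a[3] - s * a[1],
    t * a[1] * a[3] - s * a[2], t * a[2] * a[3] + s * a[1], t * a[3]^2 + c_
  ), 3L, 3L, byrow = TRUE)
}

# rotate the atoms in `idx` about the line through p1 -> p2 by `angle`
rotate_about_bond <- function(conf, idx, p1, p2, angle) {
  R <- rotation_matrix(p2 - p1, angle)
  shifted <- sweep(conf[idx, , drop = FALSE], 2L, p1)
  conf[idx, ] <- shifted %*% t(R) + matrix(p1, length(idx), 3L, byrow = TRUE)
  conf
}

#' Generate a random trial pose
#'
#' The deformation is applied in a fixed order: (i) the ligand geometric
#' center is moved to a point drawn uniformly from the search sphere;
#' (ii) the whole ligand is rotated about a random axis through its center
#' by an angle uniform in \[-pi, pi\]; (iii) each rotatable torsion is
#' turned by an independent angle uniform in \[-pi, pi\].  Bond lengths and
#' bend angles are untouched, and the pose is not re-centered after the
#' torsion moves.  Randomness comes from R's global RNG stream; seed it
#' (as [run_search()] does) for reproducibility.
#'
#' @param ligand A [flexible_ligand()].
#' @param ref_conf Reference conformation to deform.
#' @param cfg A [search_config()]; `sphere_center` must be set.
#' @return A new conformation.
#' @export
random_trial_pose <- function(ligand, ref_conf, cfg) {
  ref_conf <- as_conformation(ref_conf, n_atoms = nrow(ligand$atoms))
  center <- cfg$sphere_center
  if (is.null(center))
    stop("cfg$sphere_center must be set before pose generation")
  # (i) uniform point in the sphere
  dir <- stats::rnorm(3L)
  dir <- dir / sqrt(sum(dir * dir))
  radius <- cfg$sphere_radius * stats::runif(1L)^(1 / 3)
  target <- center + radius * dir
  conf <- sweep(ref_conf, 2L, geometric_center(ref_conf) - target)
  # (ii) whole-body rotation about a random axis through the center
  if (nrow(conf) > 1L) {
    axis <- stats::rnorm(3L)
    angle <- stats::runif(1L, -pi, pi)
    conf <- rotate_about_bond(conf, seq_len(nrow(conf)),
                              target, target + axis, angle)
  }
  # (iii) independent torsion rotations
  for (tor in ligand$torsions) {
    angle <- stats::runif(1L, -pi, pi)
    conf <- rotate_about_bond(conf, tor$rotating_set,
                              conf[tor$axis[1L], ], conf[tor$axis[2L], ],
                              angle)
  }
  conf
}

#' Clash filter for trial poses
#'
#' A pose passes only if every ligand-ligand pair (1-2 and 1-3 bonded
#' pairs exempt) and every receptor-ligand pair is separated by more than
#' `cutoff`; a pair exactly at the cutoff rejects.
#'
#' @param receptor A [rigid_receptor()] or `NULL`.
#' @param ligand A [flexible_ligand()].
#' @param conf The trial conformation.
#' @param cutoff Separation cutoff, A.
#' @return `TRUE` if the pose is accepted.
#' @export
clash_filter <- function(receptor, ligand, conf, cutoff = 0.5) {
  stopifnot(cutoff > 0)
  conf <- as_conformation(conf, n_atoms = nrow(ligand$atoms))
  pr <- ligand$nonbonded_pairs
  if (nrow(pr) > 0L) {
    d <- conf[pr[, 1L], , drop = FALSE] - conf[pr[, 2L], , drop = FALSE]
    if (min(rowSums(d * d)) <= cutoff^2) return(FALSE)
  }
  if (!is.null(receptor) && nrow(receptor$atoms) > 0L) {
    rc <- receptor$coords
    for (a in seq_len(nrow(conf))) {
      d <- matrix(conf[a, ], nrow(rc), 3L, byrow = TRUE) - rc
      if (min(rowSums(d * d)) <= cutoff^2) return(FALSE)
    }
  }
  TRUE
}

#' Local minimization of a pose
#'
#' All ligand Cartesian coordinates are free; minimization uses L-BFGS-B
#' (unbounded) and converges when the maximum gradient component drops to
#' `cfg$grad_tol`.  The optimizer is restarted from its end point until the
#' analytic gradient criterion is met or the iteration budget is spent.
#'
#' @param model An [energy_model()].
#' @param receptor,ligand The structures.
#' @param start Starting conformation (should pass [clash_filter()]).
#' @param cfg A [search_config()].
#' @return An object of class `local_minimum` (fields `conf`, `energy`,
#'   `n_optimizer_steps`, `origin_trial_index`) or of class
#'   `minimize_failure` with a `reason` field.
#' @export
local_minimize <- function(model, receptor, ligand, start, cfg) {
  start <- as_conformation(start, n_atoms = nrow(ligand$atoms))
  fn <- function(x) {
    evaluate_model(model, receptor, ligand,
                   matrix(x, ncol = 3L))$energy
  }
  gr <- function(x) {
    as.numeric(evaluate_model(model, receptor, ligand,
                              matrix(x, ncol = 3L))$gradient)
  }
  failure <- function(reason) structure(list(reason = reason),
                                        class = "minimize_failure")
  par <- as.numeric(start)
  total_steps <- 0L
  budget <- cfg$max_iter
  for (attempt in seq_len(20L)) {
    fit <- tryCatch(
      stats::optim(par, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = min(budget, 2000L),
                                  pgtol = cfg$grad_tol, factr = 1)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(failure("optimizer error"))
    total_steps <- total_steps + fit$counts[[1L]]
    budget <- budget - fit$counts[[1L]]
    par <- fit$par
    g <- tryCatch(gr(par), error = function(e) NULL)
    if (is.null(g) || !all(is.finite(g)) || !is.finite(fit$value))
      return(failure("non-finite energy or gradient"))
    if (max(abs(g)) <= cfg$grad_tol) {
      return(structure(list(
        conf = matrix(par, ncol = 3L,
                      dimnames = list(NULL, c("x", "y", "z"))),
        energy = fit$value,
        n_optimizer_steps = total_steps,
        origin_trial_index = NA_integer_
      ), class = "local_minimum"))
    }
    if (budget <= 0L) break
  }
  failure("iteration cap reached")
}

#' Create an empty minima set
#'
#' The capacity-bounded, energy-sorted, RMSD-deduplicated collection of
#' local minima maintained during the search.
#'
#' @param capacity Maximum number of members.
#' @param dedup_rmsd Distinctness threshold, heavy-atom RMSD, A.
#' @param model_tag Provenance label naming the target function the
#'   energies belong to.
#' @return An object of class `minima_set`.
#' @export
minima_set <- function(capacity = 1024L, dedup_rmsd = 0.1,
                       model_tag = "toy") {
  stopifnot(capacity >= 1, dedup_rmsd > 0)
  structure(list(members = list(), capacity = as.integer(capacity),
                 dedup_rmsd = dedup_rmsd, model_tag = model_tag),
            class = "minima_set")
}

#' @export
print.minima_set <- function(x, ...) {
  cat("<minima_set> [", x$model_tag, "] ", length(x$members), "/",
      x$capacity, " minima", sep = "")
  if (length(x$members) > 0L)
    cat("; E in [", format(x$members[[1L]]$energy, digits = 6), ", ",
        format(x$members[[length(x$members)]]$energy, digits = 6),
        "] kcal/mol", sep = "")
  cat("\n")
  invisible(x)
}

#' Member energies of a minima set
#' @param set A [minima_set()].
#' @return Numeric vector of energies, ascending.
#' @export
set_energies <- function(set) {
  vapply(set$members, `[[`, 0, "energy")
}

#' Insert a local minimum into a minima set
#'
#' Insertion rules: a minimum whose geometric center lies outside the
#' search sphere is rejected; a minimum within `dedup_rmsd` heavy-atom RMSD
#' (identity atom mapping, no superposition) of any stored member is a
#' duplicate and rejected; at capacity, a minimum no better than the
#' current worst is rejected, otherwise it is inserted and the
#' highest-energy member is evicted.  Sorted ascending order is maintained,
#' ties broken by insertion order.
#'
#' @param set A [minima_set()].
#' @param m A `local_minimum`.
#' @param ligand The [flexible_ligand()] (for heavy-atom indices).
#' @param sphere_center,sphere_radius Optional search-sphere check applied
#'   to the minimum's geometric center.
#' @return List with the updated `set`, logical `accepted`, and a `reason`
#'   string (`"inserted"`, `"out_of_sphere"`, `"duplicate"`,
#'   `"capacity"`).
#' @export
minima_set_insert <- function(set, m, ligand, sphere_center = NULL,
                              sphere_radius = NULL) {
  stopifnot(inherits(set, "minima_set"), inherits(m, "local_minimum"))
  if (!is.null(sphere_center) && !is.null(sphere_radius)) {
    ctr <- geometric_center(m$conf)
    if (sqrt(sum((ctr - sphere_center)^2)) > sphere_radius)
      return(list(set = set, accepted = FALSE, reason = "out_of_sphere"))
  }
  energies <- set_energies(set)
  n <- length(energies)
  # cheap capacity cut first: a candidate no better than the current worst
  # of a full set can never enter, duplicate or not
  if (n >= set$capacity && m$energy >= energies[n])
    return(list(set = set, accepted = FALSE, reason = "capacity"))
  hv <- ligand$heavy_indices
  for (other in set$members) {
    if (rmsd_fast(m$conf, other$conf, hv) <= set$dedup_rmsd)
      return(list(set = set, accepted = FALSE, reason = "duplicate"))
  }
  pos <- sum(energies <= m$energy)   # stable: ties rank after incumbents
  set$members <- append(set$members, list(m), after = pos)
  if (length(set$members) > set$capacity)
    set$members <- set$members[seq_len(set$capacity)]
  list(set = set, accepted = TRUE, reason = "inserted")
}

#' Run the Monte Carlo minima search
#'
#' The search loop: draw a random trial pose in the search sphere, discard
#' clashing poses, locally minimize the survivors, and offer each minimum
#' to the capacity-bounded minima set.  The sphere center defaults to the
#' geometric center of the native pose.  With the same seed and
#' configuration the result is identical.
#'
#' @param receptor A [rigid_receptor()].
#' @param ligand A [flexible_ligand()].
#' @param native_conf The native (crystal) ligand pose; used as the
#'   deformation reference and default sphere center.
#' @param model An [energy_model()].
#' @param cfg A [search_config()].
#' @return A list with `set` (a [minima_set()]) and `diagnostics` (class
#'   `search_diagnostics`: trial counters, the update-event trial indices
#'   and the trial index of the last global-minimum change).
#' @export
run_search <- function(receptor, ligand, native_conf, model, cfg) {
  stopifnot(inherits(cfg, "search_config"))
  native_conf <- as_conformation(native_conf, n_atoms = nrow(ligand$atoms))
  if (is.null(cfg$sphere_center))
    cfg$sphere_center <- geometric_center(native_conf)
  set.seed(cfg$seed)
  set <- minima_set(capacity = cfg$capacity, dedup_rmsd = cfg$dedup_rmsd,
                    model_tag = model$name)
  diag <- list(
    n_test_optimizations = 0L, n_clash_rejected = 0L,
    n_out_of_sphere_rejected = 0L, n_optimizer_failures = 0L,
    n_duplicate_rejected = 0L, n_capacity_rejected = 0L,
    n_inserted = 0L,
    update_events = integer(0), last_global_update = NA_integer_
  )
  t0 <- proc.time()[["elapsed"]]
  for (trial in seq_len(cfg$max_test_optimizations)) {
    if (!is.null(cfg$time_budget) &&
        proc.time()[["elapsed"]] - t0 > cfg$time_budget) break
    diag$n_test_optimizations <- diag$n_test_optimizations + 1L
    pose <- random_trial_pose(ligand, native_conf, cfg)
    if (!clash_filter(receptor, ligand, pose, cfg$clash_cutoff)) {
      diag$n_clash_rejected <- diag$n_clash_rejected + 1L
      next
    }
    m <- local_minimize(model, receptor, ligand, pose, cfg)
    if (inherits(m, "minimize_failure")) {
      diag$n_optimizer_failures <- diag$n_optimizer_failures + 1L
      next
    }
    m$origin_trial_index <- trial
    best_before <- if (length(set$members) > 0L) set$members[[1L]]$energy else Inf
    res <- minima_set_insert(set, m, ligand,
                             sphere_center = cfg$sphere_center,
                             sphere_radius = cfg$sphere_radius)
    set <- res$set
    if (res$accepted) {
      diag$n_inserted <- diag$n_inserted + 1L
      diag$update_events <- c(diag$update_events, trial)
      if (set$members[[1L]]$energy < best_before)
        diag$last_global_update <- trial
    } else {
      field <- switch(res$reason,
                      out_of_sphere = "n_out_of_sphere_rejected",
                      duplicate = "n_duplicate_rejected",
                      capacity = "n_capacity_rejected")
      diag[[field]] <- diag[[field]] + 1L
    }
  }
  if (length(set$members) == 0L)
    warning("search produced an empty minima set")
  class(diag) <- "search_diagnostics"
  list(set = set, diagnostics = diag)
}

#' @export
print.search_diagnostics <- function(x, ...) {
  cat("<search_diagnostics> ", x$n_test_optimizations, " trials: ",
      x$n_inserted, " inserted, ", x$n_clash_rejected, " clash-rejected, ",
      x$n_optimizer_failures, " optimizer failures, ",
      x$n_out_of_sphere_rejected, " out-of-sphere, ",
      x$n_duplicate_rejected, " duplicates, ",
      x$n_capacity_rejected, " below capacity cut\n", sep = "")
  invisible(x)
}
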