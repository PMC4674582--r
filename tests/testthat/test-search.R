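# Trial-pose generation, clash filtering, local minimization and the
# minima-set bookkeeping.

test_that("trial poses are deterministic under a fixed seed", {
  lig <- make_toy_ligand(toy_system_spec("none", 5, 2))$ligand
  cfg <- default_cfg(seed = 7)
  set.seed(7); a <- random_trial_pose(lig, lig$ref_conf, cfg)
  set.seed(7); b <- random_trial_pose(lig, lig$ref_conf, cfg)
  expect_identical(a, b)
})

test_that("trial-pose centers stay in the sphere and bond geometry is preserved", {
  cfg <- search_config(sphere_center = c(1, -2, 3), sphere_radius = 8)
  # rigid ligand: steps (i) and (ii) leave the center exactly where drawn
  rigid <- make_toy_ligand(toy_system_spec("none", 3))$ligand
  set.seed(10)
  for (k in 1:50) {
    pose <- random_trial_pose(rigid, rigid$ref_conf, cfg)
    expect_lte(sqrt(sum((geometric_center(pose) - cfg$sphere_center)^2)),
               cfg$sphere_radius)
  }
  # flexible ligand: torsion turns (deliberately not re-centered) shift
  # the centroid by at most the ligand radius; bonds stay rigid
  lig <- make_toy_ligand(toy_system_spec("none", 6, 3))$ligand
  blen <- function(conf) {
    d <- conf[lig$bonds$i, , drop = FALSE] - conf[lig$bonds$j, , drop = FALSE]
    sqrt(rowSums(d * d))
  }
  ref_len <- blen(lig$ref_conf)
  span <- max(dist(lig$ref_conf))
  set.seed(11)
  for (k in 1:50) {
    pose <- random_trial_pose(lig, lig$ref_conf, cfg)
    expect_lte(sqrt(sum((geometric_center(pose) - cfg$sphere_center)^2)),
               cfg$sphere_radius + span)
    expect_lt(max(abs(blen(pose) - ref_len)), 1e-9)
  }
})

test_that("clash filtering applies the strict more-than-cutoff rule with bonded exemptions", {
  probe <- probe_ligand()
  rec04 <- rigid_receptor("C", cbind(0.4, 0, 0))
  rec05 <- rigid_receptor("C", cbind(0.5, 0, 0))
  rec06 <- rigid_receptor("C", cbind(0.6, 0, 0))
  at0 <- cbind(0, 0, 0)
  expect_false(clash_filter(rec04, probe, at0, 0.5))
  expect_false(clash_filter(rec05, probe, at0, 0.5))  # boundary rejects
  expect_true(clash_filter(rec06, probe, at0, 0.5))
  # bonded ligand pair at a normal bond length never triggers the filter
  diatomic <- make_toy_ligand(toy_system_spec("none", 2))$ligand
  expect_true(clash_filter(NULL, diatomic, rbind(c(0, 0, 0), c(1.0, 0, 0)),
                           0.5))
  # but a nonbonded 1-4 pair does
  chain <- make_toy_ligand(toy_system_spec("none", 4, 1))$ligand
  folded <- chain$ref_conf
  folded[4, ] <- folded[1, ] + c(0.3, 0, 0)
  expect_false(clash_filter(NULL, chain, folded, 0.5))
})

test_that("local minimization converges a convex well to max-gradient 1e-5", {
  lig <- probe_ligand()
  model <- quadratic_model(cbind(0.5, -0.25, 1), k = 3)
  cfg <- default_cfg()
  set.seed(4)
  for (k in 1:5) {
    start <- cbind(runif(1, -4, 4), runif(1, -4, 4), runif(1, -4, 4))
    m <- local_minimize(model, NULL, lig, start, cfg)
    expect_s3_class(m, "local_minimum")
    g <- evaluate_model(model, NULL, lig, m$conf)$gradient
    expect_lte(max(abs(g)), cfg$grad_tol)
    expect_equal(unname(m$conf), unname(cbind(0.5, -0.25, 1)),
                 tolerance = 1e-5)
  }
})

test_that("a double-well start relaxes into its own basin, matching a fine grid scan", {
  lig <- probe_ligand()
  model <- double_well_1d_model()
  cfg <- default_cfg()
  m <- local_minimize(model, NULL, lig, cbind(-0.6, 0.01, 0), cfg)
  expect_lt(m$conf[1, 1], 0)   # stays in the left basin
  # independent oracle: 1e-4-step scan of the x axis
  xs <- seq(-2, 0, by = 1e-4)
  es <- sapply(xs, function(x)
    evaluate_model(model, NULL, lig, cbind(x, 0, 0))$energy)
  expect_equal(m$energy, min(es), tolerance = 1e-6)
})

test_that("degenerate starts fail gracefully rather than crash", {
  lig <- make_toy_ligand(toy_system_spec("none", 2))$ligand
  model <- toy_energy_model()
  cfg <- default_cfg()
  start <- rbind(c(0, 0, 0), c(0, 0, 0))
  res <- local_minimize(model, NULL, lig, start, cfg)
  expect_s3_class(res, "minimize_failure")
})

test_that("minima-set insertion follows the dedup, sphere and capacity rules", {
  lig <- probe_ligand()
  set <- minima_set(capacity = 3, dedup_rmsd = 0.1)
  # base case: empty set accepts at rank 1
  r <- minima_set_insert(set, mk_min(0, -10), lig)
  expect_true(r$accepted)
  set <- r$set
  expect_equal(set_energies(set), -10)
  # duplicate within 0.05 A rejected even if lower in energy
  r <- minima_set_insert(set, mk_min(0.05, -12), lig)
  expect_false(r$accepted)
  expect_equal(r$reason, "duplicate")
  # fill to capacity {-10, -9, -8}
  set <- minima_set_insert(set, mk_min(1, -9), lig)$set
  set <- minima_set_insert(set, mk_min(2, -8), lig)$set
  # -8.5 enters, evicting -8
  r <- minima_set_insert(set, mk_min(3, -8.5), lig)
  expect_true(r$accepted)
  set <- r$set
  expect_equal(set_energies(set), c(-10, -9, -8.5))
  # -7 bounces off the capacity cut
  r <- minima_set_insert(set, mk_min(4, -7), lig)
  expect_false(r$accepted)
  expect_equal(r$reason, "capacity")
  # out-of-sphere centers are rejected when the sphere is given
  r <- minima_set_insert(set, mk_min(30, -20), lig,
                         sphere_center = c(0, 0, 0), sphere_radius = 8)
  expect_false(r$accepted)
  expect_equal(r$reason, "out_of_sphere")
})

test_that("set invariants survive thousands of randomized insertions", {
  lig <- probe_ligand()
  set <- minima_set(capacity = 32, dedup_rmsd = 0.1)
  set.seed(99)
  n_trials <- 10000L
  xs <- matrix(runif(3 * n_trials, -5, 5), ncol = 3)
  es <- rnorm(n_trials, sd = 5)
  for (k in seq_len(n_trials)) {
    m <- mk_min(xs[k, 1], es[k], xs[k, 2], xs[k, 3])
    set <- minima_set_insert(set, m, lig)$set
    if (k %% 2500L == 0L || k == n_trials) {
      e <- set_energies(set)
      expect_lte(length(e), set$capacity)
      expect_true(!is.unsorted(e))
      confs <- lapply(set$members, `[[`, "conf")
      for (i in seq_along(confs)[-1]) {
        for (j in seq_len(i - 1L)) {
          expect_gt(heavy_atom_rmsd(confs[[i]], confs[[j]],
                                    lig$heavy_indices), set$dedup_rmsd)
        }
      }
    }
  }
  expect_equal(length(set$members), set$capacity)
})

test_that("equal-energy members keep insertion order", {
  lig <- probe_ligand()
  set <- mk_set(xs = c(0, 1, 2), energies = c(-5, -5, -5), ligand = lig)
  expect_equal(vapply(set$members, function(m) m$conf[1, 1], 0), c(0, 1, 2))
})

test_that("the search is deterministic and its trial counters are conserved", {
  spec <- toy_system_spec("double-well")
  rec <- make_toy_pocket(spec)
  probe <- make_toy_ligand(spec)$ligand
  model <- toy_energy_model(spec$field_params)
  cfg <- search_config(sphere_center = c(0, 0, 0), sphere_radius = 4,
                       max_test_optimizations = 120, seed = 5)
  a <- run_search(rec, probe, cbind(2, 0, 0), model, cfg)
  b <- run_search(rec, probe, cbind(2, 0, 0), model, cfg)
  expect_equal(set_energies(a$set), set_energies(b$set))
  expect_identical(lapply(a$set$members, `[[`, "conf"),
                   lapply(b$set$members, `[[`, "conf"))
  d <- a$diagnostics
  expect_equal(d$n_test_optimizations, 120L)
  expect_equal(d$n_clash_rejected + d$n_optimizer_failures +
                 d$n_out_of_sphere_rejected + d$n_duplicate_rejected +
                 d$n_capacity_rejected + d$n_inserted,
               d$n_test_optimizations)
  expect_true(all(diff(d$update_events) > 0))
})

test_that("an impossible search area yields an empty set with a warning", {
  spec <- toy_system_spec("double-well")
  rec <- make_toy_pocket(spec)
  probe <- make_toy_ligand(spec)$ligand
  model <- toy_energy_model()
  # tiny sphere above the pocket: every optimized pose slides down into a
  # well outside the sphere and is rejected by the center check
  cfg <- search_config(sphere_center = c(0, 6, 0), sphere_radius = 0.5,
                       max_test_optimizations = 5, seed = 2)
  expect_warning(res <- run_search(rec, probe, cbind(0, 6, 0), model, cfg),
                 "empty")
  expect_equal(length(res$set$members), 0L)
})
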