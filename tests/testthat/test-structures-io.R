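# Structure reading, torsion perception and archive serialization.

test_that("receptor reading keeps ATOM records and drops HETATM", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.560   6.512  -4.162  1.00  0.00           C",
    "HETATM    4  O   HOH A   2       2.000   2.000   2.000  1.00  0.00           O",
    "END"
  ), path)
  rec <- read_receptor(path)
  expect_s3_class(rec, "rigid_receptor")
  expect_equal(nrow(rec$atoms), 3L)
  expect_equal(rec$atoms$element, c("N", "C", "C"))
  expect_true(all(rec$atoms$mass > 0))
})

test_that("a PDB without ATOM records is an empty-structure error", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"
  ), path)
  expect_error(read_receptor(path), "ATOM records")
  expect_error(read_receptor(tempfile(fileext = ".pdb")), "parse")
})

test_that("receptor write-then-read preserves coordinates to PDB precision", {
  rec <- make_toy_pocket(toy_system_spec("spherical-cavity"))
  path <- tempfile(fileext = ".pdb")
  write_receptor_pdb(rec, path)
  back <- read_receptor(path)
  expect_equal(nrow(back$atoms), nrow(rec$atoms))
  expect_lt(max(abs(back$coords - rec$coords)), 1.5e-3)
})

test_that("SDF ligand reading resolves atoms, bonds, torsions and mass", {
  lig <- read_ligand(butane_sdf())
  expect_equal(nrow(lig$atoms), 14L)
  expect_equal(length(lig$heavy_indices), 4L)
  expect_equal(length(lig$torsions), 1L)
  expect_equal(sort(lig$torsions[[1]]$axis), c(2L, 3L))
  # mass additivity
  expect_equal(lig$total_mass, 4 * 12.0107 + 10 * 1.00794, tolerance = 1e-10)
  expect_equal(lig$formal_charge, 0L)

  benzene <- read_ligand(benzene_sdf())
  expect_equal(nrow(benzene$atoms), 12L)
  expect_equal(length(benzene$torsions), 0L)
  expect_true(all(benzene$bonds$in_ring[benzene$bonds$j <= 6]))
})

test_that("a multi-molecule SDF is an ambiguity error", {
  one <- readLines(butane_sdf())
  path <- tempfile(fileext = ".sdf")
  writeLines(c(one, one), path)
  expect_error(read_ligand(path), "ambiguous")
})

test_that("torsion perception excludes rings and hydrogen-only rotors", {
  expect_equal(length(ethane_ligand()$torsions), 0L)
  expect_equal(length(cyclohexane_ligand()$torsions), 0L)
  chain <- make_toy_ligand(toy_system_spec("none", 4, 1))$ligand
  expect_equal(length(chain$torsions), 1L)
})

test_that("deleting a torsion axis bond splits the graph into the rotating set and its complement", {
  for (spec_n in list(c(4, 1), c(6, 3), c(8, 5))) {
    lig <- make_toy_ligand(toy_system_spec("none", spec_n[1], spec_n[2]))$ligand
    n <- nrow(lig$atoms)
    for (tor in lig$torsions) {
      b <- which(
        (lig$bonds$i == tor$axis[1] & lig$bonds$j == tor$axis[2]) |
        (lig$bonds$j == tor$axis[1] & lig$bonds$i == tor$axis[2])
      )
      g2 <- igraph::delete_edges(lig$graph, b)
      comp <- igraph::components(g2)$membership
      expect_equal(max(comp), 2L)
      rot_side <- comp[tor$axis[2]]
      expect_setequal(c(tor$rotating_set, tor$axis[2]),
                      which(comp == rot_side))
      expect_false(tor$axis[1] %in% tor$rotating_set)
      expect_false(tor$axis[2] %in% tor$rotating_set)
      # rotating side is never the larger component
      expect_lte(length(tor$rotating_set) + 1L,
                 n - length(tor$rotating_set) - 1L)
    }
  }
})

test_that("torsion detection is invariant to atom reordering up to relabeling", {
  reorder_lig <- function(lig, perm) {
    inv <- order(perm)
    flexible_ligand(
      element = lig$atoms$element[perm],
      coords = lig$ref_conf[perm, ],
      bonds = data.frame(i = inv[lig$bonds$i], j = inv[lig$bonds$j],
                         order = lig$bonds$order)
    )
  }
  # asymmetric chain: both torsions have unequal sides, so the rotating
  # sets themselves must map exactly under the relabeling
  pent <- make_toy_ligand(toy_system_spec("none", 5, 2))$ligand
  key <- function(tor, map = identity)
    paste(paste(sort(map(tor$axis)), collapse = ","),
          paste(sort(map(tor$rotating_set)), collapse = ","), sep = "|")
  set.seed(3)
  for (rep in 1:5) {
    perm <- sample(nrow(pent$atoms))
    pent2 <- reorder_lig(pent, perm)
    expect_setequal(vapply(pent2$torsions, key, "", map = function(i) perm[i]),
                    vapply(pent$torsions, key, ""))
  }
  # butane's central bond splits 7/7; under relabeling the index tie-break
  # may legitimately pick the mirror side, so only the axis is pinned
  lig <- read_ligand(butane_sdf())
  for (rep in 1:5) {
    perm <- sample(nrow(lig$atoms))
    lig2 <- reorder_lig(lig, perm)
    expect_equal(length(lig2$torsions), 1L)
    expect_setequal(perm[lig2$torsions[[1]]$axis], lig$torsions[[1]]$axis)
    mapped <- sort(perm[lig2$torsions[[1]]$rotating_set])
    sides <- list(c(4L, 10:14), c(1L, 5:9))
    expect_true(any(vapply(sides, identical, TRUE, y = mapped)))
  }
})

test_that("geometric center is the unweighted centroid and is translation-equivariant", {
  expect_equal(geometric_center(cbind(1, 2, 3)), c(x = 1, y = 2, z = 3))
  expect_equal(unname(geometric_center(rbind(c(-1, 0, 0), c(1, 0, 0)))),
               c(0, 0, 0))
  set.seed(1)
  conf <- matrix(rnorm(30), 10, 3)
  d <- c(0.5, -2, 7)
  expect_equal(geometric_center(sweep(conf, 2, -d)),
               geometric_center(conf) + d)
  expect_error(geometric_center(matrix(numeric(0), 0, 3)), "empty")
})

test_that("minima archives round-trip energies and coordinates", {
  lig <- make_toy_ligand(toy_system_spec("none", 4, 1))$ligand
  set <- minima_set(capacity = 8, model_tag = "toy")
  set.seed(5)
  for (k in 1:4) {
    m <- structure(list(
      conf = lig$ref_conf + matrix(rnorm(nrow(lig$atoms) * 3), ncol = 3),
      energy = rnorm(1) * 10, n_optimizer_steps = k,
      origin_trial_index = k
    ), class = "local_minimum")
    set <- minima_set_insert(set, m, lig)$set
  }
  sdf <- tempfile(fileext = ".sdf")
  csv <- tempfile(fileext = ".csv")
  write_minima_archive(set, lig, sdf, index_csv = csv,
                       native_conf = lig$ref_conf)
  back <- read_minima_archive(sdf, lig)
  expect_equal(length(back$members), 4L)
  expect_equal(set_energies(back), set_energies(set), tolerance = 1e-6)
  for (k in 1:4)
    expect_lt(max(abs(back$members[[k]]$conf - set$members[[k]]$conf)),
              1e-4)
  idx <- read.csv(csv)
  expect_equal(idx$rank, 1:4)
  expect_equal(idx$energy, set_energies(set), tolerance = 1e-9)
  expect_true(all(is.finite(idx$rmsd_to_native)))
  expect_true(all(idx$cluster_id >= 1))
})

test_that("archives written here are readable by an independent SDF toolkit", {
  skip_if_not_installed("ChemmineR")
  lig <- make_toy_ligand(toy_system_spec("none", 4, 1))$ligand
  set <- minima_set(capacity = 4)
  m <- structure(list(conf = lig$ref_conf, energy = -1.25,
                      n_optimizer_steps = 1L, origin_trial_index = 1L),
                 class = "local_minimum")
  set <- minima_set_insert(set, m, lig)$set
  path <- tempfile(fileext = ".sdf")
  write_minima_archive(set, lig, path)
  sdfset <- ChemmineR::read.SDFset(path)
  expect_equal(length(sdfset), 1L)
  ab <- ChemmineR::atomblock(sdfset[[1]])
  expect_equal(unname(ab[, 1:3]), unname(lig$ref_conf), tolerance = 1e-4)
  expect_equal(nrow(ChemmineR::bondblock(sdfset[[1]])), nrow(lig$bonds))
})
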