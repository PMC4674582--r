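# Structure containers and readers: rigid receptor, flexible ligand,
# conformations, rotatable-torsion perception.

normalize_element <- function(x) {
  x <- trimws(x)
  bad <- !nzchar(x)
  if (any(bad)) stop("atom(s) with empty element symbol")
  paste0(toupper(substr(x, 1L, 1L)),
         tolower(substr(x, 2L, nchar(x))))
}

make_atom_frame <- function(element, partial_charge = 0) {
  element <- normalize_element(element)
  vdw <- element_vdw(element)
  data.frame(
    element = element,
    mass = element_mass(element),
    is_heavy = element != "H",
    partial_charge = rep_len(partial_charge, length(element)),
    vdw_sigma = vdw[, "sigma"],
    vdw_epsilon = vdw[, "epsilon"],
    stringsAsFactors = FALSE
  )
}

#' Coerce to a conformation matrix
#'
#' A conformation is an n x 3 numeric matrix of Cartesian coordinates in
#' Angstrom, rows ordered exactly as the atoms of the molecule it belongs to.
#'
#' @param x A numeric matrix (or object coercible to one) with 3 columns,
#'   or a length-3 vector for a single atom.
#' @param n_atoms Optional expected atom count, checked if given.
#' @return The validated coordinate matrix.
#' @export
as_conformation <- function(x, n_atoms = NULL) {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L) stop("coordinates not a multiple of 3")
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("a conformation must have 3 columns")
  if (nrow(x) < 1L) stop("empty conformation")
  if (!all(is.finite(x))) stop("non-finite coordinates in conformation")
  if (!is.null(n_atoms) && nrow(x) != n_atoms)
    stop("conformation has ", nrow(x), " atoms, expected ", n_atoms)
  dimnames(x) <- list(NULL, c("x", "y", "z"))
  storage.mode(x) <- "double"
  x
}

#' Construct a rigid receptor
#'
#' The receptor defines the fixed external field for the minima search: its
#' coordinates never move after load.
#'
#' @param element Character vector of element symbols.
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param source_id Label for provenance (e.g. a PDB identifier).
#' @param partial_charge Per-atom partial charges, elementary units
#'   (recycled; default 0).
#' @param vdw Optional n x 2 matrix overriding the per-element Lennard-Jones
#'   `sigma` (A) and `epsilon` (kcal/mol) used by the built-in toy field.
#' @return An object of class `rigid_receptor`.
#' @export
rigid_receptor <- function(element, coords, source_id = "unknown",
                           partial_charge = 0, vdw = NULL) {
  atoms <- make_atom_frame(element, partial_charge)
  coords <- as_conformation(coords, n_atoms = nrow(atoms))
  if (!is.null(vdw)) {
    vdw <- as.matrix(vdw)
    atoms$vdw_sigma <- rep_len(vdw[, 1L], nrow(atoms))
    atoms$vdw_epsilon <- rep_len(vdw[, 2L], nrow(atoms))
  }
  structure(
    list(atoms = atoms, coords = coords, source_id = source_id),
    class = "rigid_receptor"
  )
}

#' @export
print.rigid_receptor <- function(x, ...) {
  cat("<rigid_receptor> ", x$source_id, ": ", nrow(x$atoms), " atoms\n",
      sep = "")
  invisible(x)
}

#' Read a receptor structure from a PDB file
#'
#' Only `ATOM` records are retained: all `HETATM` records (waters, ions,
#' cofactors, the ligand itself) are stripped on read, and the remaining
#' protein is treated as rigid.  Hydrogens are expected to be present
#' already; protonation is an upstream responsibility.
#'
#' @param path Path to a PDB file.
#' @return A [rigid_receptor()].
#' @export
read_receptor <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  sel <- pdb$atom$type == "ATOM"
  if (!any(sel))
    stop("no ATOM records in '", path, "': empty structure after HETATM removal")
  at <- pdb$atom[sel, , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || any(is.na(elem) | !nzchar(trimws(elem)))) {
    elem2 <- tryCatch(bio3d::atom2ele(pdb)[sel], error = function(e) NULL)
    if (is.null(elem2))
      stop("cannot resolve element symbols in '", path, "'")
    miss <- is.na(elem) | !nzchar(trimws(elem))
    elem[miss] <- elem2[miss]
  }
  rigid_receptor(
    element = elem,
    coords = cbind(at$x, at$y, at$z),
    source_id = tools::file_path_sans_ext(basename(path))
  )
}

#' Write a receptor to a PDB file
#'
#' @param receptor A [rigid_receptor()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_receptor_pdb <- function(receptor, path) {
  n <- nrow(receptor$atoms)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(receptor$coords)),
    type = rep("ATOM", n),
    resno = seq_len(n),
    resid = rep("UNK", n),
    eleno = seq_len(n),
    elety = receptor$atoms$element,
    chain = rep("A", n),
    elesy = receptor$atoms$element
  )
  invisible(path)
}

#' Construct a flexible ligand
#'
#' Builds the full ligand topology used by the search: bond graph with ring
#' perception, rotatable torsions, heavy-atom index set, angle triples and
#' the nonbonded pair list with 1-2/1-3 exclusions.
#'
#' @param element Character vector of element symbols (explicit hydrogens
#'   included).
#' @param coords Reference conformation, n x 3 Angstrom.
#' @param bonds Data frame with integer columns `i`, `j` and `order`.
#' @param partial_charge Per-atom partial charges (recycled; default 0).
#' @param formal_charge_atoms Per-atom integer formal charges (default 0).
#' @param vdw Optional n x 2 override of Lennard-Jones `sigma`, `epsilon`.
#' @return An object of class `flexible_ligand` with fields `atoms`, `bonds`
#'   (including an `in_ring` flag), `torsions`, `heavy_indices`,
#'   `total_mass`, `formal_charge`, `angles`, `nonbonded_pairs`, `excluded`
#'   and the reference conformation `ref_conf`.
#' @export
flexible_ligand <- function(element, coords, bonds, partial_charge = 0,
                            formal_charge_atoms = 0, vdw = NULL) {
  atoms <- make_atom_frame(element, partial_charge)
  n <- nrow(atoms)
  coords <- as_conformation(coords, n_atoms = n)
  if (!is.null(vdw)) {
    vdw <- as.matrix(vdw)
    atoms$vdw_sigma <- rep_len(vdw[, 1L], n)
    atoms$vdw_epsilon <- rep_len(vdw[, 2L], n)
  }
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0L) {
    stopifnot(all(c("i", "j") %in% names(bonds)))
    if (is.null(bonds$order)) bonds$order <- 1L
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n) ||
        any(bonds$i == bonds$j))
      stop("bond indices out of range")
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0L)
    g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
  if (igraph::components(g)$no != 1L)
    stop("ligand bond graph is not connected")
  bonds$in_ring <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0L) {
    bridge_ids <- as.integer(igraph::bridges(g))
    bonds$in_ring <- !(seq_len(nrow(bonds)) %in% bridge_ids)
  }
  lig <- structure(
    list(
      atoms = atoms,
      bonds = bonds,
      graph = g,
      heavy_indices = which(atoms$is_heavy),
      total_mass = sum(atoms$mass),
      formal_charge = as.integer(sum(rep_len(formal_charge_atoms, n))),
      formal_charge_atoms = as.integer(rep_len(formal_charge_atoms, n)),
      ref_conf = coords
    ),
    class = "flexible_ligand"
  )
  lig$angles <- enumerate_angles(lig)
  excl <- excluded_pairs(lig)
  lig$excluded <- excl
  lig$nonbonded_pairs <- nonbonded_pairs(n, excl)
  lig$torsions <- detect_torsions(lig)
  lig
}

#' @export
print.flexible_ligand <- function(x, ...) {
  cat("<flexible_ligand> ", nrow(x$atoms), " atoms (",
      length(x$heavy_indices), " heavy), ", nrow(x$bonds), " bonds, ",
      length(x$torsions), " rotatable torsion(s)\n", sep = "")
  invisible(x)
}

# all i-j-k angle triples (j central), i < k
enumerate_angles <- function(lig) {
  n <- nrow(lig$atoms)
  out <- list()
  adj <- igraph::as_adj_list(lig$graph)
  for (j in seq_len(n)) {
    nb <- sort(as.integer(adj[[j]]))
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2L)
    out[[length(out) + 1L]] <- cbind(i = cmb[1L, ], j = j, k = cmb[2L, ])
  }
  if (length(out) == 0L)
    return(matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("i", "j", "k"))))
  do.call(rbind, out)
}

# 2-column matrix of 1-2 and 1-3 pairs (i < j)
excluded_pairs <- function(lig) {
  p12 <- cbind(pmin(lig$bonds$i, lig$bonds$j), pmax(lig$bonds$i, lig$bonds$j))
  p13 <- cbind(pmin(lig$angles[, "i"], lig$angles[, "k"]),
               pmax(lig$angles[, "i"], lig$angles[, "k"]))
  unique(rbind(p12, p13))
}

nonbonded_pairs <- function(n, excluded) {
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L))
  all_pairs <- t(utils::combn(seq_len(n), 2L))
  if (nrow(excluded) == 0L) return(all_pairs)
  key <- function(m) m[, 1L] * (n + 1L) + m[, 2L]
  all_pairs[!(key(all_pairs) %in% key(excluded)), , drop = FALSE]
}

#' Detect rotatable torsions of a ligand
#'
#' A rotatable torsion is a single (order-1) acyclic bond of the ligand.
#' Terminal rotors are excluded: each axis atom must have at least one
#' non-hydrogen neighbour besides its axis partner, so bonds that only spin
#' hydrogens (methyl, hydroxyl, ethane-like rotors) are not counted.  The
#' rotating set is the smaller of the two components obtained by deleting
#' the axis bond (ties resolved to the component containing the
#' higher-indexed axis atom), excluding the axis atoms themselves.
#'
#' @param ligand A [flexible_ligand()].
#' @return A list of torsion definitions, each a list with `axis` (ordered
#'   pair of atom indices), `rotating_set` (integer vector) and `quad`
#'   (a 4-atom dihedral i-a1-a2-l used for torsion-potential evaluation).
#' @export
detect_torsions <- function(ligand) {
  bonds <- ligand$bonds
  atoms <- ligand$atoms
  g <- ligand$graph
  adj <- igraph::as_adj_list(g)
  out <- list()
  for (b in seq_len(nrow(bonds))) {
    if (bonds$order[b] != 1L || bonds$in_ring[b]) next
    a1 <- bonds$i[b]; a2 <- bonds$j[b]
    nb1 <- setdiff(as.integer(adj[[a1]]), a2)
    nb2 <- setdiff(as.integer(adj[[a2]]), a1)
    h1 <- nb1[atoms$is_heavy[nb1]]
    h2 <- nb2[atoms$is_heavy[nb2]]
    if (length(h1) == 0L || length(h2) == 0L) next
    g2 <- igraph::delete_edges(g, b)
    comp <- igraph::components(g2)$membership
    side1 <- which(comp == comp[a1])
    side2 <- which(comp == comp[a2])
    if (length(side1) < length(side2)) {
      rot <- side1
    } else if (length(side2) < length(side1)) {
      rot <- side2
    } else {
      hi <- max(a1, a2)
      rot <- if (hi %in% side1) side1 else side2
    }
    # orient the axis so the second atom sits on the rotating side
    axis <- if (a2 %in% rot) c(a1, a2) else c(a2, a1)
    rot <- setdiff(rot, axis)
    quad <- c(min(h1), a1, a2, min(h2))
    if (axis[1L] == a2) quad <- rev(quad)
    out[[length(out) + 1L]] <- list(
      axis = axis, rotating_set = sort(rot), quad = quad
    )
  }
  out
}

#' Geometric center of a conformation
#'
#' The unweighted centroid: the center of gravity with all atomic masses set
#' to one, hydrogens included.  This is the point used both to place random
#' trial poses and to test whether an optimized pose left the search sphere.
#'
#' @param conf A conformation (n x 3 matrix, Angstrom).
#' @return A length-3 numeric vector.
#' @export
geometric_center <- function(conf) {
  conf <- as_conformation(conf)
  colMeans(conf)
}

#' Read a ligand structure
#'
#' SDF is read natively; MOL2 and PDB inputs are converted to SDF through
#' OpenBabel (the `ChemmineOB` package), which also infers connectivity for
#' PDB ligands.  The file must contain exactly one molecule with explicit
#' hydrogens.
#'
#' @param path Path to an SDF, MOL2 or PDB file.
#' @param format One of `"auto"` (by extension), `"sdf"`, `"mol2"`, `"pdb"`.
#' @return A [flexible_ligand()] with `ref_conf` set to the file coordinates.
#' @export
read_ligand <- function(path, format = c("auto", "sdf", "mol2", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      sdf = "sdf", mol = "sdf", mol2 = "mol2", pdb = "pdb",
      stop("cannot infer ligand format from extension '", ext, "'")
    )
  }
  if (format %in% c("mol2", "pdb")) {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
      stop("reading ", toupper(format),
           " ligands requires the ChemmineOB package")
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    ChemmineOB::convertFormatFile(toupper(format), "SDF", path, tmp)
    if (!file.exists(tmp) || length(readLines(tmp, warn = FALSE)) < 4L)
      stop("connectivity inference failed for '", path, "'")
    path <- tmp
  }
  recs <- read_sdf_file(path)
  if (length(recs) > 1L)
    stop("ambiguous input: ", length(recs), " molecules in '", path,
         "'; expected exactly one")
  rec <- recs[[1L]]
  flexible_ligand(
    element = rec$element,
    coords = rec$coords,
    bonds = rec$bonds,
    formal_charge_atoms = rec$charge
  )
}

#' Write a ligand conformation to an SDF file
#'
#' @param ligand A [flexible_ligand()].
#' @param conf Conformation to write (defaults to the reference).
#' @param path Output path.
#' @param title Molecule title.
#' @param props Named character vector of SDF data fields.
#' @return The path, invisibly.
#' @export
write_ligand_sdf <- function(ligand, conf = ligand$ref_conf, path,
                             title = "ligand", props = character(0)) {
  rec <- list(
    title = title,
    element = ligand$atoms$element,
    coords = as_conformation(conf, n_atoms = nrow(ligand$atoms)),
    charge = ligand$formal_charge_atoms,
    bonds = ligand$bonds[, c("i", "j", "order"), drop = FALSE],
    props = props
  )
  write_sdf_file(list(rec), path)
}
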