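# Minima-archive serialization: a multi-record SDF holding one ligand pose
# per stored minimum with its energies as data fields, plus an optional
# CSV index (rank, energy, RMSD to native, cluster id).

#' Write a minima set to an SDF archive
#'
#' One SDF record per member, rank order, with data fields
#' `energy_kcal_mol`, `rank`, `model_tag` and (when present on a member)
#' `rescored_energy_kcal_mol`.  Energies are stored at full precision;
#' coordinates at the 1e-4 A precision of the SDF format.
#'
#' @param set A [minima_set()].
#' @param ligand The [flexible_ligand()] the poses belong to.
#' @param path Output SDF path.
#' @param index_csv Optional path for a CSV index with columns `rank`,
#'   `energy`, `rmsd_to_native`, `cluster_id` (RMSD/cluster columns need
#'   `native_conf`).
#' @param native_conf Optional native pose for the index RMSD column.
#' @param link_rmsd Cluster linkage threshold for the index, A.
#' @return `path`, invisibly.
#' @export
write_minima_archive <- function(set, ligand, path, index_csv = NULL,
                                 native_conf = NULL, link_rmsd = 1.4) {
  stopifnot(inherits(set, "minima_set"))
  recs <- lapply(seq_along(set$members), function(k) {
    m <- set$members[[k]]
    props <- c(
      energy_kcal_mol = sprintf("%.12g", m$energy),
      rank = as.character(k),
      model_tag = set$model_tag
    )
    if (!is.null(m$rescored_energy))
      props["rescored_energy_kcal_mol"] <- sprintf("%.12g", m$rescored_energy)
    list(
      title = sprintf("minimum_%d", k),
      element = ligand$atoms$element,
      coords = m$conf,
      charge = ligand$formal_charge_atoms,
      bonds = ligand$bonds[, c("i", "j", "order"), drop = FALSE],
      props = props
    )
  })
  write_sdf_file(recs, path)
  if (!is.null(index_csv)) {
    n <- length(set$members)
    idx <- data.frame(rank = seq_len(n), energy = set_energies(set),
                      rmsd_to_native = NA_real_, cluster_id = NA_integer_)
    if (!is.null(native_conf) && n > 0L) {
      idx$rmsd_to_native <- vapply(set$members, function(m)
        heavy_atom_rmsd(m$conf, native_conf, ligand$heavy_indices), 0)
      idx$cluster_id <- cluster_minima(set, ligand, link_rmsd,
                                       native_conf)$labels
    }
    utils::write.csv(idx, index_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Read a minima set from an SDF archive
#'
#' @param path Archive written by [write_minima_archive()].
#' @param ligand The [flexible_ligand()] the poses belong to (atom order
#'   must match the archive).
#' @param capacity,dedup_rmsd Set parameters to restore (defaults: the
#'   archive size and 0.1 A).
#' @return A [minima_set()] sorted ascending by energy.
#' @export
read_minima_archive <- function(path, ligand, capacity = NULL,
                                dedup_rmsd = 0.1) {
  recs <- read_sdf_file(path)
  n_atoms <- nrow(ligand$atoms)
  members <- lapply(recs, function(rec) {
    if (nrow(rec$coords) != n_atoms)
      stop("archive record has ", nrow(rec$coords),
           " atoms; ligand has ", n_atoms)
    e <- suppressWarnings(as.numeric(rec$props[["energy_kcal_mol"]]))
    if (is.na(e)) stop("archive record without a valid energy_kcal_mol")
    m <- structure(list(
      conf = as_conformation(rec$coords),
      energy = e,
      n_optimizer_steps = NA_integer_,
      origin_trial_index = NA_integer_
    ), class = "local_minimum")
    if (!is.null(rec$props) &&
        "rescored_energy_kcal_mol" %in% names(rec$props))
      m$rescored_energy <- as.numeric(rec$props[["rescored_energy_kcal_mol"]])
    m
  })
  tag <- if (length(recs) > 0L && "model_tag" %in% names(recs[[1L]]$props))
    recs[[1L]]$props[["model_tag"]] else "unknown"
  set <- minima_set(
    capacity = if (is.null(capacity)) max(length(members), 1L) else capacity,
    dedup_rmsd = dedup_rmsd, model_tag = tag
  )
  set$members <- members[order(vapply(members, `[[`, 0, "energy"))]
  set
}
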