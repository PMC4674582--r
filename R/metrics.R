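# RMSD-based evaluation metrics for minima sets: near-native indices
# (IN / INN), pose clustering, energy-window counts and RMSD profiles.

# validation-free inner loop shared by deduplication and clustering
rmsd_fast <- function(a, b, heavy_indices) {
  d <- a[heavy_indices, , drop = FALSE] - b[heavy_indices, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}

#' Heavy-atom RMSD between two conformations
#'
#' Root-mean-square deviation over the heavy atoms under the identity atom
#' mapping, without superposition and without chemical-symmetry
#' correction: the receptor frame is fixed, so poses are compared in
#' place.
#'
#' @param a,b Conformations with identical atom ordering.
#' @param heavy_indices Indices of the heavy atoms.
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(a, b, heavy_indices) {
  a <- as_conformation(a); b <- as_conformation(b)
  if (nrow(a) != nrow(b))
    stop("conformations have different atom counts (", nrow(a), " vs ",
         nrow(b), ")")
  if (length(heavy_indices) < 1L) stop("at least one heavy atom required")
  d <- a[heavy_indices, , drop = FALSE] - b[heavy_indices, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}

#' Native-pose reference
#'
#' Bundles the experimentally observed (non-optimized) native pose with its
#' locally optimized counterpart under the evaluated target function.
#'
#' @param native_conf The crystal pose.
#' @param optimized_native_conf The native pose after local minimization
#'   under the evaluated model (optional if only INN is needed).
#' @param optimized_native_energy Its energy, kcal/mol (optional if only
#'   INN is needed).
#' @return An object of class `native_reference`.
#' @export
native_reference <- function(native_conf, optimized_native_conf = NULL,
                             optimized_native_energy = NULL) {
  structure(list(
    native_conf = as_conformation(native_conf),
    optimized_native_conf = if (is.null(optimized_native_conf)) NULL
                            else as_conformation(optimized_native_conf),
    optimized_native_energy = optimized_native_energy
  ), class = "native_reference")
}

#' Index of Native (IN)
#'
#' The rank the optimized-native energy would take if inserted into the
#' energy-sorted minima list: one plus the number of stored minima with
#' energy strictly below it.  `IN = 1` therefore means no stored minimum
#' beats the native pose.  If every stored member lies below the native
#' energy the true rank is unknown (the set is capacity-truncated) and
#' `Inf` is returned.
#'
#' @param set A [minima_set()], sorted ascending.
#' @param ref A [native_reference()] with `optimized_native_energy` set.
#' @return A positive integer rank, or `Inf`.
#' @export
index_of_native <- function(set, ref) {
  stopifnot(inherits(set, "minima_set"))
  if (is.null(ref$optimized_native_energy))
    stop("optimized_native_energy missing from the native reference")
  energies <- set_energies(set)
  if (length(energies) == 0L) return(1)
  below <- sum(energies < ref$optimized_native_energy)
  if (below == length(energies)) return(Inf)
  below + 1
}

#' Index of Near Native (INN)
#'
#' The smallest rank whose member lies within `threshold` heavy-atom RMSD
#' of the non-optimized native pose; `Inf` if no stored minimum is that
#' close.
#'
#' @param set A [minima_set()], sorted ascending.
#' @param ref A [native_reference()] (only `native_conf` is used).
#' @param ligand The [flexible_ligand()].
#' @param threshold Near-native RMSD threshold, A (default 2).
#' @return A positive integer rank, or `Inf`.
#' @export
index_of_near_native <- function(set, ref, ligand, threshold = 2) {
  stopifnot(inherits(set, "minima_set"), threshold > 0)
  for (k in seq_along(set$members)) {
    if (heavy_atom_rmsd(set$members[[k]]$conf, ref$native_conf,
                        ligand$heavy_indices) < threshold)
      return(k)
  }
  Inf
}

#' Cluster the minima of a set by pairwise RMSD
#'
#' The pairwise rule "two conformations belong to one cluster if their
#' RMSD is below `link_rmsd`" is not transitive; its minimal closure is
#' single linkage, i.e. connected components of the graph whose edges are
#' the sub-threshold pairs (the default).  Complete linkage is available
#' as a stricter alternative.  Clusters are indexed 1..k by ascending
#' lowest member energy.
#'
#' @param set A [minima_set()].
#' @param ligand The [flexible_ligand()].
#' @param link_rmsd Linkage threshold, A (default 1.4).
#' @param native_conf Optional native pose; if given, the native cluster
#'   index is the lowest-indexed cluster containing a member within
#'   `link_rmsd` of it, or `Inf` if the native pose falls into no cluster.
#' @param linkage `"single"` (connected components) or `"complete"`.
#' @return An object of class `cluster_report`: `labels` (per member),
#'   `n_clusters`, `cluster_link_rmsd`, `native_cluster_index`.
#' @export
cluster_minima <- function(set, ligand, link_rmsd = 1.4,
                           native_conf = NULL,
                           linkage = c("single", "complete")) {
  stopifnot(inherits(set, "minima_set"), link_rmsd > 0)
  linkage <- match.arg(linkage)
  n <- length(set$members)
  if (n == 0L) {
    return(structure(list(labels = integer(0), n_clusters = 0L,
                          cluster_link_rmsd = link_rmsd,
                          native_cluster_index = Inf),
                     class = "cluster_report"))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- rmsd_fast(set$members[[i]]$conf,
                                      set$members[[j]]$conf,
                                      ligand$heavy_indices)
    }
  }
  if (n == 1L) {
    raw <- 1L
  } else if (linkage == "single") {
    adj <- (D < link_rmsd)
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    raw <- as.integer(igraph::components(g)$membership)
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    raw <- as.integer(stats::cutree(hc, h = link_rmsd * (1 - 1e-9)))
  }
  energies <- set_energies(set)
  lowest <- vapply(seq_len(max(raw)),
                   function(cl) min(energies[raw == cl]), 0)
  relabel <- integer(max(raw))
  relabel[order(lowest)] <- seq_len(max(raw))
  labels <- relabel[raw]
  native_idx <- Inf
  if (!is.null(native_conf)) {
    d_nat <- vapply(set$members, function(m)
      heavy_atom_rmsd(m$conf, native_conf, ligand$heavy_indices), 0)
    hit <- d_nat < link_rmsd
    if (any(hit)) native_idx <- min(labels[hit])
  }
  structure(list(labels = labels, n_clusters = max(labels),
                 cluster_link_rmsd = link_rmsd,
                 native_cluster_index = native_idx),
            class = "cluster_report")
}

#' Count minima inside a thermal energy window
#'
#' The number of stored minima within `width_kT` times kT of the global
#' minimum; only these contribute appreciably to the multiwell binding
#' free energy.
#'
#' @param set A non-empty [minima_set()].
#' @param width_kT Window width in units of kT (default 5).
#' @param temperature Temperature, K (default 310).
#' @return Integer count (the global minimum itself always counts; with
#'   width 0, exact ties at the minimum are all counted).
#' @export
window_count <- function(set, width_kT = 5, temperature = 310) {
  energies <- set_energies(set)
  if (length(energies) == 0L) stop("empty minima set")
  kT <- physical_constants()$kB_kcal * temperature
  sum(energies <= energies[1L] + width_kT * kT)
}

#' RMSD profile of a minima set
#'
#' Heavy-atom RMSD of every member to the native pose, sorted ascending.
#' The first element is the "lowest RMSD" summary statistic of a search.
#'
#' @param set A non-empty [minima_set()].
#' @param native_conf The native pose.
#' @param ligand The [flexible_ligand()].
#' @return Sorted numeric vector of RMSDs, A.
#' @export
rmsd_profile <- function(set, native_conf, ligand) {
  if (length(set$members) == 0L) stop("empty minima set")
  sort(vapply(set$members, function(m)
    heavy_atom_rmsd(m$conf, native_conf, ligand$heavy_indices), 0))
}

#' Full index report for a minima set
#'
#' Convenience wrapper computing IN and INN together.
#'
#' @inheritParams index_of_near_native
#' @param inn_threshold Near-native RMSD threshold, A (default 2).
#' @return List of class `index_report` with `IN`, `INN`,
#'   `inn_rmsd_threshold`.
#' @export
index_report <- function(set, ref, ligand, inn_threshold = 2) {
  structure(list(
    IN = index_of_native(set, ref),
    INN = index_of_near_native(set, ref, ligand, inn_threshold),
    inn_rmsd_threshold = inn_threshold
  ), class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "inf" else format(v)
  cat("<index_report> IN = ", fmt(x$IN), ", INN = ", fmt(x$INN),
      " (threshold ", x$inn_rmsd_threshold, " A)\n", sep = "")
  invisible(x)
}
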