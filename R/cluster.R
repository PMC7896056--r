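#' Average structure of superposed conformations
#'
#' Superposes each member onto `reference` using the `align_on` atoms and
#' returns the atom-wise arithmetic mean of the superposed coordinates.
#'
#' @param members list of `labeled_structure` objects (at least one).
#' @param reference `labeled_structure` to superpose onto.
#' @param align_on role tokens used for the superposition.
#' @return A `labeled_structure` with the averaged coordinates and the
#'   reference topology.
#' @export
average_structure <- function(members, reference,
                              align_on = "protein-calpha") {
  if (length(members) == 0L)
    stop("cannot average an empty member list")
  ai <- which(role_mask(reference$atoms, align_on))
  if (length(ai) == 0L)
    stop("empty alignment selection")
  acc <- matrix(0, nrow(reference$xyz), 3L)
  for (m in members) {
    if (!same_topology(m, reference))
      stop("member does not share the reference topology")
    sup <- kabsch_superpose(m$xyz[ai, , drop = FALSE],
                            reference$xyz[ai, , drop = FALSE])
    acc <- acc + apply_superposition(m$xyz, sup)
  }
  labeled_structure(reference$atoms, acc / length(members))
}

#' Cluster a conformational ensemble by iterative average structures
#'
#' Partitions the frames of an ensemble into metastable states with the
#' iterative average-structure method: a tentative reference (the first
#' remaining frame; at the very start, the first snapshot of the first
#' run) collects all remaining frames within `cutoff` of it, the average
#' of those superposed members becomes the new reference, and membership
#' and average are refined until two successive averages differ by less
#' than `convergence`. The converged member set is removed as a new
#' cluster and the procedure repeats until no frames remain, so the
#' result is a partition. The distance is [rmsd_selective()] with the
#' given selections (default: align on protein C-alpha, measure over
#' C-alpha plus ligand heavy atoms).
#'
#' @param ensemble an `md_ensemble`.
#' @param cutoff membership cutoff in Angstrom (default 2.0); membership
#'   is inclusive (`<= cutoff`).
#' @param convergence convergence threshold on the RMSD between
#'   successive average structures, Angstrom (default 0.01).
#' @param align_on,measure_on role-token selections for the distance.
#' @param max_iter safety cap on refinement cycles per cluster (default
#'   100); on hitting it the cluster is finalised at the last iterate
#'   with a warning.
#' @return An `ensemble_clustering` object: `assignment` (frame index ->
#'   cluster id, discovery order), and `clusters`, a list with per-cluster
#'   `average` structure, `members`, `size`, `iterations` and `converged`.
#' @export
cluster_ensemble <- function(ensemble, cutoff = 2.0, convergence = 0.01,
                             align_on = "protein-calpha",
                             measure_on = c("protein-calpha", "ligand-heavy"),
                             max_iter = 100L) {
  stopifnot(cutoff > 0, convergence > 0, max_iter >= 1L)
  nf <- n_frames(ensemble)
  remaining <- seq_len(nf)
  assignment <- integer(nf)
  clusters <- list()
  while (length(remaining) > 0L) {
    ref <- get_frame(ensemble, remaining[1L])
    iter <- 0L
    converged <- FALSE
    members <- integer(0)
    while (iter < max_iter) {
      iter <- iter + 1L
      d <- vapply(remaining, function(i)
        rmsd_selective(get_frame(ensemble, i), ref, align_on, measure_on),
        numeric(1))
      members <- remaining[d <= cutoff]
      avg <- average_structure(lapply(members, get_frame,
                                      ensemble = ensemble),
                               ref, align_on)
      shift <- rmsd_selective(avg, ref, align_on, measure_on)
      ref <- avg
      if (shift < convergence) {
        converged <- TRUE
        break
      }
    }
    if (!converged)
      warning(sprintf(
        "cluster %d not converged after %d refinement cycles; finalised at last iterate",
        length(clusters) + 1L, max_iter))
    id <- length(clusters) + 1L
    assignment[members] <- id
    clusters[[id]] <- list(average = ref, members = members,
                           size = length(members), iterations = iter,
                           converged = converged)
    remaining <- setdiff(remaining, members)
  }
  structure(list(assignment = assignment, clusters = clusters,
                 cutoff = cutoff, convergence = convergence,
                 align_on = align_on, measure_on = measure_on),
            class = "ensemble_clustering")
}

#' @export
print.ensemble_clustering <- function(x, ...) {
  cat("Ensemble clustering:", length(x$clusters), "cluster(s) over",
      length(x$assignment), "frames (cutoff", x$cutoff, "A)\n")
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: %d frames (%.1f%%), %d refinement cycle(s)%s\n",
                i, cl$size, 100 * cl$size / length(x$assignment),
                cl$iterations,
                if (cl$converged) "" else " [not converged]"))
  }
  invisible(x)
}

#' @export
summary.ensemble_clustering <- function(object, ...) {
  data.frame(cluster = seq_along(object$clusters),
             size = vapply(object$clusters, `[[`, integer(1), "size"),
             population = vapply(object$clusters, `[[`, integer(1), "size") /
               length(object$assignment),
             iterations = vapply(object$clusters, `[[`, integer(1),
                                 "iterations"),
             converged = vapply(object$clusters, `[[`, logical(1),
                                "converged"))
}

#' Per-frame RMSD trace against a reference structure
#'
#' One [rmsd_selective()] value per frame, in frame order -- the standard
#' trajectory RMSD plot of a ligand--protein complex against, e.g., a
#' docking model.
#'
#' @inheritParams cluster_ensemble
#' @param reference `labeled_structure` sharing the ensemble topology.
#' @return Numeric vector, one value (Angstrom) per frame.
#' @export
rmsd_trace <- function(ensemble, reference,
                       align_on = "protein-calpha",
                       measure_on = c("protein-calpha", "ligand-heavy")) {
  vapply(seq_len(n_frames(ensemble)), function(i)
    rmsd_selective(get_frame(ensemble, i), reference, align_on, measure_on),
    numeric(1))
}
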