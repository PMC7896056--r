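#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimise the
#' least-squares deviation of `mobile` onto `reference`. Reflections are
#' excluded by the determinant correction in the SVD solution: molecular
#' frames are chiral, so an improper "fit" would be meaningless. All
#' points carry equal weight.
#'
#' @param mobile,reference numeric matrices of matching dimension
#'   (n x 3, n >= 3), coordinates in Angstrom.
#' @return A `superposition` object: `rotation` (3 x 3, det +1),
#'   `translation` (length-3), and `rmsd` (Angstrom) of the transformed
#'   mobile set against the reference.
#' @examples
#' ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' kabsch_superpose(ref, ref)$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- as.matrix(mobile)
  Q <- as.matrix(reference)
  if (!identical(dim(P), dim(Q)))
    stop("mobile and reference must have the same number of points")
  if (ncol(P) != 3L)
    stop("coordinates must be n x 3 matrices")
  if (nrow(P) < 3L)
    stop("superposition needs at least 3 points")
  cm <- colMeans(P)
  cr <- colMeans(Q)
  Pc <- sweep(P, 2L, cm)
  Qc <- sweep(Q, 2L, cr)
  if (max(abs(Pc)) < 1e-12 || max(abs(Qc)) < 1e-12)
    stop("degenerate input: all points coincident")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.vector(cr - R %*% cm)
  mapped <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((mapped - Qc)^2)))
  structure(list(rotation = R, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid superposition to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param sup a `superposition` from [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2L, sup$translation, "+")
}

plain_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Selective RMSD after alignment on a chosen atom set
#'
#' Superposes `frame` onto `reference` using only the `align_on` atoms,
#' applies that transform to the whole frame, and evaluates the RMSD over
#' the `measure_on` atoms. The default selections follow the convention
#' used for trajectory analysis of a protein--ligand complex: align on
#' the protein C-alpha trace, measure over C-alpha plus ligand heavy
#' atoms, so the measured value reflects ligand motion relative to the
#' protein frame.
#'
#' @param frame,reference `labeled_structure` objects sharing a topology.
#' @param align_on,measure_on character vectors of role tokens (see
#'   [labeled_structure()]).
#' @return RMSD in Angstrom.
#' @export
rmsd_selective <- function(frame, reference,
                           align_on = "protein-calpha",
                           measure_on = c("protein-calpha", "ligand-heavy")) {
  if (!same_topology(frame, reference))
    stop("frame and reference do not share a topology")
  ai <- which(role_mask(frame$atoms, align_on))
  mi <- which(role_mask(frame$atoms, measure_on))
  if (length(ai) == 0L || length(mi) == 0L)
    stop("empty atom selection")
  sup <- kabsch_superpose(frame$xyz[ai, , drop = FALSE],
                          reference$xyz[ai, , drop = FALSE])
  moved <- apply_superposition(frame$xyz, sup)
  plain_rmsd(moved[mi, , drop = FALSE], reference$xyz[mi, , drop = FALSE])
}
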