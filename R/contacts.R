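#' Per-residue ligand contact probabilities
#'
#' For each protein residue, the fraction of frames in which any heavy
#' atom of that residue lies within `cutoff` of any ligand heavy atom
#' (hydrogens excluded on both sides, distances inclusive of the cutoff).
#' Also records the ensemble bound fraction: the fraction of frames in
#' which *any* protein heavy atom is within `cutoff` of any ligand heavy
#' atom, i.e. the time fraction the ligand spends bound anywhere on the
#' protein. By set containment the bound fraction is always at least the
#' largest per-residue probability.
#'
#' @param ensemble an `md_ensemble` containing at least one ligand heavy
#'   atom and one protein residue.
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @return A `contact_profile`: data.frame with `resno`, `resid`,
#'   `probability` and `category`, plus attributes `bound_fraction` and
#'   `cutoff`.
#' @export
residue_contact_probability <- function(ensemble, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  top <- ensemble$topology
  pi_ <- which(role_mask(top, "protein-heavy"))
  li <- which(role_mask(top, "ligand-heavy"))
  if (length(li) == 0L) stop("ensemble contains no ligand heavy atoms")
  if (length(pi_) == 0L) stop("ensemble contains no protein heavy atoms")
  reskey <- paste(top$chain[pi_], top$resno[pi_])
  resf <- factor(reskey, levels = unique(reskey))
  nf <- n_frames(ensemble)
  nres <- nlevels(resf)
  hits <- matrix(0L, nres, nf)
  bound <- logical(nf)
  cut2 <- cutoff^2
  for (f in seq_len(nf)) {
    px <- ensemble$coords[pi_, , f, drop = FALSE][, , 1, drop = TRUE]
    lx <- ensemble$coords[li, , f, drop = FALSE][, , 1, drop = TRUE]
    px <- matrix(px, ncol = 3L)
    lx <- matrix(lx, ncol = 3L)
    d2 <- outer(rowSums(px^2), rowSums(lx^2), "+") - 2 * tcrossprod(px, lx)
    amin <- apply(d2, 1L, min)             # per protein atom, min over ligand
    rmin <- tapply(amin, resf, min)        # per residue
    hits[, f] <- as.integer(rmin <= cut2)
    bound[f] <- min(amin) <= cut2
  }
  first <- match(levels(resf), reskey)
  prob <- rowMeans(hits)
  out <- data.frame(resno = top$resno[pi_][first],
                    resid = top$resid[pi_][first],
                    probability = prob,
                    category = categorize_contacts(prob),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, bound_fraction = mean(bound), cutoff = cutoff,
            class = c("contact_profile", "data.frame"))
}

#' Ensemble bound fraction
#'
#' Fraction of frames in which any ligand heavy atom is within `cutoff`
#' of any protein heavy atom.
#'
#' @inheritParams residue_contact_probability
#' @return Numeric scalar in \[0, 1\].
#' @export
bound_fraction <- function(ensemble, cutoff = 4.0) {
  attr(residue_contact_probability(ensemble, cutoff), "bound_fraction")
}

#' Contact-probability categories
#'
#' Bins fractional probabilities into `low` (< 20\%), `moderate`
#' (20--50\%, both ends inclusive) and `high` (> 50\%). The high bin is
#' strictly above 50\%; exactly 20\% falls in `moderate`.
#'
#' @param probability numeric vector of fractions in \[0, 1\], or a
#'   `contact_profile`.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
categorize_contacts <- function(probability) {
  if (inherits(probability, "contact_profile"))
    probability <- probability$probability
  if (any(probability < 0 | probability > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  factor(ifelse(probability > 0.5, "high",
                ifelse(probability >= 0.2, "moderate", "low")),
         levels = c("low", "moderate", "high"))
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("Contact profile: %d residues, cutoff %.1f A, bound fraction %.4f\n",
              nrow(x), attr(x, "cutoff"), attr(x, "bound_fraction")))
  print.data.frame(x, ...)
  invisible(x)
}
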