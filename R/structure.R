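#' Labelled molecular structure
#'
#' A single conformation of a protein--ligand complex in which every atom
#' carries a role tag used by all downstream selections. Roles are:
#' \describe{
#'   \item{`protein-calpha`}{protein C-alpha atoms}
#'   \item{`protein-heavy`}{protein heavy atoms other than C-alpha}
#'   \item{`ligand-heavy`}{ligand (HETATM, non-water) heavy atoms}
#'   \item{`hydrogen`}{hydrogens on either molecule}
#' }
#' In a selection, the token `protein-heavy` means *all* protein heavy atoms
#' (C-alpha included); use `protein-calpha` for the backbone trace alone.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`
#'   (atom name), `elem` (element symbol) and `role`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return An object of class `labeled_structure`.
#' @export
labeled_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L)
    stop("xyz must have three columns (x, y, z)")
  if (nrow(atoms) != nrow(xyz))
    stop("atoms and xyz describe different numbers of atoms")
  if (!all(is.finite(xyz)))
    stop("all coordinates must be finite")
  needed <- c("chain", "resno", "resid", "elety", "elem", "role")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  ok <- atoms$role %in% c("protein-calpha", "protein-heavy",
                          "ligand-heavy", "hydrogen")
  if (!all(ok))
    stop("unknown role(s): ", paste(unique(atoms$role[!ok]), collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$resno <- as.integer(atoms$resno)
  structure(list(atoms = atoms, xyz = xyz),
            class = "labeled_structure")
}

#' @export
print.labeled_structure <- function(x, ...) {
  tab <- table(x$atoms$role)
  cat("Labelled structure:", nrow(x$xyz), "atoms (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
  invisible(x)
}

# Logical mask over atoms for a set of role tokens. "protein-heavy"
# expands to calpha + other protein heavy atoms (calpha IS a heavy atom).
role_mask <- function(atoms, roles) {
  roles <- match.arg(roles,
                     c("protein-calpha", "protein-heavy", "ligand-heavy",
                       "hydrogen"),
                     several.ok = TRUE)
  expanded <- roles
  if ("protein-heavy" %in% roles)
    expanded <- union(expanded, "protein-calpha")
  atoms$role %in% expanded
}

#' Select atom indices by role
#'
#' @param x a `labeled_structure` or `md_ensemble`.
#' @param roles character vector of role tokens (see
#'   [labeled_structure()]).
#' @return Integer vector of atom indices.
#' @export
select_roles <- function(x, roles) {
  atoms <- if (inherits(x, "md_ensemble")) x$topology else x$atoms
  which(role_mask(atoms, roles))
}

same_topology <- function(a, b) {
  nrow(a$atoms) == nrow(b$atoms) &&
    identical(a$atoms$resno, b$atoms$resno) &&
    identical(a$atoms$elety, b$atoms$elety) &&
    identical(a$atoms$role, b$atoms$role)
}

#' Conformational ensemble
#'
#' An ordered set of frames sharing one topology, e.g. an MD trajectory
#' (or several concatenated runs) of a protein--ligand complex.
#'
#' @param topology atom table as in [labeled_structure()].
#' @param coords numeric array `n_atoms x 3 x n_frames` in Angstrom.
#' @param frame_interval time between frames in ps (metadata only;
#'   default 10 ps).
#' @param run_starts integer vector of frame indices where concatenated
#'   runs begin (metadata only).
#' @return An object of class `md_ensemble`.
#' @export
md_ensemble <- function(topology, coords, frame_interval = 10,
                        run_starts = 1L) {
  coords <- if (length(dim(coords)) == 2L)
    array(coords, dim = c(dim(coords), 1L)) else coords
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[3] < 1L)
    stop("ensemble must contain at least one frame")
  if (nrow(topology) != dim(coords)[1])
    stop("topology and coords disagree on atom count")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  topology$resno <- as.integer(topology$resno)
  structure(list(topology = topology,
                 coords = coords,
                 frame_interval = frame_interval,
                 run_starts = as.integer(run_starts)),
            class = "md_ensemble")
}

#' Number of frames in an ensemble
#' @param ensemble an `md_ensemble`.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Extract one frame as a labelled structure
#' @param ensemble an `md_ensemble`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(ensemble, i) {
  if (i < 1L || i > n_frames(ensemble))
    stop("frame index out of range")
  labeled_structure(ensemble$topology, ensemble$coords[, , i])
}

#' @export
print.md_ensemble <- function(x, ...) {
  cat("Ensemble:", n_frames(x), "frames x", nrow(x$topology), "atoms;",
      "frame interval", x$frame_interval, "ps;",
      length(x$run_starts), "run(s)\n")
  invisible(x)
}
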