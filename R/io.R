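#' Backbone amide peak list
#'
#' One row per residue of a 1H-15N correlation spectrum: residue number,
#' one-letter residue label, proton and nitrogen shifts in ppm, and a
#' status (`observed`, `unassigned`, or `proline` -- the latter two have
#' no backbone NH peak and carry `NA` shifts).
#'
#' @param resno integer residue numbers (unique).
#' @param resid one-letter residue codes.
#' @param w_h,w_n 1H and 15N shifts, ppm (`NA` unless observed).
#' @param status per-residue status.
#' @return A `peak_list` data.frame.
#' @export
peak_list <- function(resno, resid, w_h, w_n,
                      status = rep("observed", length(resno))) {
  if (anyDuplicated(resno))
    stop("residue numbers must be unique")
  ok <- status %in% c("observed", "unassigned", "proline")
  if (!all(ok)) stop("unknown status value(s)")
  obs <- status == "observed"
  if (any(obs & (!is.finite(w_h) | !is.finite(w_n))))
    stop("observed residues must have finite shifts")
  out <- data.frame(resno = as.integer(resno), resid = resid,
                    w_h = as.numeric(w_h), w_n = as.numeric(w_n),
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Read a Sparky-style peak list
#'
#' Whitespace-delimited text, one row per residue: an assignment label
#' then the 1H and 15N shifts in ppm (e.g. `T200N-H 8.123 120.452`).
#' `#` starts a comment. Unobservable rows use `-` in the shift columns:
#' prolines are written as e.g. `P211 - -` and unassigned residues as
#' `*190* - -`.
#'
#' @param path input file.
#' @return A `peak_list`.
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  resno <- integer(0); resid <- character(0)
  w_h <- w_n <- numeric(0); status <- character(0)
  for (ln in keep) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) != 3L)
      stop(sprintf("%s:%d: expected 3 fields, found %d",
                   path, ln, length(tok)))
    lab <- tok[1L]
    if (grepl("^\\*[0-9]+\\*$", lab)) {
      resno <- c(resno, as.integer(gsub("\\*", "", lab)))
      resid <- c(resid, "X"); w_h <- c(w_h, NA); w_n <- c(w_n, NA)
      status <- c(status, "unassigned")
      next
    }
    m <- regmatches(lab, regexec("^([A-Za-z])([0-9]+)", lab))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("%s:%d: malformed assignment '%s'", path, ln, lab))
    resno <- c(resno, as.integer(m[3L]))
    resid <- c(resid, toupper(m[2L]))
    if (tok[2L] == "-" || tok[3L] == "-") {
      w_h <- c(w_h, NA); w_n <- c(w_n, NA)
      status <- c(status,
                  if (toupper(m[2L]) == "P") "proline" else "unassigned")
    } else {
      h <- suppressWarnings(as.numeric(tok[2L]))
      nn <- suppressWarnings(as.numeric(tok[3L]))
      if (is.na(h) || is.na(nn))
        stop(sprintf("%s:%d: non-numeric shift", path, ln))
      w_h <- c(w_h, h); w_n <- c(w_n, nn)
      status <- c(status, "observed")
    }
  }
  if (anyDuplicated(resno))
    stop(sprintf("%s: duplicate residue number(s): %s", path,
                 paste(unique(resno[duplicated(resno)]), collapse = ", ")))
  peak_list(resno, resid, w_h, w_n, status)
}

#' Write a Sparky-style peak list
#'
#' @param x a `peak_list`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_peaklist <- function(x, path) {
  lines <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    lines[i] <- switch(x$status[i],
      observed = sprintf("%s%dN-H %.3f %.3f", x$resid[i], x$resno[i],
                         x$w_h[i], x$w_n[i]),
      proline = sprintf("P%d - -", x$resno[i]),
      unassigned = sprintf("*%d* - -", x$resno[i]))
  }
  writeLines(c("# assignment  w_1H(ppm)  w_15N(ppm)", lines), path)
  invisible(path)
}

solvent_resids <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD",
                    "NA", "CL", "K", "MG", "ZN", "CA2")

standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE", "HSD", "HSE", "HSP")

assign_roles <- function(atom) {
  elem <- toupper(trimws(atom$elesy))
  elem[is.na(elem) | elem == ""] <- NA
  # fallback when the element column is absent: H/1H/2H/3H name prefixes
  name_h <- grepl("^[123]?H", trimws(atom$elety))
  is_h <- ifelse(is.na(elem), name_h, elem == "H")
  # ligand = HETATM or non-standard residue, water/ions excluded (some
  # writers emit ligands as ATOM records in multi-model files)
  is_lig <- (atom$type == "HETATM" | !(atom$resid %in% standard_aa)) &
    !(atom$resid %in% solvent_resids)
  ifelse(is_h, "hydrogen",
         ifelse(is_lig, "ligand-heavy",
                ifelse(trimws(atom$elety) == "CA", "protein-calpha",
                       "protein-heavy")))
}

pdb_to_parts <- function(pdb) {
  atom <- pdb$atom
  drop <- atom$type == "HETATM" & atom$resid %in% solvent_resids
  atom <- atom[!drop, , drop = FALSE]
  topo <- data.frame(chain = ifelse(is.na(atom$chain), "A", atom$chain),
                     resno = atom$resno,
                     resid = atom$resid,
                     elety = atom$elety,
                     elem = ifelse(is.na(atom$elesy) | atom$elesy == "",
                                   substr(trimws(atom$elety), 1L, 1L),
                                   trimws(atom$elesy)),
                     role = assign_roles(atom),
                     stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  keep_idx <- which(!drop)
  cols <- as.vector(rbind(3 * keep_idx - 2, 3 * keep_idx - 1, 3 * keep_idx))
  xyz <- xyz[, cols, drop = FALSE]
  list(topology = topo, xyz = xyz)
}

xyz_rows_to_array <- function(xyz) {
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  coords <- array(0, dim = c(na, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  coords
}

#' Read a conformational ensemble from PDB
#'
#' Accepts either a multi-model PDB file (MODEL/ENDMDL records, frames
#' in model order) or a directory of single-model PDB files taken in
#' lexicographic order. Roles are assigned from the records: HETATM
#' residues other than water/ions are the ligand, hydrogens are
#' identified by the element column (falling back to H/1H/2H/3H name
#' prefixes), `CA`-named protein atoms are the C-alpha trace. Solvent
#' is dropped. Residue numbering is taken verbatim.
#'
#' @param path PDB file or directory of `.pdb` files.
#' @param frame_interval time per frame in ps (metadata, default 10).
#' @return An `md_ensemble`.
#' @export
read_ensemble <- function(path, frame_interval = 10) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) == 0L) stop("no .pdb files in ", path)
    parts <- lapply(files, function(f)
      pdb_to_parts(bio3d::read.pdb(f, verbose = FALSE)))
    topo <- parts[[1L]]$topology
    for (p in parts[-1L])
      if (!identical(p$topology$elety, topo$elety) ||
          !identical(p$topology$resno, topo$resno))
        stop("inconsistent topology across PDB files")
    xyz <- do.call(rbind, lapply(parts, `[[`, "xyz"))
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    p <- pdb_to_parts(pdb)
    topo <- p$topology
    xyz <- p$xyz
  }
  md_ensemble(topo, xyz_rows_to_array(xyz), frame_interval = frame_interval)
}

#' Read a single structure from PDB
#'
#' First model only; same role assignment as [read_ensemble()].
#'
#' @param path PDB file.
#' @return A `labeled_structure`.
#' @export
read_structure <- function(path) {
  p <- pdb_to_parts(bio3d::read.pdb(path, verbose = FALSE))
  labeled_structure(p$topology, matrix(p$xyz[1L, ], ncol = 3L, byrow = TRUE))
}

#' Write a labelled structure to PDB
#'
#' @param structure a `labeled_structure`.
#' @param path output PDB path.
#' @param b optional per-atom B-factor column values (e.g. category
#'   codes).
#' @return The path, invisibly.
#' @export
write_structure_pdb <- function(structure, path, b = NULL) {
  at <- structure$atoms
  if (is.null(b)) b <- rep(0, nrow(at))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$xyz)),
                   type = ifelse(at$role == "ligand-heavy", "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, b = b, elesy = at$elem)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB
#'
#' @param ensemble an `md_ensemble`.
#' @param path output PDB path.
#' @return The path, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  at <- ensemble$topology
  nf <- n_frames(ensemble)
  xyz <- t(vapply(seq_len(nf),
                  function(f) as.vector(t(ensemble$coords[, , f])),
                  numeric(3L * nrow(at))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(at$role == "ligand-heavy", "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, elesy = at$elem)
  invisible(path)
}

#' Read/write per-injection thermogram CSV
#'
#' Columns `injection`, `volume` (uL), `heat` (ucal).
#'
#' @param path CSV path.
#' @param protocol an `itc_protocol` to attach (needed for
#'   normalisation and fitting).
#' @return An `itc_thermogram`.
#' @export
read_thermogram <- function(path, protocol = NULL) {
  d <- utils::read.csv(path)
  need <- c("injection", "volume", "heat")
  if (!all(need %in% names(d)))
    stop("thermogram CSV needs columns: ", paste(need, collapse = ", "))
  if (is.null(protocol))
    protocol <- itc_protocol(injections = d$volume)
  new_thermogram(d$heat, protocol)
}

#' @rdname read_thermogram
#' @param x an `itc_thermogram`.
#' @export
write_thermogram <- function(x, path) {
  utils::write.csv(data.frame(injection = x$injection, volume = x$volume,
                              heat = x$heat),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read/write an ITC protocol as a flat key-value config
#'
#' Lines `key = value`; keys `V0`, `M0`, `X0`, `temperature`, and
#' `injections` (comma-separated uL volumes).
#'
#' @param path config path.
#' @return An `itc_protocol`.
#' @export
read_protocol <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- do.call(rbind, strsplit(lines, "\\s*=\\s*"))
  vals <- stats::setNames(kv[, 2L], trimws(kv[, 1L]))
  itc_protocol(V0 = as.numeric(vals[["V0"]]),
               M0 = as.numeric(vals[["M0"]]),
               X0 = as.numeric(vals[["X0"]]),
               injections = as.numeric(strsplit(vals[["injections"]],
                                                ",")[[1L]]),
               temperature = as.numeric(vals[["temperature"]]))
}

#' @rdname read_protocol
#' @param protocol an `itc_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  writeLines(c(sprintf("V0 = %g", protocol$V0),
               sprintf("M0 = %g", protocol$M0),
               sprintf("X0 = %g", protocol$X0),
               sprintf("temperature = %g", protocol$temperature),
               sprintf("injections = %s",
                       paste(protocol$injections, collapse = ","))),
             path)
  invisible(path)
}

#' Write a contact-probability report CSV
#'
#' @param profile a `contact_profile`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_contact_report <- function(profile, path) {
  d <- as.data.frame(profile)
  d$percent <- 100 * d$probability
  utils::write.csv(d[, c("resno", "resid", "probability", "percent",
                         "category")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a chemical-shift-perturbation report CSV
#'
#' @param table a `csp_table`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_csp_report <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
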