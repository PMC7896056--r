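#' Combined amide chemical-shift perturbation
#'
#' The weighted combined shift change between free and bound backbone
#' amide resonances,
#' \deqn{\delta\Delta = \sqrt{\delta\Delta_{HN}^2 +
#'       0.25\,\delta\Delta_{15N}^2},}
#' where the 0.25 weighting compensates the wider dispersion of the
#' nitrogen dimension. Even in both arguments, so the free-minus-bound
#' sign convention does not affect the result.
#'
#' @param d_hn proton shift difference, ppm (free minus bound).
#' @param d_n nitrogen-15 shift difference, ppm (free minus bound).
#' @return Combined perturbation in ppm, same length as the inputs.
#' @examples
#' compute_csp(0.03, 0.20)  # 0.1044031
#' @export
compute_csp <- function(d_hn, d_n) {
  if (length(d_hn) != length(d_n))
    stop("d_hn and d_n must have equal length")
  sqrt(d_hn^2 + 0.25 * d_n^2)
}

#' Classify chemical-shift perturbations
#'
#' Bins combined perturbations into `none` (0.00--0.04 ppm, upper bound
#' exclusive), `moderate` (0.04--0.08 ppm, both bounds inclusive) and
#' `large` (> 0.08 ppm).
#'
#' @param ddelta non-negative combined perturbations in ppm; `NA` maps to
#'   `unobservable`.
#' @return Factor with levels `none`, `moderate`, `large`, `unobservable`.
#' @export
classify_csp <- function(ddelta) {
  if (any(ddelta < 0, na.rm = TRUE))
    stop("combined perturbations cannot be negative")
  out <- ifelse(is.na(ddelta), "unobservable",
                ifelse(ddelta > 0.08, "large",
                       ifelse(ddelta >= 0.04, "moderate", "none")))
  factor(out, levels = c("none", "moderate", "large", "unobservable"))
}

#' Pair free and bound peak lists by residue number
#'
#' Residues present and observed in both lists are paired for
#' perturbation analysis; residues missing from either list, unassigned,
#' or proline are carried through with status `unobservable` and excluded
#' from the perturbation computation.
#'
#' @param free,bound `peak_list` objects (see [read_peaklist()] /
#'   [make_peaklists()]) on the same residue numbering.
#' @return data.frame with one row per residue seen in either list:
#'   `resno`, `resid`, `h_free`, `n_free`, `h_bound`, `n_bound`, and
#'   `status` (`observed` or `unobservable`).
#' @export
match_peaks <- function(free, bound) {
  for (pl in list(free, bound))
    if (anyDuplicated(pl$resno))
      stop("duplicate residue numbers in peak list")
  resno <- sort(union(free$resno, bound$resno))
  fi <- match(resno, free$resno)
  bi <- match(resno, bound$resno)
  obs <- function(pl, idx)
    !is.na(idx) & pl$status[ifelse(is.na(idx), 1L, idx)] == "observed"
  both <- obs(free, fi) & obs(bound, bi)
  resid <- ifelse(!is.na(fi), free$resid[ifelse(is.na(fi), 1L, fi)],
                  bound$resid[ifelse(is.na(bi), 1L, bi)])
  data.frame(resno = resno, resid = resid,
             h_free = ifelse(both, free$w_h[fi], NA_real_),
             n_free = ifelse(both, free$w_n[fi], NA_real_),
             h_bound = ifelse(both, bound$w_h[bi], NA_real_),
             n_bound = ifelse(both, bound$w_n[bi], NA_real_),
             status = ifelse(both, "observed", "unobservable"),
             stringsAsFactors = FALSE)
}

#' Chemical-shift-perturbation table from free/bound peak lists
#'
#' Pairs the two lists, computes per-residue shift differences
#' (free minus bound), the combined perturbation and its category.
#'
#' @inheritParams match_peaks
#' @return A `csp_table`: data.frame with `resno`, `resid`, `d_hn`,
#'   `d_n`, `ddelta`, `category`.
#' @export
csp_table <- function(free, bound) {
  m <- match_peaks(free, bound)
  d_hn <- m$h_free - m$h_bound
  d_n <- m$n_free - m$n_bound
  dd <- compute_csp(d_hn, d_n)
  out <- data.frame(resno = m$resno, resid = m$resid,
                    d_hn = d_hn, d_n = d_n, ddelta = dd,
                    category = classify_csp(dd),
                    stringsAsFactors = FALSE)
  class(out) <- c("csp_table", "data.frame")
  out
}

#' @export
print.csp_table <- function(x, ...) {
  tab <- table(x$category)
  cat("CSP table:", nrow(x), "residues (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

# numeric codes written into the B-factor column when mapping categories
# onto a structure: unobservable/-absent -1, none 0, moderate 1, large 2
csp_category_code <- function(category) {
  codes <- c(none = 0, moderate = 1, large = 2, unobservable = -1)
  unname(codes[as.character(category)])
}

#' Map perturbation categories onto a structure file
#'
#' Writes a copy of the structure in PDB format with each residue's
#' perturbation category encoded as a numeric code in the B-factor
#' column (none 0, moderate 1, large 2, unobservable -1), constant
#' within each residue -- ready for colouring in a molecular viewer.
#' Table residues not present in the structure are skipped with a
#' message; structure residues absent from the table get code -1.
#'
#' @param structure a `labeled_structure`.
#' @param table a `csp_table`.
#' @param path output PDB path.
#' @return The path, invisibly.
#' @export
annotate_structure <- function(structure, table, path) {
  resno <- structure$atoms$resno
  missing <- setdiff(table$resno, unique(resno))
  if (length(missing))
    message("residues not in structure, skipped: ",
            paste(missing, collapse = ", "))
  idx <- match(resno, table$resno)
  code <- ifelse(is.na(idx), -1,
                 csp_category_code(table$category[ifelse(is.na(idx), 1L, idx)]))
  write_structure_pdb(structure, path, b = code)
  invisible(path)
}
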