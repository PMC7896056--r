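#' Ratiometric FRET ratio
#'
#' Acceptor over donor emission intensity (e.g. mRuby2 at 600 nm over
#' Clover at 515 nm under donor excitation); invariant to overall
#' detector gain.
#'
#' @param donor,acceptor positive fluorescence intensities (arbitrary
#'   units), recycled to a common length.
#' @return acceptor / donor.
#' @export
fret_ratio <- function(donor, acceptor) {
  if (any(donor <= 0) || any(acceptor <= 0))
    stop("intensities must be positive")
  acceptor / donor
}

as_group_list <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$group)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least two observations")
  lapply(groups, as.numeric)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA on a list of groups: the F
#' statistic is the between-group over within-group mean square, with
#' its p-value from the F distribution.
#'
#' @param groups named list of numeric vectors (each of length >= 2), or
#'   a data.frame with columns `value` and `group`.
#' @return List with `F`, `p`, degrees of freedom `df1`/`df2`, the
#'   within-group mean square `mse`, and the per-group summary table.
#' @export
one_way_anova <- function(groups) {
  g <- as_group_list(groups)
  value <- unlist(g, use.names = FALSE)
  fac <- factor(rep(names(g), lengths(g)), levels = names(g))
  if (stats::var(value) < .Machine$double.eps)
    stop("degenerate input: zero total variance")
  fit <- stats::aov(value ~ fac)
  tab <- stats::anova(fit)
  gs <- data.frame(group = names(g), n = lengths(g),
                   mean = vapply(g, mean, numeric(1)),
                   sd = vapply(g, stats::sd, numeric(1)),
                   row.names = NULL)
  list(F = tab$`F value`[1L], p = tab$`Pr(>F)`[1L],
       df1 = tab$Df[1L], df2 = tab$Df[2L],
       mse = tab$`Mean Sq`[2L], groups = gs)
}

#' Tukey HSD comparison with compact letter display
#'
#' All pairwise group comparisons after a one-way ANOVA, adjusted with
#' the studentized range distribution (Tukey--Kramer harmonic form for
#' unbalanced groups), plus a compact letter display: groups sharing a
#' letter are exactly those whose adjusted p-value is at least `alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha significance level for the letter display (default
#'   0.05).
#' @return A `group_comparison` object: per-group table (with letters),
#'   ANOVA `F`/`p`, and the pairwise table with Tukey-adjusted
#'   p-values.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  g <- as_group_list(groups)
  aov_res <- one_way_anova(g)
  k <- length(g)
  means <- vapply(g, mean, numeric(1))
  ns <- lengths(g)
  pairs <- utils::combn(k, 2L)
  diff <- means[pairs[1L, ]] - means[pairs[2L, ]]
  se_q <- sqrt(aov_res$mse / 2 * (1 / ns[pairs[1L, ]] + 1 / ns[pairs[2L, ]]))
  q <- abs(diff) / se_q
  p_adj <- stats::ptukey(q, nmeans = k, df = aov_res$df2,
                         lower.tail = FALSE)
  pw <- data.frame(group1 = names(g)[pairs[1L, ]],
                   group2 = names(g)[pairs[2L, ]],
                   diff = diff, se = se_q * sqrt(2), q = q,
                   p_adj = p_adj, significant = p_adj < alpha,
                   row.names = NULL)
  sig <- matrix(FALSE, k, k)
  sig[t(pairs)] <- pw$significant
  sig <- sig | t(sig)
  letters_by_group <- compact_letters(names(g), means, sig)
  gs <- aov_res$groups
  gs$letters <- letters_by_group[gs$group]
  structure(list(groups = gs, F = aov_res$F, p = aov_res$p,
                 df1 = aov_res$df1, df2 = aov_res$df2,
                 mse = aov_res$mse, pairwise = pw, alpha = alpha),
            class = "group_comparison")
}

# Compact letter display by insert-and-absorb: start from one letter
# shared by all groups; for every significantly different pair split any
# letter column containing both, then drop columns that became subsets
# of another. Groups are processed in order of decreasing mean (ties by
# label order) so output is deterministic.
compact_letters <- function(labels, means, sig) {
  k <- length(labels)
  ord <- order(-means, labels)
  cols <- list(seq_len(k))
  sig_pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(sig_pairs))) {
    i <- sig_pairs[r, 1L]; j <- sig_pairs[r, 2L]
    new_cols <- list()
    for (col in cols) {
      if (i %in% col && j %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
      } else new_cols <- c(new_cols, list(col))
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) for (b in seq_along(new_cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_cols[[a]] %in% new_cols[[b]]) &&
          !(all(new_cols[[b]] %in% new_cols[[a]]) && a < b))
        keep[a] <- FALSE
    }
    cols <- new_cols[keep]
  }
  # order letters by the best-ranked group they contain
  first_rank <- vapply(cols, function(col) min(match(col, ord)), numeric(1))
  cols <- cols[order(first_rank)]
  out <- vapply(seq_len(k), function(gi) {
    paste(letters[which(vapply(cols, function(col) gi %in% col,
                               logical(1)))], collapse = "")
  }, character(1))
  stats::setNames(out, labels)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  cat(sprintf("Tukey HSD at alpha = %g (same letter: not significantly different)\n",
              x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' @export
summary.group_comparison <- function(object, ...) {
  print(object)
  cat("\nPairwise comparisons:\n")
  print(object$pairwise, row.names = FALSE)
  invisible(object)
}

#' Compare FRET ratios across conditions
#'
#' Computes per-replicate FRET ratios and runs the one-way ANOVA +
#' Tukey HSD comparison with compact letters.
#'
#' @param data data.frame with columns `group` and either `ratio` or
#'   both `donor` and `acceptor`.
#' @param alpha significance level (default 0.05).
#' @return A `group_comparison` (see [tukey_hsd()]).
#' @export
fret_compare <- function(data, alpha = 0.05) {
  if (!"ratio" %in% names(data)) {
    if (!all(c("donor", "acceptor") %in% names(data)))
      stop("data needs a 'ratio' column or 'donor' and 'acceptor' columns")
    data$ratio <- fret_ratio(data$donor, data$acceptor)
  }
  groups <- split(data$ratio, factor(data$group, levels = unique(data$group)))
  tukey_hsd(groups, alpha = alpha)
}
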