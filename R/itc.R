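#' ITC titration protocol
#'
#' Describes an isothermal titration calorimetry experiment on a
#' constant-volume (overflow) cell. Defaults reproduce a typical
#' MicroCal iTC200 peptide titration: a 200 uL cell holding 10 uM
#' macromolecule, 20 injections (one 0.4 uL pre-injection then 19 x
#' 2.0 uL) of 500 uM titrant, at 25 C.
#'
#' @param V0 cell volume, uL.
#' @param M0 macromolecule concentration in the cell, uM.
#' @param X0 titrant concentration in the syringe, uM.
#' @param injections ordered injection volumes, uL (>= 2).
#' @param temperature cell temperature, C (metadata).
#' @return An `itc_protocol` object.
#' @export
itc_protocol <- function(V0 = 200, M0 = 10, X0 = 500,
                         injections = c(0.4, rep(2.0, 19)),
                         temperature = 25) {
  stopifnot(V0 > 0, M0 > 0, X0 > 0, all(injections > 0),
            length(injections) >= 2L)
  structure(list(V0 = V0, M0 = M0, X0 = X0,
                 injections = as.numeric(injections),
                 temperature = temperature),
            class = "itc_protocol")
}

#' @export
print.itc_protocol <- function(x, ...) {
  cat(sprintf(
    "ITC protocol: %.0f uL cell, %.3g uM macromolecule, %.3g uM titrant,\n  %d injections (%s uL) at %.0f C\n",
    x$V0, x$M0, x$X0, length(x$injections),
    paste(format(unique(x$injections)), collapse = "/"), x$temperature))
  invisible(x)
}

#' Cell concentrations after each injection
#'
#' Tracks macromolecule and titrant concentrations in a constant-volume
#' cell under the continuous-perfusion (instant mixing) model: an
#' injection of volume dV displaces an equal volume of well-mixed cell
#' content, so each species relaxes toward the syringe composition as
#' `c' = c_in + (c - c_in) * exp(-dV/V0)` (c_in = 0 for the
#' macromolecule, X0 for the titrant). This is the limit of step-by-step
#' mole bookkeeping with infinitesimal injection increments; the common
#' dV/2V0 correction agrees to first order.
#'
#' @param protocol an `itc_protocol`.
#' @param i injection index, 0..n (0 = before any injection).
#' @return Named numeric vector `c(M = , X = )` in uM.
#' @export
concentrations_after_injection <- function(protocol, i) {
  n <- length(protocol$injections)
  if (i < 0 || i > n) stop("injection index out of range")
  cc <- cell_concentrations(protocol)
  c(M = cc$M[i + 1L], X = cc$X[i + 1L])
}

# concentrations after injections 0..n as vectors of length n+1
cell_concentrations <- function(protocol) {
  f <- exp(-cumsum(protocol$injections) / protocol$V0)
  list(M = protocol$M0 * c(1, f),
       X = protocol$X0 * (1 - c(1, f)))
}

# equilibrium complex concentration (uM) for total macromolecule sites
# n_sites = N*M and total titrant X, single-site mass action with
# dissociation constant kd (uM); numerically safe form of the quadratic
complex_concentration <- function(M, X, N, kd) {
  a <- N * M + X + kd
  disc <- a^2 - 4 * N * M * X
  disc[disc < 0] <- 0            # guard tiny negative round-off
  # subtraction-safe root: 2*N*M*X / (a + sqrt(disc))
  2 * N * M * X / (a + sqrt(disc))
}

# noise-free per-injection heats in ucal for a one-site model.
# Heat i = DH * (change in moles of complex formed), with the material
# displaced during injection i accounted for by the trapezoid term.
one_site_heats <- function(protocol, N, kd, dH) {
  cc <- cell_concentrations(protocol)
  C <- complex_concentration(cc$M, cc$X, N, kd)   # uM, after inj 0..n
  dV <- protocol$injections
  V0 <- protocol$V0
  n <- length(dV)
  i1 <- seq_len(n) + 1L
  i0 <- seq_len(n)
  # uM * uL = 1e-12 mol; * kcal/mol = 1e-12 kcal = 1e-3 ucal
  dH * 1e-3 * (V0 * (C[i1] - C[i0]) + dV * (C[i1] + C[i0]) / 2)
}

#' Simulate a one-site ITC thermogram
#'
#' Generates per-injection integrated heats from the single-site binding
#' isotherm: at each step the bound-complex concentration solves the
#' mass-action quadratic at the current cell composition, and the
#' injection heat is the enthalpy of the change in complex, with the
#' displaced-volume correction of the overflow cell. Optional additive
#' i.i.d. Gaussian noise on the heats; a seed is then mandatory so
#' simulations are reproducible.
#'
#' @param protocol an `itc_protocol`.
#' @param N stoichiometry (sites per macromolecule).
#' @param kd dissociation constant, uM (> 0).
#' @param dH binding enthalpy, kcal/mol (negative = exothermic).
#' @param noise_sd Gaussian noise standard deviation on the integrated
#'   heats, ucal (default 0).
#' @param seed integer RNG seed; required when `noise_sd > 0`.
#' @return An `itc_thermogram`: data.frame with `injection`, `volume`
#'   (uL) and `heat` (ucal); the protocol and planted parameters are
#'   attached as attributes.
#' @export
simulate_titration <- function(protocol, N = 1, kd, dH,
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(protocol, "itc_protocol"))
  if (kd <= 0) stop("dissociation constant must be positive")
  if (N <= 0) stop("stoichiometry must be positive")
  q <- one_site_heats(protocol, N, kd, dH)
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("a seed is required for noisy simulation")
    set.seed(seed)
    q <- q + stats::rnorm(length(q), 0, noise_sd)
  }
  new_thermogram(q, protocol,
                 params = c(N = N, kd = kd, dH = dH, noise_sd = noise_sd))
}

new_thermogram <- function(heat, protocol, params = NULL) {
  out <- data.frame(injection = seq_along(heat),
                    volume = protocol$injections,
                    heat = as.numeric(heat))
  structure(out, protocol = protocol, params = params,
            class = c("itc_thermogram", "data.frame"))
}

#' Subtract a blank titration from a sample thermogram
#'
#' Element-wise subtraction of background heats (titrant into buffer,
#' same schedule) from a sample thermogram.
#'
#' @param sample,blank `itc_thermogram` objects of equal length on the
#'   same schedule.
#' @return Corrected `itc_thermogram`.
#' @export
subtract_background <- function(sample, blank) {
  if (nrow(sample) != nrow(blank))
    stop("sample and blank have different injection counts")
  if (!isTRUE(all.equal(sample$volume, blank$volume)))
    stop("sample and blank use different injection schedules")
  new_thermogram(sample$heat - blank$heat, attr(sample, "protocol"))
}

#' Normalised heats in kcal per mole of injectant
#'
#' @param thermogram an `itc_thermogram`.
#' @param protocol its `itc_protocol` (defaults to the attached one).
#' @return Numeric vector, kcal per mol of injected titrant.
#' @export
normalized_heats <- function(thermogram, protocol = attr(thermogram, "protocol")) {
  # ucal -> kcal: 1e-9; moles injected = X0(uM)*dV(uL)*1e-12
  thermogram$heat * 1e3 / (protocol$X0 * thermogram$volume)
}

#' Fit the one-site binding isotherm to a thermogram
#'
#' Least-squares fit of normalised heats against the single-site forward
#' model of [simulate_titration()] ("one set of sites"), estimating the
#' association constant (reported as K_D), enthalpy, a constant
#' per-injection offset absorbing residual dilution heat, and optionally
#' the stoichiometry N. The first injection (typically a small
#' pre-injection) is excluded from the residuals by default. The Wiseman
#' c-value `N * M0 / K_D` is reported, with a warning below 1 -- there N
#' is poorly identified and should be fixed.
#'
#' @param thermogram an `itc_thermogram` (background-corrected).
#' @param protocol its `itc_protocol` (defaults to the attached one).
#' @param fix_n fix the stoichiometry at `start["N"]` (default 1) rather
#'   than fitting it; recommended for low-c data.
#' @param include_first include the first injection in the fit.
#' @param start optional named vector of starting values among `N`, `kd`
#'   (uM), `dH` (kcal/mol), `offset` (kcal/mol).
#' @return An `itc_fit` object with `coefficients` (N, kd, dH, offset),
#'   standard errors, the c-value and fit diagnostics. Methods:
#'   `print`, `summary`, `coef`, `vcov`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @export
fit_one_site <- function(thermogram, protocol = attr(thermogram, "protocol"),
                         fix_n = FALSE, include_first = FALSE,
                         start = NULL) {
  stopifnot(inherits(protocol, "itc_protocol"))
  if (is.unsorted(thermogram$injection))
    stop("injections must be in titration order; the forward model is sequential")
  y <- normalized_heats(thermogram, protocol)
  use <- rep(TRUE, length(y))
  if (!include_first) use[1L] <- FALSE
  if (sum(use) < 5L)
    stop("need at least 5 informative injections")
  if (all(abs(thermogram$heat[use]) < 1e-12))
    stop("all heats are zero; nothing to fit")
  s <- c(N = 1, kd = protocol$M0, dH = NA, offset = 0)
  tot <- sum(thermogram$heat)
  s["dH"] <- tot / (1e-3 * protocol$M0 * protocol$V0)  # saturation guess
  if (abs(s["dH"]) < 0.5) s["dH"] <- -1
  if (!is.null(start)) s[names(start)] <- start
  model_norm <- function(N, kd, dH, offset) {
    q <- one_site_heats(protocol, N, kd, dH)
    q * 1e3 / (protocol$X0 * protocol$injections) + offset
  }
  if (fix_n) {
    par0 <- c(lkd = log(s[["kd"]]), dH = s[["dH"]], offset = s[["offset"]])
    resid_fn <- function(p)
      model_norm(s[["N"]], exp(p[["lkd"]]), p[["dH"]], p[["offset"]])[use] - y[use]
  } else {
    par0 <- c(N = s[["N"]], lkd = log(s[["kd"]]), dH = s[["dH"]],
              offset = s[["offset"]])
    resid_fn <- function(p)
      model_norm(p[["N"]], exp(p[["lkd"]]), p[["dH"]], p[["offset"]])[use] - y[use]
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0, 9))
    warning("one-site fit did not converge: ", fit$message)
  p <- fit$par
  est <- c(N = if (fix_n) s[["N"]] else p[["N"]],
           kd = exp(p[["lkd"]]), dH = p[["dH"]], offset = p[["offset"]])
  # standard errors from local curvature, delta method for kd = exp(lkd)
  np <- length(p)
  dfres <- sum(use) - np
  sigma2 <- sum(fit$fvec^2) / max(dfres, 1L)
  vc <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) {
    matrix(NA_real_, np, np, dimnames = list(names(p), names(p)))
  })
  se_raw <- sqrt(pmax(diag(vc), 0))
  se <- c(N = if (fix_n) NA_real_ else se_raw[["N"]],
          kd = se_raw[["lkd"]] * est[["kd"]],
          dH = se_raw[["dH"]], offset = se_raw[["offset"]])
  cval <- est[["N"]] * protocol$M0 / est[["kd"]]
  if (cval < 1)
    warning(sprintf(
      "low c-value (%.2f): stoichiometry is poorly identified; consider fix_n = TRUE",
      cval))
  structure(list(coefficients = est, se = se, vcov = vc,
                 c_value = cval, fix_n = fix_n,
                 include_first = include_first,
                 fitted_norm = model_norm(est[["N"]], est[["kd"]],
                                          est[["dH"]], est[["offset"]]),
                 observed_norm = y, used = use,
                 protocol = protocol, thermogram = thermogram,
                 deviance = sum(fit$fvec^2), df.residual = dfres,
                 info = fit$info, message = fit$message,
                 niter = fit$niter),
            class = "itc_fit")
}

#' @export
coef.itc_fit <- function(object, ...) object$coefficients

#' @export
vcov.itc_fit <- function(object, ...) object$vcov

#' @export
fitted.itc_fit <- function(object, ...) object$fitted_norm

#' @export
residuals.itc_fit <- function(object, ...)
  object$observed_norm - object$fitted_norm

#' @export
predict.itc_fit <- function(object, protocol = object$protocol, ...) {
  cf <- object$coefficients
  q <- one_site_heats(protocol, cf[["N"]], cf[["kd"]], cf[["dH"]])
  q * 1e3 / (protocol$X0 * protocol$injections) + cf[["offset"]]
}

#' @export
print.itc_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("One-site ITC fit\n")
  cat(sprintf("  K_D   = %.3g uM (se %.2g)%s\n", cf[["kd"]], x$se[["kd"]],
              if (x$fix_n) ", N fixed" else ""))
  cat(sprintf("  N     = %.3g%s\n", cf[["N"]],
              if (x$fix_n) " (fixed)" else sprintf(" (se %.2g)", x$se[["N"]])))
  cat(sprintf("  dH    = %.3g kcal/mol (se %.2g)\n", cf[["dH"]],
              x$se[["dH"]]))
  cat(sprintf("  c     = %.2f%s\n", x$c_value,
              if (x$c_value < 1) "  [low c]" else ""))
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  cf <- object$coefficients
  tab <- data.frame(estimate = cf, std_error = object$se[names(cf)])
  out <- list(coefficients = tab, c_value = object$c_value,
              K_a = 1 / cf[["kd"]], deviance = object$deviance,
              df.residual = object$df.residual, fix_n = object$fix_n)
  class(out) <- "summary.itc_fit"
  out
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  cat("One-site ITC fit (\"one set of sites\")\n\n")
  print(x$coefficients)
  cat(sprintf("\nK_a = %.4g 1/uM, c = %.2f, residual SS = %.3g on %d df\n",
              x$K_a, x$c_value, x$deviance, x$df.residual))
  invisible(x)
}

#' @export
plot.itc_fit <- function(x, ...) {
  xr <- molar_ratio(x$protocol)
  plot(xr[x$used], x$observed_norm[x$used],
       xlab = "molar ratio (titrant/macromolecule)",
       ylab = "kcal/mol of injectant", ...)
  graphics::lines(xr, x$fitted_norm)
  invisible(x)
}

# titrant / macromolecule molar ratio in the cell after each injection
molar_ratio <- function(protocol) {
  cc <- cell_concentrations(protocol)
  (cc$X / cc$M)[-1L]
}

#' Dissociation-constant fold change
#'
#' Affinity enhancement as the ratio of a reference K_D to the K_D under
#' some condition (e.g. with an activator present); > 1 means the
#' condition binds more tightly. Reports print to one decimal.
#'
#' @param kd_reference,kd_condition positive dissociation constants in
#'   the same units.
#' @return The dimensionless ratio.
#' @examples
#' fold_change(55.0, 6.67)  # ~8.2
#' @export
fold_change <- function(kd_reference, kd_condition) {
  if (any(kd_reference <= 0) || any(kd_condition <= 0))
    stop("dissociation constants must be positive")
  kd_reference / kd_condition
}
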