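#' Synthetic helical protein--ligand scaffold
#'
#' A small alpha-helical C-alpha scaffold (default 49 residues numbered
#' 183--231, mirroring an N-terminal activator-binding domain) plus a
#' rigid 20-heavy-atom two-ring ligand, positioned at a given offset.
#' The scaffold is deliberately coarse (C-alpha trace only): it carries
#' the statistical structure the ensemble analyses assume -- metastable
#' ligand poses, per-residue contacts -- without pretending to be a
#' force-field model.
#'
#' @param ligand_offset length-3 numeric, position of the ligand centre
#'   in the helix frame (helix axis = z, radius 2.3 A, rise 1.5
#'   A/residue).
#' @param n_res number of residues (default 49).
#' @param start_resno first residue number (default 183).
#' @return A `labeled_structure` of the complex.
#' @export
synthetic_complex <- function(ligand_offset = c(6, 0, 30),
                              n_res = 49, start_resno = 183) {
  ang <- (seq_len(n_res) - 1) * 100 * pi / 180
  prot <- cbind(2.3 * cos(ang), 2.3 * sin(ang),
                (seq_len(n_res) - 1) * 1.5)
  resno <- seq(start_resno, length.out = n_res)
  resid <- rep("ALA", n_res)
  # ligand: two fused hexagonal rings plus an 8-atom tail, 20 heavy atoms
  hex <- function(cx) cbind(cx + 1.4 * cos(seq(0, 5) * pi / 3),
                            1.4 * sin(seq(0, 5) * pi / 3), 0)
  tail <- cbind(seq(2.8, by = 1.2, length.out = 8), 0.6, 0.4)
  lig <- rbind(hex(-1.4), hex(1.4), tail)
  lig <- sweep(lig, 2L, colMeans(lig))
  lig <- sweep(lig, 2L, ligand_offset, "+")
  atoms <- data.frame(
    chain = c(rep("A", n_res), rep("L", 20L)),
    resno = c(resno, rep(900L, 20L)),
    resid = c(resid, rep("LIG", 20L)),
    elety = c(rep("CA", n_res), sprintf("C%d", 1:20)),
    elem = "C",
    role = c(rep("protein-calpha", n_res), rep("ligand-heavy", 20L)),
    stringsAsFactors = FALSE)
  labeled_structure(atoms, rbind(prot, lig))
}

#' Specification for a synthetic conformational ensemble
#'
#' Describes an ensemble with a small number of metastable ligand
#' binding modes: frames dwell in a mode and occasionally jump
#' (first-order Markov switching with stationary distribution equal to
#' the mode weights), with isotropic Gaussian positional noise about
#' each mode's pose.
#'
#' @param n_frames number of frames.
#' @param modes list of `labeled_structure` poses sharing one topology.
#'   Default: two poses of [synthetic_complex()] whose ligand centres
#'   are ~15 A apart (bound and quasi-dissociated modes).
#' @param weights mode weights summing to 1.
#' @param switch_prob per-step probability of redrawing the mode from
#'   `weights` (default 0.1); the stationary mode distribution is
#'   `weights`.
#' @param noise_sd per-coordinate Gaussian noise, A (default 0.2; frame
#'   RMSD about a pose is then `sqrt(3) * noise_sd`).
#' @param seed integer RNG seed (required).
#' @return An `ensemble_spec` object.
#' @export
ensemble_spec <- function(n_frames = 100,
                          modes = list(synthetic_complex(c(6, 0, 30)),
                                       synthetic_complex(c(6, 12, 40))),
                          weights = c(0.6, 0.4),
                          switch_prob = 0.1,
                          noise_sd = 0.2,
                          seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("mode weights must sum to 1")
  if (length(weights) != length(modes))
    stop("one weight per mode is required")
  if (noise_sd < 0) stop("noise sd cannot be negative")
  for (m in modes[-1L])
    if (!same_topology(m, modes[[1L]]))
      stop("all mode poses must share one topology")
  structure(list(n_frames = as.integer(n_frames), modes = modes,
                 weights = weights, switch_prob = switch_prob,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ensemble_spec")
}

# independent straight-loop contact truth (same definition as the
# contact module, deliberately different code path)
truth_contacts <- function(ensemble, cutoff = 4.0) {
  top <- ensemble$topology
  pidx <- which(top$role %in% c("protein-calpha", "protein-heavy"))
  lidx <- which(top$role == "ligand-heavy")
  resnos <- unique(top$resno[pidx])
  nf <- n_frames(ensemble)
  frac <- numeric(length(resnos))
  bound <- 0L
  for (f in seq_len(nf)) {
    any_contact <- FALSE
    for (r in seq_along(resnos)) {
      aidx <- pidx[top$resno[pidx] == resnos[r]]
      hit <- FALSE
      for (a in aidx) {
        for (l in lidx) {
          d <- sqrt(sum((ensemble$coords[a, , f] -
                           ensemble$coords[l, , f])^2))
          if (d <= cutoff) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) {
        frac[r] <- frac[r] + 1
        any_contact <- TRUE
      }
    }
    if (any_contact) bound <- bound + 1L
  }
  list(per_residue = data.frame(resno = resnos, fraction = frac / nf),
       bound_fraction = bound / nf)
}

#' Generate a synthetic ensemble with planted binding modes
#'
#' Samples frames by the Markov mode process of [ensemble_spec()] with
#' isotropic Gaussian atomic noise about each mode's pose, and returns
#' the ground truth alongside the data: per-frame mode labels and exact
#' per-residue contact fractions recomputed from the generated
#' coordinates by an independent straight-loop implementation.
#'
#' @param spec an `ensemble_spec`.
#' @param contact_cutoff cutoff used for the truth contact fractions, A.
#' @return List with `ensemble` (an `md_ensemble`) and `truth` (per-frame
#'   `labels`, per-residue `contacts`, `bound_fraction`).
#' @export
make_ensemble <- function(spec, contact_cutoff = 4.0) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  nm <- length(spec$modes)
  labels <- integer(spec$n_frames)
  labels[1L] <- sample.int(nm, 1L, prob = spec$weights)
  if (spec$n_frames > 1L) for (f in 2L:spec$n_frames) {
    labels[f] <- if (stats::runif(1) < spec$switch_prob)
      sample.int(nm, 1L, prob = spec$weights) else labels[f - 1L]
  }
  na <- nrow(spec$modes[[1L]]$xyz)
  coords <- array(0, dim = c(na, 3L, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    coords[, , f] <- spec$modes[[labels[f]]]$xyz +
      matrix(stats::rnorm(na * 3L, 0, spec$noise_sd), na, 3L)
  }
  ens <- md_ensemble(spec$modes[[1L]]$atoms, coords)
  tc <- truth_contacts(ens, contact_cutoff)
  list(ensemble = ens,
       truth = list(labels = labels, contacts = tc$per_residue,
                    bound_fraction = tc$bound_fraction,
                    contact_cutoff = contact_cutoff))
}

#' Specification for synthetic free/bound peak lists
#'
#' @param residues residue number range (default 183:231).
#' @param perturbed named list: residue number -> `c(d_hn, d_n)` planted
#'   free-minus-bound shift differences in ppm.
#' @param noise_sd measurement noise on each bound-state shift, ppm.
#' @param prolines residue numbers emitted as unobservable prolines.
#' @param unassigned residue numbers emitted as unassigned.
#' @param seed integer RNG seed (required).
#' @return A `peaklist_spec` object.
#' @export
peaklist_spec <- function(residues = 183:231,
                          perturbed = list(),
                          noise_sd = 0,
                          prolines = c(211L, 231L),
                          unassigned = integer(0),
                          seed) {
  if (missing(seed)) stop("an explicit seed is required")
  pert_res <- as.integer(names(perturbed))
  if (length(perturbed) && !all(pert_res %in% residues))
    stop("perturbed residues must lie inside the residue range")
  structure(list(residues = as.integer(residues), perturbed = perturbed,
                 noise_sd = noise_sd, prolines = as.integer(prolines),
                 unassigned = as.integer(unassigned),
                 seed = as.integer(seed)),
            class = "peaklist_spec")
}

#' Generate free/bound amide peak lists with planted perturbations
#'
#' Free-state shifts are drawn in realistic backbone amide ranges (1H
#' 7.2--9.8 ppm, 15N 105--130 ppm); bound-state shifts are the free
#' shifts minus the planted differences, plus optional Gaussian noise.
#' Prolines and unassigned residues appear in both lists with
#' unobservable status. The truth table holds the noise-free combined
#' perturbations and their categories.
#'
#' @param spec a `peaklist_spec`.
#' @return List with `free` and `bound` (`peak_list` objects) and
#'   `truth` (a noise-free `csp_table`).
#' @export
make_peaklists <- function(spec) {
  stopifnot(inherits(spec, "peaklist_spec"))
  set.seed(spec$seed)
  res <- spec$residues
  n <- length(res)
  aa <- c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N",
          "Q", "R", "S", "T", "V", "W", "Y")
  resid <- aa[1L + (res %% length(aa))]
  resid[res %in% spec$prolines] <- "P"
  status <- rep("observed", n)
  status[res %in% spec$prolines] <- "proline"
  status[res %in% spec$unassigned] <- "unassigned"
  h_free <- stats::runif(n, 7.2, 9.8)
  n_free <- stats::runif(n, 105, 130)
  d_hn <- d_n <- numeric(n)
  for (nm in names(spec$perturbed)) {
    i <- match(as.integer(nm), res)
    d_hn[i] <- spec$perturbed[[nm]][1L]
    d_n[i] <- spec$perturbed[[nm]][2L]
  }
  h_bound <- h_free - d_hn
  n_bound <- n_free - d_n
  if (spec$noise_sd > 0) {
    h_bound <- h_bound + stats::rnorm(n, 0, spec$noise_sd)
    n_bound <- n_bound + stats::rnorm(n, 0, spec$noise_sd)
  }
  obs <- status == "observed"
  mk <- function(h, nn) peak_list(resno = res, resid = resid,
                                  w_h = ifelse(obs, h, NA_real_),
                                  w_n = ifelse(obs, nn, NA_real_),
                                  status = status)
  dd <- compute_csp(d_hn, d_n)
  truth <- data.frame(resno = res, resid = resid,
                      d_hn = ifelse(obs, d_hn, NA_real_),
                      d_n = ifelse(obs, d_n, NA_real_),
                      ddelta = ifelse(obs, dd, NA_real_),
                      category = classify_csp(ifelse(obs, dd, NA_real_)),
                      stringsAsFactors = FALSE)
  class(truth) <- c("csp_table", "data.frame")
  list(free = mk(h_free, n_free), bound = mk(h_bound, n_bound),
       truth = truth)
}

#' Generate a synthetic ITC titration with its buffer blank
#'
#' Delegates the binding heats to [simulate_titration()] and adds a
#' small constant per-injection dilution heat; the blank holds the
#' dilution heat (plus noise) alone, so noise-free background
#' subtraction recovers the pure binding heats.
#'
#' @inheritParams simulate_titration
#' @param dilution_heat constant dilution heat per injection, ucal
#'   (default -0.2).
#' @return List with `sample` and `blank` (`itc_thermogram` objects) and
#'   `truth` (planted parameters).
#' @export
make_itc <- function(protocol, N = 1, kd, dH, noise_sd = 0, seed = NULL,
                     dilution_heat = -0.2) {
  binding <- simulate_titration(protocol, N, kd, dH, noise_sd = 0)
  nq <- nrow(binding)
  eps_s <- eps_b <- numeric(nq)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required for noisy simulation")
    set.seed(seed)
    eps_s <- stats::rnorm(nq, 0, noise_sd)
    eps_b <- stats::rnorm(nq, 0, noise_sd)
  }
  sample <- new_thermogram(binding$heat + dilution_heat + eps_s, protocol)
  blank <- new_thermogram(dilution_heat + eps_b, protocol)
  list(sample = sample, blank = blank,
       truth = list(N = N, kd = kd, dH = dH,
                    dilution_heat = dilution_heat, noise_sd = noise_sd))
}

#' Generate replicated FRET measurements per condition
#'
#' Gaussian replicate FRET ratios about each group mean, emitted as a
#' replicate table with consistent donor/acceptor intensities (donor
#' fixed at 1000 a.u.).
#'
#' @param means named numeric vector of group mean ratios.
#' @param sd common replicate standard deviation.
#' @param n replicates per group (>= 2).
#' @param seed integer RNG seed (required).
#' @return data.frame with `group`, `replicate`, `donor`, `acceptor`,
#'   `ratio`.
#' @export
make_fret <- function(means, sd = 0.05, n = 3, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (n < 2) stop("need at least two replicates per group")
  if (is.null(names(means))) names(means) <- paste0("g", seq_along(means))
  set.seed(seed)
  ratio <- as.vector(vapply(means, function(m) stats::rnorm(n, m, sd),
                            numeric(n)))
  ratio <- pmax(ratio, 1e-6)
  data.frame(group = rep(names(means), each = n),
             replicate = rep(seq_len(n), length(means)),
             donor = 1000,
             acceptor = 1000 * ratio,
             ratio = ratio,
             stringsAsFactors = FALSE)
}
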