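# Independent oracles and fixture builders used across the suite.

# uniform random rotation matrices from random quaternions
random_rotations <- function(k) {
  q <- matrix(stats::rnorm(4 * k), k, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # rows of the flattened 3x3 rotation, one rotation per row (row-major)
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

# Brute-force rotation-grid minimum RMSD after centroid alignment.
# Uses rmsd^2(R) = (sum|p|^2 + sum|q|^2 - 2<R, H>)/n with H the
# cross-covariance, so each rotation costs one inner product.
grid_rmsd_oracle <- function(mobile, reference, k = 1e5) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  H <- crossprod(P, Q)           # sum p_i q_i^T
  const <- sum(P^2) + sum(Q^2)
  n <- nrow(P)
  best <- Inf
  remaining <- k
  while (remaining > 0) {
    m <- min(remaining, 2e5)
    R <- random_rotations(m)
    # <R, H> for row-major flattened R: R[,1]*H[1,1]+R[,2]*H[1,2]+...
    tr <- R %*% as.vector(t(H))
    best <- min(best, min((const - 2 * tr) / n))
    remaining <- remaining - m
  }
  sqrt(max(best, 0))
}

# expected covering angle of k random rotations (median-order scale):
# P(angle <= t) ~ t^3/(3*pi) for small t, so min angle ~ (3*pi/k)^(1/3)
grid_resolution <- function(k) (3 * pi / k)^(1 / 3)

# step-by-step mole/volume bookkeeping oracle for the overflow cell:
# each injection is split into micro-injections; every micro-step adds
# dv of syringe solution, mixes, and expels dv of the mixture
cell_conc_oracle <- function(V0, M0, X0, injections, micro = 4000L) {
  M <- M0; X <- 0
  for (dV in injections) {
    dv <- dV / micro
    for (s in seq_len(micro)) {
      M <- M * V0 / (V0 + dv)
      X <- (X * V0 + X0 * dv) / (V0 + dv)
    }
  }
  c(M = M, X = X)
}

# bisection solve of the single-site mass-action equilibrium for the
# complex concentration (independent of the closed-form quadratic)
complex_bisect <- function(M, X, N, kd, tol = 1e-12) {
  f <- function(C) (N * M - C) * (X - C) - kd * C
  lo <- 0; hi <- min(N * M, X)
  if (hi <= 0) return(0)
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# from-scratch sums-of-squares one-way ANOVA
anova_ss_oracle <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  k <- length(groups)
  n <- length(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = Fv, p = stats::pf(Fv, k - 1, n - k, lower.tail = FALSE))
}

# single-step max-q permutation oracle for Tukey-type adjusted p-values
# (balanced groups): permutes pooled observations, recomputes the
# maximum studentized pairwise statistic, and returns for each observed
# pair the fraction of permutations whose max-q exceeds it
perm_tukey_oracle <- function(groups, reps = 1e5) {
  k <- length(groups)
  n <- lengths(groups)[1]
  stopifnot(all(lengths(groups) == n))
  x <- unlist(groups)
  N <- length(x)
  idx <- rep(seq_len(k), each = n)
  qmax <- numeric(reps)
  for (r in seq_len(reps)) {
    p <- x[sample.int(N)]
    m <- vapply(seq_len(k), function(g) mean(p[idx == g]), numeric(1))
    v <- vapply(seq_len(k), function(g) sum((p[idx == g] - m[g])^2),
                numeric(1))
    mse <- sum(v) / (N - k)
    qmax[r] <- max(abs(outer(m, m, "-"))) / sqrt(mse / n)
  }
  m0 <- vapply(groups, mean, numeric(1))
  mse0 <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                     numeric(1))) / (N - k)
  q0 <- abs(outer(m0, m0, "-")) / sqrt(mse0 / n)
  pairs <- which(upper.tri(q0), arr.ind = TRUE)
  data.frame(g1 = pairs[, 1], g2 = pairs[, 2],
             p_perm = vapply(seq_len(nrow(pairs)), function(i)
               mean(qmax >= q0[pairs[i, 1], pairs[i, 2]]), numeric(1)))
}

# adjusted Rand index between two partitions
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# tiny non-coplanar reference used by several geometry tests
tetrahedron <- function() rbind(c(0, 0, 0), c(1, 0, 0),
                                c(0, 1, 0), c(0, 0, 1))

random_rigid_motion <- function() {
  R <- matrix(random_rotations(1), 3, 3, byrow = TRUE)
  list(R = R, t = stats::runif(3, -10, 10))
}

apply_motion <- function(xyz, motion) {
  sweep(xyz %*% t(motion$R), 2, motion$t, "+")
}
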