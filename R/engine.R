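#' @useDynLib jointdfe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Phase-space grid on [0, 1], crowded near the absorbing boundaries where
# the allele-frequency density varies fastest (and, under strong negative
# selection, where almost all density lives). tanh stretching of a uniform
# grid; crwd controls the boundary refinement.
phi_grid <- function(pts, crwd = 3.5) {
  stopifnot(pts >= 10)
  u <- seq(-1, 1, length.out = pts)
  x <- 0.5 * (1 + tanh(crwd * u) / tanh(crwd))
  x[1] <- 0
  x[pts] <- 1
  x
}

# Trapezoid weights for integration over a non-uniform grid.
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

# Expected sample AFS from a 1D density: E[F_i] = int phi(x) C(n,i) x^i
# (1-x)^(n-i) dx, trapezoid over the phase-space grid. Returns counts 0..n.
afs_from_phi_1d <- function(phi, xx, n) {
  w <- trapz_weights(xx)
  B <- outer(xx, 0:n, function(x, i) stats::dbinom(i, n, x))
  as.vector(crossprod(B, phi * w))
}

afs_from_phi_2d <- function(phi, xx, n1, n2) {
  w <- trapz_weights(xx)
  B1 <- outer(xx, 0:n1, function(x, i) stats::dbinom(i, n1, x))
  B2 <- outer(xx, 0:n2, function(x, j) stats::dbinom(j, n2, x))
  crossprod(B1, (phi * w) %*% (B2 * w))
}

# Quadratic Richardson extrapolation to zero grid spacing from three
# solutions computed on grids with pts[1] < pts[2] < pts[3] points.
richardson3 <- function(vals, pts) {
  d <- 1 / (pts - 1)
  l1 <- (d[2] * d[3]) / ((d[1] - d[2]) * (d[1] - d[3]))
  l2 <- (d[1] * d[3]) / ((d[2] - d[1]) * (d[2] - d[3]))
  l3 <- (d[1] * d[2]) / ((d[3] - d[1]) * (d[3] - d[2]))
  vals[[1]] * l1 + vals[[2]] * l2 + vals[[3]] * l3
}

# Default extrapolation grid sizes for given sample sizes, following the
# convention of base = max(n) + 10 with two refinements 10 points apart.
default_pts <- function(n1, n2, floor_pts = 40L) {
  base <- max(floor_pts, max(n1, n2) + 10L)
  as.integer(base + c(0L, 10L, 20L))
}

engine_nsteps <- function(T, dt_target = 2e-3, min_steps = 100L, max_steps = 10000L) {
  max(min_steps, min(max_steps, ceiling(T / dt_target)))
}

# Raw (single-grid) pipeline: ancestral 1D equilibrium (+ optional pre-split
# epoch), lift to the 2D diagonal, integrate the split epoch, sample.
joint_afs_single_grid <- function(demo, sel, n1, n2, pts, crwd = 3.5) {
  xx <- phi_grid(pts, crwd)
  phi1 <- phi1d_equilibrium_cpp(xx, 1, sel$gamma1, sel$h, 1)
  if (demo$id == "IM_pre" && demo$T_pre > 0) {
    ns <- engine_nsteps(demo$T_pre)
    phi1 <- phi1d_integrate_cpp(
      phi1, xx, rep(demo$nu_pre, ns),
      sel$gamma1, sel$h, 1, demo$T_pre / ns
    )
  }
  if (demo$id == "equilibrium") {
    # both axes sample the same ancestral population: perfectly correlated
    # frequencies on the diagonal
    phi2 <- phi_1d_to_2d(phi1, xx)
    return(afs_from_phi_2d(phi2, xx, n1, n2))
  }
  phi2 <- phi_1d_to_2d(phi1, xx)
  T <- demo$T
  if (T > 0) {
    ns <- engine_nsteps(T)
    tt <- (seq_len(ns) - 0.5) / ns # midpoint of each step
    if (demo$id %in% c("split_mig", "split_no_mig")) {
      nu1_t <- rep(demo$nu1, ns)
      nu2_t <- rep(demo$nu2, ns)
    } else { # IM, IM_pre: exponential growth from the founding fractions
      start1 <- demo$s_frac * if (demo$id == "IM_pre") demo$nu_pre else 1
      start2 <- (1 - demo$s_frac) * if (demo$id == "IM_pre") demo$nu_pre else 1
      nu1_t <- start1 * (demo$nu1 / start1)^tt
      nu2_t <- start2 * (demo$nu2 / start2)^tt
    }
    phi2 <- phi2d_integrate_cpp(
      phi2, xx, nu1_t, nu2_t, demo$m12, demo$m21,
      sel$gamma1, sel$gamma2, sel$h, 1, T / ns
    )
  }
  afs_from_phi_2d(phi2, xx, n1, n2)
}

# Place a 1D density on the 2D diagonal (both populations share the
# ancestral frequency at the instant of the split).
phi_1d_to_2d <- function(phi1, xx) {
  L <- length(xx)
  inv_half <- numeric(L)
  inv_half[1] <- 2 / (xx[2] - xx[1])
  inv_half[L] <- 2 / (xx[L] - xx[L - 1])
  inv_half[2:(L - 1)] <- 2 / (xx[3:L] - xx[1:(L - 2)])
  phi2 <- matrix(0, L, L)
  diag(phi2) <- phi1 * inv_half
  phi2
}

#' Expected joint allele frequency spectrum under demography and selection
#'
#' Computes the expected two-population joint AFS `F(gamma1, gamma2)` at
#' population-scaled mutation rate `theta = 1` by numerically integrating
#' the two-dimensional diffusion approximation of allele frequencies: the
#' ancestral population is brought to mutation-selection-drift equilibrium,
#' the density is placed on the diagonal at the split, and the two
#' populations then evolve under drift, selection with dominance, size
#' change and migration. The solution is computed on three successively
#' finer phase-space grids and Richardson-extrapolated to zero spacing.
#'
#' @param demo a [demographic_model()].
#' @param sel a [selection_regime()].
#' @param n1,n2 haploid sample sizes (each `>= 2`).
#' @param pts optional integer vector of three grid sizes; defaults to
#'   `max(n1, n2) + 10` plus refinements of 10 and 20 points.
#' @param crwd boundary crowding strength of the phase-space grid.
#' @return a `joint_spectrum` of expectations at `theta = 1` with the
#'   absorbing corners masked.
#' @examples
#' demo <- demographic_model("split_mig", nu1 = 1, nu2 = 1, T = 0.1, m12 = 1, m21 = 1)
#' fs <- expected_joint_afs(demo, selection_regime(0, 0), n1 = 6, n2 = 6)
#' @export
expected_joint_afs <- function(demo, sel = selection_regime(0, 0), n1, n2,
                               pts = NULL, crwd = 3.5) {
  stopifnot(inherits(demo, "demographic_model"), inherits(sel, "selection_regime"))
  if (n1 < 2 || n2 < 2) stop("haploid sample sizes must be >= 2")
  if (is.null(pts)) pts <- default_pts(n1, n2)
  stopifnot(length(pts) == 3, all(diff(pts) > 0))
  sols <- lapply(pts, function(p) joint_afs_single_grid(demo, sel, n1, n2, p, crwd))
  vals <- richardson3(sols, pts)
  if (any(!is.finite(vals))) {
    stop(sprintf(
      "diffusion engine returned non-finite expectations (model %s, gamma1 = %g, gamma2 = %g)",
      demo$id, sel$gamma1, sel$gamma2
    ))
  }
  # extrapolation can produce tiny negative values in entries with
  # negligible mass; clip them to zero
  neg <- vals < 0
  if (any(neg[-c(1, length(vals))])) {
    worst <- min(vals)
    if (worst < -1e-2 * max(vals)) {
      warning(sprintf("clipped negative expectations (most negative %.3g)", worst))
    }
  }
  vals[vals < 0] <- 0
  joint_spectrum(vals, kind = "expected")
}

#' Single-population equilibrium spectrum under selection
#'
#' Expected AFS of a single population at mutation-selection-drift
#' equilibrium with `theta = 1`, for derived-allele counts `1 .. n-1`.
#' At `gamma = 0` this is the classical neutral expectation `theta / i`.
#'
#' @param gamma population-scaled selection coefficient (`<= 0`).
#' @param h dominance coefficient.
#' @param n haploid sample size (`>= 2`).
#' @param pts optional three extrapolation grid sizes.
#' @return numeric vector of length `n - 1`.
#' @examples
#' equilibrium_spectrum_1d(0, 0.5, 4) # approx c(1, 1/2, 1/3)
#' @export
equilibrium_spectrum_1d <- function(gamma, h = 0.5, n, pts = NULL) {
  if (n < 2) stop("haploid sample size must be >= 2")
  if (!is.finite(gamma) || !is.finite(h)) stop("selection parameters must be finite")
  if (gamma > 0) stop("positive selection coefficients are not supported")
  if (is.null(pts)) pts <- default_pts(n, n)
  sols <- lapply(pts, function(p) {
    xx <- phi_grid(p)
    afs_from_phi_1d(phi1d_equilibrium_cpp(xx, 1, gamma, h, 1), xx, n)
  })
  vals <- richardson3(sols, pts)
  pmax(vals[2:n], 0)
}
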