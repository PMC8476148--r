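# Discrete Wright-Fisher oracle: an independent route to the expected joint
# AFS via explicit finite-population transition matrices, used to validate
# the diffusion engine. Population-scaled parameters (gamma, T, scaled
# migration, relative sizes) are preserved under the rescaling to a small
# simulated ancestral size N_sim, so the oracle converges to the diffusion
# answer as N_sim grows (error O(1/N_sim)).

# Deterministic allele-frequency change from one round of viability
# selection with genotype fitnesses 1 : 1+2hs : 1+2s.
wf_post_selection <- function(x, s, h) {
  wbar <- x^2 * (1 + 2 * s) + 2 * x * (1 - x) * (1 + 2 * h * s) + (1 - x)^2
  (x^2 * (1 + 2 * s) + x * (1 - x) * (1 + 2 * h * s)) / wbar
}

# Expected number of segregating sites per frequency class (1 .. 2N-1) at
# mutation-selection-drift equilibrium, theta at the diffusion scale with
# ancestral reference size N_ref.
wf_equilibrium_1d <- function(N, s, h, theta = 1, influx = theta / 2) {
  states <- 0:(2 * N)
  xstar <- wf_post_selection(states / (2 * N), s, h)
  P <- outer(states, states, function(k, l) stats::dbinom(l, 2 * N, xstar[k + 1]))
  Pint <- P[2:(2 * N), 2:(2 * N)]
  rhs <- c(influx, rep(0, 2 * N - 2))
  solve(diag(2 * N - 1) - t(Pint), rhs)
}

# One generation forward for the interior-state vector under constant size.
wf_step_1d <- function(f, N, s, h, influx) {
  states <- 1:(2 * N - 1)
  xstar <- wf_post_selection(states / (2 * N), s, h)
  P <- outer(states, states, function(k, l) stats::dbinom(l, 2 * N, xstar[k]))
  out <- as.vector(crossprod(P, f))
  out[1] <- out[1] + influx
  out
}

#' Expected joint AFS from an explicit Wright-Fisher chain
#'
#' Validation oracle for [expected_joint_afs()]: evolves the full joint
#' distribution of derived-allele counts in two finite Wright-Fisher
#' populations (selection, dominance, migration, mutation influx at
#' `theta = 1`) and downsamples binomially to the requested sample sizes.
#' The ancestral population of `N_sim` diploids is brought to equilibrium
#' by a direct linear solve, both daughter populations are founded by
#' binomial sampling from the ancestral frequency, and the chain then runs
#' for `round(2 * N_sim * T)` generations.
#'
#' @param demo a [demographic_model()] (`equilibrium`, `split_mig`,
#'   `split_no_mig`, `IM`, or `IM_pre`; IM-type growth is applied through a
#'   per-generation size trajectory).
#' @param sel a [selection_regime()].
#' @param n1,n2 haploid sample sizes.
#' @param N_sim diploid ancestral population size of the simulated chain.
#' @return a `joint_spectrum` of expectations at `theta = 1`.
#' @export
wright_fisher_oracle <- function(demo, sel, n1, n2, N_sim = 40) {
  stopifnot(inherits(demo, "demographic_model"), inherits(sel, "selection_regime"))
  theta <- 1
  s1 <- sel$gamma1 / (2 * N_sim)
  s2 <- sel$gamma2 / (2 * N_sim)
  h <- sel$h
  # ancestral equilibrium at relative size 1
  f_anc <- wf_equilibrium_1d(N_sim, s1, h, theta)
  N_anc <- N_sim
  if (demo$id == "IM_pre" && demo$T_pre > 0) {
    N_pre <- max(2L, round(N_sim * demo$nu_pre))
    gens_pre <- round(2 * N_sim * demo$T_pre)
    # founding of the resized ancestral population by binomial sampling
    B <- outer(1:(2 * N_anc - 1) / (2 * N_anc), 0:(2 * N_pre), function(x, l) {
      stats::dbinom(l, 2 * N_pre, x)
    })
    f_anc <- as.vector(crossprod(B[, 2:(2 * N_pre)], f_anc))
    influx <- theta * demo$nu_pre / 2
    for (g in seq_len(gens_pre)) f_anc <- wf_step_1d(f_anc, N_pre, s1, h, influx)
    N_anc <- N_pre
  }
  if (demo$id == "equilibrium") {
    states <- 1:(2 * N_anc - 1)
    Bs1 <- outer(states / (2 * N_anc), 0:n1, function(x, i) stats::dbinom(i, n1, x))
    Bs2 <- outer(states / (2 * N_anc), 0:n2, function(x, j) stats::dbinom(j, n2, x))
    F <- crossprod(Bs1, f_anc * Bs2)
    return(joint_spectrum(F, kind = "expected"))
  }
  gens <- round(2 * N_sim * demo$T)
  if (demo$id %in% c("split_mig", "split_no_mig")) {
    N1_t <- rep(max(2L, round(N_sim * demo$nu1)), max(gens, 1))
    N2_t <- rep(max(2L, round(N_sim * demo$nu2)), max(gens, 1))
  } else {
    start1 <- demo$s_frac * if (demo$id == "IM_pre") demo$nu_pre else 1
    start2 <- (1 - demo$s_frac) * if (demo$id == "IM_pre") demo$nu_pre else 1
    tt <- if (gens > 0) seq_len(gens) / gens else 1
    N1_t <- pmax(2L, round(N_sim * start1 * (demo$nu1 / start1)^tt))
    N2_t <- pmax(2L, round(N_sim * start2 * (demo$nu2 / start2)^tt))
  }
  N1_0 <- if (gens > 0) N1_t[1] else max(2L, round(N_sim * demo$nu1))
  N2_0 <- if (gens > 0) N2_t[1] else max(2L, round(N_sim * demo$nu2))
  if ((2 * max(N1_t) + 1) * (2 * max(N2_t) + 1) > 3e5) {
    stop("Wright-Fisher joint state space too large; reduce N_sim")
  }
  m1 <- demo$m12 / (2 * N_sim) # per-generation fraction of pop1 from pop2
  m2 <- demo$m21 / (2 * N_sim)
  # founding: both daughters sample binomially from the ancestral frequency
  x_anc <- 1:(2 * N_anc - 1) / (2 * N_anc)
  B1a <- outer(x_anc, 0:(2 * N1_0), function(x, l) stats::dbinom(l, 2 * N1_0, x))
  B2a <- outer(x_anc, 0:(2 * N2_0), function(x, l) stats::dbinom(l, 2 * N2_0, x))
  D <- crossprod(B1a, f_anc * B2a)
  N1 <- N1_0
  N2 <- N2_0
  kern <- NULL
  for (g in seq_len(gens)) {
    N1n <- N1_t[g]
    N2n <- N2_t[g]
    if (is.null(kern) || N1n != kern$N1n || N2n != kern$N2n || N1 != kern$N1 || N2 != kern$N2) {
      kern <- wf_joint_kernels(N1, N2, N1n, N2n, s1, s2, h, m1, m2)
    }
    D <- wf_joint_step(D, kern)
    N1 <- N1n
    N2 <- N2n
    nu1 <- N1 / N_sim
    nu2 <- N2 / N_sim
    D[2, 1] <- D[2, 1] + theta * nu1 / 2
    D[1, 2] <- D[1, 2] + theta * nu2 / 2
  }
  x1 <- 0:(2 * N1) / (2 * N1)
  x2 <- 0:(2 * N2) / (2 * N2)
  Bs1 <- outer(x1, 0:n1, function(x, i) stats::dbinom(i, n1, x))
  Bs2 <- outer(x2, 0:n2, function(x, j) stats::dbinom(j, n2, x))
  F <- crossprod(Bs1, D %*% Bs2)
  joint_spectrum(F, kind = "expected")
}

# Precompute per-generation transition kernels. A1[y1, x2, x1] is the
# probability pop1 moves to count y1 given current counts (x1, x2); A2
# likewise for pop2. Migration makes each population's expected frequency
# depend on the other's current frequency.
wf_joint_kernels <- function(N1, N2, N1n, N2n, s1, s2, h, m1, m2) {
  x1 <- 0:(2 * N1) / (2 * N1)
  x2 <- 0:(2 * N2) / (2 * N2)
  sel1 <- wf_post_selection(x1, s1, h)
  sel2 <- wf_post_selection(x2, s2, h)
  g1 <- outer(sel1, sel2, function(a, b) (1 - m1) * a + m1 * b) # L1 x L2
  g2 <- outer(sel1, sel2, function(a, b) m2 * a + (1 - m2) * b)
  L1 <- length(x1)
  L2 <- length(x2)
  L1n <- 2 * N1n + 1
  L2n <- 2 * N2n + 1
  A1 <- array(0, c(L1n, L2, L1))
  A2 <- array(0, c(L2, L2n, L1))
  y1 <- 0:(2 * N1n)
  y2 <- 0:(2 * N2n)
  for (i in seq_len(L1)) {
    A1[, , i] <- outer(y1, g1[i, ], function(y, p) stats::dbinom(y, 2 * N1n, p))
    A2[, , i] <- t(outer(y2, g2[i, ], function(y, p) stats::dbinom(y, 2 * N2n, p)))
  }
  list(A1 = A1, A2 = A2, N1 = N1, N2 = N2, N1n = N1n, N2n = N2n, L1n = L1n, L2n = L2n)
}

wf_joint_step <- function(D, kern) {
  L1 <- dim(kern$A1)[3]
  Dn <- matrix(0, kern$L1n, kern$L2n)
  for (i in seq_len(L1)) {
    U <- sweep(kern$A1[, , i], 2, D[i, ], "*") # [y1, x2]
    Dn <- Dn + U %*% kern$A2[, , i] # [y1, y2]
  }
  Dn
}
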