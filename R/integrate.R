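# Integration of a joint DFE over a selection cache: Eq.-style decomposition
# of the mixture into a 1D integral along the diagonal cache (perfectly
# correlated component) plus a 2D product integral over the full grid
# (independent component), with out-of-domain tail mass assigned to the
# nearest boundary spectra. The trapezoid rule is applied on the raw
# (non-uniform, log-spaced) gamma abscissae; in-domain node weights are
# rescaled so that their sum equals the analytic in-domain probability
# mass, which keeps the full weight accounting (in-domain + tails) exactly
# normalised.

#' Population-scaled mutation rate configuration
#'
#' The selected-class mutation rate is never free in DFE fits: it is fixed
#' at a multiple `ratio_NS` of the neutral rate inferred from the
#' demographic fit (e.g. 2.31 for human nonsynonymous/synonymous, 2.85 for
#' D. melanogaster, 2.5 for wild tomato, 5.21 for GC-conservative human
#' mutations).
#'
#' @param theta_neu population-scaled neutral mutation rate.
#' @param ratio_NS ratio of selected to neutral mutation influx.
#' @return a list with `theta_neu`, `ratio_NS` and derived `theta_sel`.
#' @export
theta_config <- function(theta_neu, ratio_NS = 2.31) {
  stopifnot(theta_neu > 0, ratio_NS > 0)
  list(theta_neu = theta_neu, ratio_NS = ratio_NS, theta_sel = ratio_NS * theta_neu)
}

#' Out-of-domain tail weights of a DFE
#'
#' Probability mass of the marginal DFE below, within, and above the cached
#' magnitude domain; the three weights sum to one exactly. The `joint`
#' variant decomposes the negative quadrant for a bivariate model into the
#' central block, four edge strips and four corner blocks.
#'
#' @param dfe a `dfe_model`.
#' @param bounds magnitude bounds `c(min_mag, max_mag)` of the cached domain.
#' @param which marginal index (bivariate lognormal only).
#' @return list with `below`, `within`, `above`.
#' @examples
#' tail_weights(lognormal_mixture_dfe(3.6, 5.1, 0.9), c(1e-4, 2000))
#' @export
tail_weights <- function(dfe, bounds, which = 1) {
  stopifnot(inherits(dfe, "dfe_model"), length(bounds) == 2, bounds[1] > 0, bounds[2] > bounds[1])
  below <- marginal_cdf_mag(dfe, bounds[1], which)
  above <- 1 - marginal_cdf_mag(dfe, bounds[2], which)
  list(below = below, within = 1 - below - above, above = above)
}

#' @rdname tail_weights
#' @export
tail_weights_joint <- function(dfe, bounds) {
  stopifnot(inherits(dfe, "dfe_model"))
  if (inherits(dfe, "dfe_mixture")) {
    t1 <- tail_weights(dfe, bounds)
    t2 <- t1
    rho <- 0
  } else {
    t1 <- tail_weights(dfe, bounds, which = 1)
    t2 <- tail_weights(dfe, bounds, which = 2)
    rho <- dfe$rho
  }
  if (inherits(dfe, "dfe_bivariate_lognormal")) {
    a <- log(bounds[1])
    b <- log(bounds[2])
    z1 <- c(lo = (a - dfe$mu1) / dfe$sigma1, hi = (b - dfe$mu1) / dfe$sigma1)
    z2 <- c(lo = (a - dfe$mu2) / dfe$sigma2, hi = (b - dfe$mu2) / dfe$sigma2)
    rect <- function(l1, u1, l2, u2) bvn_rect(l1, u1, l2, u2, rho)
    blocks <- list(
      center = rect(z1["lo"], z1["hi"], z2["lo"], z2["hi"]),
      strip_below1 = rect(-Inf, z1["lo"], z2["lo"], z2["hi"]),
      strip_above1 = rect(z1["hi"], Inf, z2["lo"], z2["hi"]),
      strip_below2 = rect(z1["lo"], z1["hi"], -Inf, z2["lo"]),
      strip_above2 = rect(z1["lo"], z1["hi"], z2["hi"], Inf),
      corner_bb = rect(-Inf, z1["lo"], -Inf, z2["lo"]),
      corner_ba = rect(-Inf, z1["lo"], z2["hi"], Inf),
      corner_ab = rect(z1["hi"], Inf, -Inf, z2["lo"]),
      corner_aa = rect(z1["hi"], Inf, z2["hi"], Inf)
    )
  } else {
    blocks <- list(
      center = t1$within * t2$within,
      strip_below1 = t1$below * t2$within,
      strip_above1 = t1$above * t2$within,
      strip_below2 = t1$within * t2$below,
      strip_above2 = t1$within * t2$above,
      corner_bb = t1$below * t2$below,
      corner_ba = t1$below * t2$above,
      corner_ab = t1$above * t2$below,
      corner_aa = t1$above * t2$above
    )
  }
  blocks
}

# Standard bivariate normal rectangle probability, computed by adaptive 1D
# quadrature of the conditional-normal CDF (deterministic).
bvn_rect <- function(l1, u1, l2, u2, rho) {
  if (abs(rho) < 1e-12) {
    return((stats::pnorm(u1) - stats::pnorm(l1)) * (stats::pnorm(u2) - stats::pnorm(l2)))
  }
  f <- function(z) {
    sd <- sqrt(1 - rho^2)
    stats::dnorm(z) * (stats::pnorm((u2 - rho * z) / sd) - stats::pnorm((l2 - rho * z) / sd))
  }
  lo <- max(l1, -10)
  hi <- min(u1, 10)
  if (hi <= lo) {
    return(0)
  }
  stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# In-domain trapezoid node weights for a marginal DFE over the cached grid,
# rescaled so their sum equals the analytic in-domain mass.
marginal_node_weights <- function(dfe, grid, which = 1) {
  tw <- trapz_weights(grid) * marginal_pdf(dfe, -grid, which)
  tails <- tail_weights(dfe, c(grid[1], grid[length(grid)]), which)
  s <- sum(tw)
  if (s > 0) tw <- tw * tails$within / s
  list(weights = tw, below = tails$below, above = tails$above, within = tails$within)
}

#' Expected selected joint AFS by DFE integration over a cache
#'
#' Integrates the cached expected spectra `F(gamma1, gamma2)` against a
#' joint DFE. For the mixture models the perfectly correlated component is
#' a one-dimensional trapezoid integral along the diagonal of the cache and
#' the independent component a two-dimensional trapezoid of the product of
#' marginals over the full grid; for the bivariate lognormal a single 2D
#' trapezoid of the joint density is used. Probability mass outside the
#' cached magnitude domain is assigned to the nearest boundary spectra
#' (edge strips to boundary rows/columns, corner blocks to corner nodes),
#' with the all-neutral-direction mass assigned to the neutral spectrum.
#' The result is scaled by `theta_sel` and then passed through the
#' ancestral-misidentification transform.
#'
#' @param cache a `selection_cache`.
#' @param dfe a `dfe_model`.
#' @param theta_sel population-scaled selected mutation rate (scalar, or a
#'   [theta_config()] whose `theta_sel` is used).
#' @param p_misid ancestral-state misidentification probability.
#' @return a `joint_spectrum` of expectations; attribute `weight_total`
#'   carries the DFE weight accounting (should be 1 up to quadrature error).
#' @export
expected_selected_afs <- function(cache, dfe, theta_sel = 1, p_misid = 0) {
  stopifnot(inherits(cache, "selection_cache"), inherits(dfe, "dfe_model"))
  if (is.list(theta_sel)) theta_sel <- theta_sel$theta_sel
  stopifnot(is.finite(theta_sel), theta_sel > 0)
  grid <- cache$grid
  np <- length(grid)
  K <- (cache$n1 + 1L) * (cache$n2 + 1L)
  S <- matrix(cache$spectra, np * np, K) # node (i,j) in row (j-1)*np+i
  neutral <- as.vector(unclass(cache$neutral))
  corner <- function(i, j) S[(j - 1L) * np + i, ]
  if (inherits(dfe, "dfe_mixture")) {
    nw <- marginal_node_weights(dfe, grid)
    # perfectly correlated component: 1D integral along the diagonal cache
    di <- (seq_len(np) - 1L) * np + seq_len(np)
    diag_part <- colSums(S[di, , drop = FALSE] * nw$weights) +
      nw$below * neutral + nw$above * corner(np, np)
    # independent component: separable 2D product integral
    W2 <- as.vector(outer(nw$weights, nw$weights))
    indep_part <- colSums(S * W2)
    # edge strips: one axis out of domain, nearest boundary row/column
    for (jj in seq_len(np)) {
      indep_part <- indep_part +
        nw$below * nw$weights[jj] * S[(jj - 1L) * np + 1L, ] + # gamma1 below
        nw$above * nw$weights[jj] * S[(jj - 1L) * np + np, ] + # gamma1 above
        nw$weights[jj] * nw$below * S[0L * np + jj, ] + # gamma2 below
        nw$weights[jj] * nw$above * S[(np - 1L) * np + jj, ] # gamma2 above
    }
    indep_part <- indep_part +
      nw$below^2 * neutral + nw$below * nw$above * corner(1, np) +
      nw$above * nw$below * corner(np, 1) + nw$above^2 * corner(np, np)
    vals <- dfe$w * diag_part + (1 - dfe$w) * indep_part
    wtot <- dfe$w * (sum(nw$weights) + nw$below + nw$above) +
      (1 - dfe$w) * ((sum(nw$weights) + nw$below + nw$above)^2)
  } else {
    blocks <- tail_weights_joint(dfe, c(grid[1], grid[np]))
    tw <- trapz_weights(grid)
    dens <- outer(-grid, -grid, function(a, b) joint_pdf(dfe, a, b))
    W2 <- outer(tw, tw) * dens
    s <- sum(W2)
    if (s > 0) W2 <- W2 * blocks$center / s
    vals <- colSums(S * as.vector(W2))
    # strips: distribute along the in-domain axis by the conditional density
    # at the boundary node, rescaled to the strip mass
    strip <- function(total, node_dens, rows) {
      q <- tw * node_dens
      if (sum(q) > 0) q <- q * total / sum(q) else q[] <- 0
      colSums(S[rows, , drop = FALSE] * q)
    }
    cond_below1 <- strip_cond_density(dfe, grid, out_axis = 1, side = "below")
    cond_above1 <- strip_cond_density(dfe, grid, out_axis = 1, side = "above")
    cond_below2 <- strip_cond_density(dfe, grid, out_axis = 2, side = "below")
    cond_above2 <- strip_cond_density(dfe, grid, out_axis = 2, side = "above")
    rows_g1lo <- (seq_len(np) - 1L) * np + 1L
    rows_g1hi <- (seq_len(np) - 1L) * np + np
    rows_g2lo <- seq_len(np)
    rows_g2hi <- (np - 1L) * np + seq_len(np)
    vals <- vals +
      strip(blocks$strip_below1, cond_below1, rows_g1lo) +
      strip(blocks$strip_above1, cond_above1, rows_g1hi) +
      strip(blocks$strip_below2, cond_below2, rows_g2lo) +
      strip(blocks$strip_above2, cond_above2, rows_g2hi) +
      blocks$corner_bb * neutral + blocks$corner_ba * corner(1, np) +
      blocks$corner_ab * corner(np, 1) + blocks$corner_aa * corner(np, np)
    wtot <- sum(unlist(blocks))
  }
  mat <- matrix(theta_sel * vals, cache$n1 + 1L, cache$n2 + 1L)
  out <- joint_spectrum(pmax(mat, 0), mask = cache$mask, kind = "expected")
  out <- misid_transform(out, p_misid)
  attr(out, "weight_total") <- wtot
  out
}

# Density along the in-domain axis of an edge strip: marginal density of the
# in-domain coordinate times the conditional probability that the other
# coordinate lies beyond the domain boundary.
strip_cond_density <- function(dfe, grid, out_axis, side) {
  np <- length(grid)
  in_axis <- 3L - out_axis
  mu_in <- if (in_axis == 1) dfe$mu1 else dfe$mu2
  sd_in <- if (in_axis == 1) dfe$sigma1 else dfe$sigma2
  mu_out <- if (out_axis == 1) dfe$mu1 else dfe$mu2
  sd_out <- if (out_axis == 1) dfe$sigma1 else dfe$sigma2
  zin <- (log(grid) - mu_in) / sd_in
  bound <- if (side == "below") log(grid[1]) else log(grid[np])
  zb <- (bound - mu_out) / sd_out
  csd <- sqrt(1 - dfe$rho^2)
  cond <- if (side == "below") {
    stats::pnorm((zb - dfe$rho * zin) / csd)
  } else {
    1 - stats::pnorm((zb - dfe$rho * zin) / csd)
  }
  marginal_pdf(dfe, -grid, which = in_axis) * cond
}
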