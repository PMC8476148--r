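#' Parametric joint-DFE models
#'
#' Three families for the joint distribution of (deleterious)
#' population-scaled selection coefficients `(gamma1, gamma2)` of a new
#' mutation in two populations:
#'
#' * `lognormal_mixture_dfe(mu, sigma, w)`: with probability `w` the two
#'   coefficients are identical (a perfectly correlated component supported
#'   on the diagonal), otherwise they are independent draws; in both cases
#'   the marginal of `log(-gamma)` is Normal(`mu`, `sigma`). For this
#'   mixture the correlation of the joint DFE equals `w`.
#' * `gamma_mixture_dfe(alpha, beta, w)`: same mixture construction with
#'   Gamma(`alpha` shape, `beta` scale) marginals for `-gamma`.
#' * `bivariate_lognormal_dfe(mu1, sigma1, mu2, sigma2, rho)`: jointly
#'   lognormal magnitudes, `rho` being the correlation of the logs
#'   (possibly asymmetric marginals).
#'
#' All densities are supported on the negative quadrant only (deleterious
#' mutations); `gamma = 0` is the neutral boundary.
#'
#' @param mu,sigma mean and standard deviation of `log(-gamma)`.
#' @param w mixture weight of the perfectly correlated component, in `[0, 1]`.
#' @param alpha,beta shape and scale of the gamma marginal of `-gamma`.
#' @param mu1,mu2,sigma1,sigma2 log-scale means and standard deviations.
#' @param rho log-scale correlation in `(-1, 1)`.
#' @return an object of class `dfe_model`.
#' @examples
#' dfe <- lognormal_mixture_dfe(mu = 3.6, sigma = 5.1, w = 0.9)
#' dfe_correlation(dfe)
#' @name dfe_models
NULL

#' @rdname dfe_models
#' @export
lognormal_mixture_dfe <- function(mu, sigma, w) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma > 0, is.finite(w), w >= 0, w <= 1)
  structure(list(family = "lognormal_mixture", mu = mu, sigma = sigma, w = w),
    class = c("dfe_lognormal_mixture", "dfe_mixture", "dfe_model")
  )
}

#' @rdname dfe_models
#' @export
gamma_mixture_dfe <- function(alpha, beta, w) {
  stopifnot(
    is.finite(alpha), alpha > 0, is.finite(beta), beta > 0,
    is.finite(w), w >= 0, w <= 1
  )
  structure(list(family = "gamma_mixture", alpha = alpha, beta = beta, w = w),
    class = c("dfe_gamma_mixture", "dfe_mixture", "dfe_model")
  )
}

#' @rdname dfe_models
#' @export
bivariate_lognormal_dfe <- function(mu1, sigma1, mu2 = mu1, sigma2 = sigma1, rho = 0) {
  stopifnot(
    is.finite(mu1), is.finite(mu2), is.finite(sigma1), sigma1 > 0,
    is.finite(sigma2), sigma2 > 0, is.finite(rho), abs(rho) < 1
  )
  structure(
    list(
      family = "bivariate_lognormal", mu1 = mu1, sigma1 = sigma1,
      mu2 = mu2, sigma2 = sigma2, rho = rho
    ),
    class = c("dfe_bivariate_lognormal", "dfe_model")
  )
}

#' @export
print.dfe_model <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf(
    "dfe_model '%s': %s\n", x$family,
    paste(sprintf("%s = %g", names(pars), unlist(pars)), collapse = ", ")
  ))
  invisible(x)
}

#' Marginal density of a joint-DFE model
#'
#' Density of the marginal distribution of a single population's
#' population-scaled selection coefficient at `gamma < 0`. For the
#' bivariate lognormal, `which` selects the population.
#'
#' @param dfe a `dfe_model`.
#' @param gamma strictly negative selection coefficient(s).
#' @param which population index (bivariate lognormal only).
#' @return non-negative density value(s).
#' @export
marginal_pdf <- function(dfe, gamma, which = 1) {
  stopifnot(inherits(dfe, "dfe_model"))
  if (any(gamma >= 0)) stop("marginal_pdf is defined for gamma < 0 only (deleterious mutations)")
  g <- -gamma
  switch(dfe$family,
    lognormal_mixture = stats::dlnorm(g, dfe$mu, dfe$sigma),
    gamma_mixture = stats::dgamma(g, shape = dfe$alpha, scale = dfe$beta),
    bivariate_lognormal = {
      if (which == 1) stats::dlnorm(g, dfe$mu1, dfe$sigma1) else stats::dlnorm(g, dfe$mu2, dfe$sigma2)
    }
  )
}

#' Joint density of a bivariate lognormal DFE
#'
#' Pointwise joint density over the negative quadrant. At `rho = 0` it
#' factorises into the product of the marginals. (The mixture families have
#' a singular diagonal component and therefore no pointwise 2D density;
#' their two components are integrated separately downstream.)
#'
#' @param dfe a `bivariate_lognormal_dfe`.
#' @param gamma1,gamma2 strictly negative coefficients (vectorised).
#' @return non-negative density value(s).
#' @export
joint_pdf <- function(dfe, gamma1, gamma2) {
  if (!inherits(dfe, "dfe_bivariate_lognormal")) {
    stop("joint_pdf is defined for the bivariate lognormal model; mixture models have a singular diagonal component")
  }
  if (any(gamma1 >= 0) || any(gamma2 >= 0)) stop("joint_pdf is defined on the negative quadrant only")
  z1 <- (log(-gamma1) - dfe$mu1) / dfe$sigma1
  z2 <- (log(-gamma2) - dfe$mu2) / dfe$sigma2
  rho <- dfe$rho
  q <- (z1^2 + z2^2 - 2 * rho * z1 * z2) / (1 - rho^2)
  exp(-q / 2) / (2 * pi * dfe$sigma1 * dfe$sigma2 * sqrt(1 - rho^2) * (-gamma1) * (-gamma2))
}

#' Draw selection-coefficient pairs from a joint DFE
#'
#' Monte-Carlo sampler matching the mixture semantics: with probability `w`
#' the pair lies exactly on the diagonal (`gamma1 == gamma2`), otherwise
#' the two coefficients are independent draws from the marginal. The
#' bivariate lognormal draws from the correlated bivariate normal of logs.
#'
#' @param dfe a `dfe_model`.
#' @param n number of pairs.
#' @param seed optional integer seed.
#' @return an `n x 2` matrix of negative coefficients.
#' @export
sample_pairs <- function(dfe, n, seed = NULL) {
  stopifnot(inherits(dfe, "dfe_model"), n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  if (inherits(dfe, "dfe_mixture")) {
    rmarg <- switch(dfe$family,
      lognormal_mixture = function(k) stats::rlnorm(k, dfe$mu, dfe$sigma),
      gamma_mixture = function(k) stats::rgamma(k, shape = dfe$alpha, scale = dfe$beta)
    )
    shared <- stats::runif(n) < dfe$w
    g1 <- rmarg(n)
    g2 <- rmarg(n)
    g2[shared] <- g1[shared]
    cbind(gamma1 = -g1, gamma2 = -g2)
  } else {
    z <- matrix(stats::rnorm(2 * n), n, 2)
    z2 <- dfe$rho * z[, 1] + sqrt(1 - dfe$rho^2) * z[, 2]
    cbind(
      gamma1 = -exp(dfe$mu1 + dfe$sigma1 * z[, 1]),
      gamma2 = -exp(dfe$mu2 + dfe$sigma2 * z2)
    )
  }
}

#' Correlation of a joint DFE
#'
#' For the mixture families the correlation of the joint distribution
#' equals the mixture proportion `w` of the perfectly correlated component.
#' For the bivariate lognormal the reported value is `rho`, the correlation
#' of the *logs* of the coefficients (the raw-scale correlation of a
#' bivariate lognormal is smaller than `rho`; the log-scale value is what
#' comparisons of `w` and `rho` use).
#'
#' @param dfe a `dfe_model`.
#' @return scalar correlation.
#' @export
dfe_correlation <- function(dfe) {
  stopifnot(inherits(dfe, "dfe_model"))
  if (inherits(dfe, "dfe_mixture")) dfe$w else dfe$rho
}

# Internal: marginal CDF of |gamma| magnitudes.
marginal_cdf_mag <- function(dfe, q, which = 1) {
  switch(dfe$family,
    lognormal_mixture = stats::plnorm(q, dfe$mu, dfe$sigma),
    gamma_mixture = stats::pgamma(q, shape = dfe$alpha, scale = dfe$beta),
    bivariate_lognormal = {
      if (which == 1) stats::plnorm(q, dfe$mu1, dfe$sigma1) else stats::plnorm(q, dfe$mu2, dfe$sigma2)
    }
  )
}
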