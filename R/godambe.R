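# Composite-likelihood uncertainty via the Godambe information matrix.
# Because the Poisson random field ignores linkage, the inverse Hessian
# understates uncertainty; the sandwich H^-1 J H^-1 with J estimated from
# block-bootstrap spectra restores valid standard errors.

#' Bootstrap spectra set
#'
#' Bundles bootstrap joint spectra (e.g. per-genomic-chunk resamples) with
#' the per-replicate scaling factors for the selected mutation rate. When
#' `theta_scale` is omitted it defaults to the ratio of segregating sites
#' in each bootstrap spectrum to the original data.
#'
#' @param spectra list of observed `joint_spectrum` objects.
#' @param data the original observed `joint_spectrum`.
#' @param theta_scale optional numeric vector of per-replicate scalings.
#' @return an object of class `bootstrap_set`.
#' @export
bootstrap_set <- function(spectra, data, theta_scale = NULL) {
  stopifnot(length(spectra) >= 1, all(vapply(spectra, inherits, TRUE, "joint_spectrum")))
  if (is.null(theta_scale)) {
    n0 <- spectrum_sum(data)
    theta_scale <- vapply(spectra, spectrum_sum, 0) / n0
  }
  stopifnot(length(theta_scale) == length(spectra), all(theta_scale > 0))
  structure(list(spectra = spectra, theta_scale = theta_scale), class = "bootstrap_set")
}

fd_gradient <- function(fn, x, step) {
  d <- length(x)
  g <- numeric(d)
  for (i in seq_len(d)) {
    hi <- step * max(1, abs(x[i]))
    xp <- x
    xm <- x
    xp[i] <- x[i] + hi
    xm[i] <- x[i] - hi
    g[i] <- (fn(xp) - fn(xm)) / (2 * hi)
  }
  g
}

fd_hessian <- function(fn, x, step) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  h <- step * pmax(1, abs(x))
  for (i in seq_len(d)) {
    for (j in i:d) {
      if (i == j) {
        xp <- x
        xm <- x
        xp[i] <- x[i] + h[i]
        xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
      } else {
        xpp <- x
        xpm <- x
        xmp <- x
        xmm <- x
        xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm[i] <- x[i] + h[i]
        xpm[j] <- x[j] - h[j]
        xmp[i] <- x[i] - h[i]
        xmp[j] <- x[j] + h[j]
        xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

godambe_se_at_step <- function(fit, data, boots, step) {
  par_t <- fit$par_t
  ll0 <- fit$loglik_factory(data, 1)
  H <- -fd_hessian(ll0, par_t, step) # observed information (transformed scale)
  scores <- t(vapply(seq_along(boots$spectra), function(b) {
    llb <- fit$loglik_factory(boots$spectra[[b]], boots$theta_scale[b])
    fd_gradient(llb, par_t, step)
  }, numeric(length(par_t))))
  J <- stats::cov(scores)
  Hinv <- tryCatch(solve(H), error = function(e) {
    stop("singular Hessian in Godambe computation; check convergence or step size")
  })
  V_t <- Hinv %*% J %*% Hinv
  # delta method back to the natural parameter scale
  est <- unpack_params(par_t, fit$free)
  jac <- vapply(fit$free, function(nm) {
    transform_jacobian(est[[nm]], param_transforms[[nm]])
  }, 0)
  V <- diag(jac, length(jac)) %*% V_t %*% diag(jac, length(jac))
  stats::setNames(sqrt(pmax(diag(V), 0)), fit$free)
}

#' Godambe sandwich standard errors for a composite-likelihood fit
#'
#' Computes the sandwich variance `H^-1 J H^-1` at the maximum
#' composite-likelihood estimate: `H` is the central-finite-difference
#' Hessian of the composite log-likelihood on the original data and `J`
#' the empirical covariance of bootstrap score vectors, each bootstrap
#' evaluated with the selected mutation rate scaled by its
#' segregating-sites ratio. Derivatives are taken on the transformed
#' parameter scale and mapped back by the delta method. A second
#' evaluation at `step / 10` cross-checks step-size sensitivity.
#'
#' @param fit a `dfe_fit` or `demog_fit`.
#' @param data the original observed `joint_spectrum` the fit used.
#' @param boots a [bootstrap_set()].
#' @param step relative finite-difference step on the transformed scale.
#' @return named vector of standard errors (natural scale), with attributes
#'   `se_check` (the `step / 10` values) and `step_sensitive` (logical).
#' @export
godambe_se <- function(fit, data, boots, step = 1e-2) {
  stopifnot(inherits(fit, "jointdfe_fit"), inherits(boots, "bootstrap_set"))
  if (!fit$converged) warning("fit did not converge; Godambe uncertainties may be unreliable")
  if (length(boots$spectra) < 20) {
    warning("fewer than 20 bootstrap spectra; score covariance may be noisy")
  }
  se <- godambe_se_at_step(fit, data, boots, step)
  se_check <- godambe_se_at_step(fit, data, boots, step / 10)
  rel <- abs(se_check - se) / pmax(se, .Machine$double.eps)
  sensitive <- any(rel[se > 0] > 0.2)
  if (isTRUE(sensitive)) {
    warning(sprintf(
      "Godambe standard errors shift by more than 20%% between steps %g and %g",
      step, step / 10
    ))
  }
  attr(se, "se_check") <- se_check
  attr(se, "step_sensitive") <- sensitive
  se
}
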