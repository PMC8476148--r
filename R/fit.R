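#' Poisson random field composite log-likelihood
#'
#' Treats every unmasked AFS entry as an independent Poisson count with the
#' model expectation as its rate (the Poisson Random Field): the composite
#' log-likelihood is `sum(-lambda + S * log(lambda) - log(S!))` over
#' unmasked entries. Entries with zero expectation but non-zero data give
#' `-Inf` with a warning.
#'
#' @param model expected `joint_spectrum`.
#' @param data observed `joint_spectrum` of the same shape and mask.
#' @return scalar composite log-likelihood.
#' @export
poisson_loglik <- function(model, data) {
  stopifnot(inherits(model, "joint_spectrum"), inherits(data, "joint_spectrum"))
  if (!identical(dim(model), dim(data))) stop("model and data spectra have different shapes")
  mask <- attr(model, "mask") | attr(data, "mask")
  lam <- unclass(model)[!mask]
  s <- unclass(data)[!mask]
  if (any(lam == 0 & s > 0)) {
    warning("model assigns zero expectation to entries with observed counts; log-likelihood is -Inf")
    return(-Inf)
  }
  term <- -lam - lgamma(s + 1)
  pos <- s > 0
  term[pos] <- term[pos] + s[pos] * log(lam[pos])
  sum(term)
}

# ---- parameter transforms ------------------------------------------------

logit <- function(p) stats::qlogis(pmin(pmax(p, 1e-9), 1 - 1e-9))
inv_logit <- function(x) stats::plogis(x)

to_transformed <- function(value, trans) {
  switch(trans,
    log = log(value),
    logit = logit(value),
    tanh = atanh(max(min(value, 1 - 1e-9), -1 + 1e-9)),
    identity = value
  )
}

from_transformed <- function(x, trans) {
  switch(trans,
    log = exp(x),
    logit = inv_logit(x),
    tanh = tanh(x),
    identity = x
  )
}

# d(natural)/d(transformed), evaluated at the natural value
transform_jacobian <- function(value, trans) {
  switch(trans,
    log = value,
    logit = value * (1 - value),
    tanh = 1 - value^2,
    identity = 1
  )
}

param_transforms <- c(
  nu1 = "log", nu2 = "log", T = "log", m12 = "log", m21 = "log",
  nu_pre = "log", T_pre = "log", s_frac = "logit",
  mu = "identity", sigma = "log", alpha = "log", beta = "log", w = "logit",
  mu1 = "identity", sigma1 = "log", mu2 = "identity", sigma2 = "log",
  rho = "tanh", p_misid = "logit"
)

pack_params <- function(values, names) {
  vapply(names, function(nm) to_transformed(values[[nm]], param_transforms[[nm]]), 0)
}

unpack_params <- function(par_t, names) {
  out <- vapply(
    seq_along(names),
    function(i) from_transformed(par_t[[i]], param_transforms[[names[[i]]]]), 0
  )
  stats::setNames(out, names)
}

# Bounded multi-start Nelder-Mead on transformed parameters. Restarts
# perturb the starting point; ties between equal-likelihood optima are
# broken toward the lexicographically smallest transformed vector.
multistart_optim <- function(par0_t, fn, n_starts = 5, seed = 0,
                             reltol = 1e-8, maxit = 2000, jitter_sd = 0.5) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  d <- length(par0_t)
  if (d == 0) {
    return(list(
      par = par0_t, value = fn(par0_t), converged = TRUE,
      start_values = fn(par0_t), start_codes = 0L
    ))
  }
  best <- NULL
  values <- numeric(0)
  codes <- integer(0)
  for (k in seq_len(n_starts)) {
    start <- if (k == 1) par0_t else par0_t + stats::rnorm(d, 0, jitter_sd)
    res <- tryCatch(
      if (d == 1) {
        stats::optim(start, fn,
          method = "Brent", lower = start - 20, upper = start + 20,
          control = list(maxit = maxit)
        )
      } else {
        stats::optim(start, fn,
          method = "Nelder-Mead",
          control = list(reltol = reltol, maxit = maxit)
        )
      },
      error = function(e) NULL
    )
    if (is.null(res)) next
    values <- c(values, res$value)
    codes <- c(codes, res$convergence)
    if (is.null(best) || res$value < best$value ||
      (res$value <= best$value + 1e-10 && lex_less(res$par, best$par))) {
      best <- res
    }
  }
  if (is.null(best)) stop("optimization failed in every start")
  list(
    par = best$par, value = best$value,
    converged = best$convergence == 0,
    start_values = values, start_codes = codes
  )
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) {
      return(TRUE)
    }
    if (a[i] > b[i]) {
      return(FALSE)
    }
  }
  FALSE
}

# ---- demographic fitting -------------------------------------------------

default_free_demo <- function(id) {
  switch(id,
    equilibrium = character(0),
    split_mig = c("nu1", "nu2", "T", "m12", "m21"),
    split_no_mig = c("nu1", "nu2", "T"),
    IM = c("s_frac", "nu1", "nu2", "T", "m12", "m21"),
    IM_pre = c("nu_pre", "T_pre", "s_frac", "nu1", "nu2", "T", "m12", "m21")
  )
}

#' Fit a demographic model to a neutral joint spectrum
#'
#' Maximises the Poisson composite likelihood of the neutral joint AFS over
#' the model's demographic parameters and an ancestral-misidentification
#' probability, with the neutral mutation rate `theta_neu` profiled
#' analytically (`theta_hat = sum(data) / sum(model at theta = 1)` over
#' unmasked entries). Optimisation is bounded multi-start Nelder-Mead on
#' transformed parameters (log for positive quantities, logit for
#' fractions).
#'
#' @param data observed neutral `joint_spectrum`.
#' @param model a [demographic_model()] used as template and starting point.
#' @param free names of parameters to optimise (default: all parameters of
#'   the model id).
#' @param misid if `TRUE`, a free misidentification probability is included.
#' @param p_misid_start starting value for the misidentification parameter.
#' @param n_starts number of perturbed optimiser restarts.
#' @param seed RNG seed controlling the restarts.
#' @param pts engine extrapolation grid sizes.
#' @param reltol,maxit optimiser control.
#' @return a `demog_fit` object with estimates, profiled `theta_neu`,
#'   maximized log-likelihood, and diagnostics.
#' @export
fit_demography <- function(data, model, free = NULL, misid = TRUE,
                           p_misid_start = 0.02, n_starts = 5, seed = 0,
                           pts = NULL, reltol = 1e-8, maxit = 2000) {
  stopifnot(inherits(data, "joint_spectrum"), inherits(model, "demographic_model"))
  ns <- sample_sizes(data)
  if (is.null(pts)) pts <- default_pts(ns[1], ns[2])
  if (is.null(free)) free <- default_free_demo(model$id)
  par_names <- c(free, if (misid) "p_misid")
  start_vals <- c(unclass(model)[free], if (misid) list(p_misid = p_misid_start))
  par0_t <- pack_params(start_vals, par_names)

  make_loglik <- function(dat, theta_scale = 1) {
    force(dat)
    function(par_t) {
      vals <- unpack_params(par_t, par_names)
      demo <- model
      demo[free] <- vals[free]
      p <- if (misid) vals[["p_misid"]] else 0
      fs <- tryCatch(
        expected_joint_afs(demo, selection_regime(0, 0), ns[1], ns[2], pts = pts),
        error = function(e) NULL
      )
      if (is.null(fs)) {
        return(-Inf)
      }
      fs <- misid_transform(fs, p)
      theta_hat <- spectrum_sum(dat) / spectrum_sum(fs)
      suppressWarnings(poisson_loglik(respectrum(unclass(fs) * theta_hat, fs), dat))
    }
  }
  ll <- make_loglik(data)
  opt <- multistart_optim(par0_t, function(p) -ll(p),
    n_starts = n_starts,
    seed = seed, reltol = reltol, maxit = maxit
  )
  est <- unpack_params(opt$par, par_names)
  demo_hat <- model
  demo_hat[free] <- est[free]
  fs_hat <- expected_joint_afs(demo_hat, selection_regime(0, 0), ns[1], ns[2], pts = pts)
  fs_hat <- misid_transform(fs_hat, if (misid) est[["p_misid"]] else 0)
  theta_neu <- spectrum_sum(data) / spectrum_sum(fs_hat)
  structure(
    list(
      params = c(est, theta_neu = theta_neu), demo = demo_hat,
      free = par_names, par_t = opt$par, loglik = -opt$value,
      converged = opt$converged, starts = n_starts, seed = seed,
      start_values = -opt$start_values, start_codes = opt$start_codes,
      loglik_factory = make_loglik, pts = pts,
      kind = "demography"
    ),
    class = c("demog_fit", "jointdfe_fit")
  )
}

# ---- DFE fitting ---------------------------------------------------------

default_free_dfe <- function(family) {
  switch(family,
    lognormal_mixture = c("mu", "sigma", "w"),
    gamma_mixture = c("alpha", "beta", "w"),
    bivariate_lognormal = c("mu1", "sigma1", "mu2", "sigma2", "rho")
  )
}

#' Fit a joint-DFE model to a selected joint spectrum
#'
#' Maximises the Poisson composite likelihood of the selected joint AFS
#' over the DFE parameters and a separate ancestral-misidentification
#' probability, holding the selected mutation rate `theta_sel` fixed (a
#' multiple of the neutral rate from the demographic fit; never free).
#' Expected spectra come from DFE integration over a selection cache built
#' under the fitted demographic model.
#'
#' @param data observed selected `joint_spectrum`.
#' @param cache a `selection_cache` built under the fitted demography.
#' @param dfe a `dfe_model` used as template and starting point.
#' @param theta_sel fixed selected-class mutation rate (scalar or
#'   [theta_config()]).
#' @param free names of DFE parameters to optimise (default: all of the
#'   family).
#' @param misid include a free misidentification probability.
#' @param p_misid_start starting misidentification probability.
#' @param n_starts,seed,reltol,maxit optimiser control.
#' @return a `dfe_fit` object; estimates pinned at a parameter boundary
#'   (e.g. `w` at 0 or 1) are flagged in `$boundary`.
#' @export
fit_dfe <- function(data, cache, dfe, theta_sel, free = NULL, misid = TRUE,
                    p_misid_start = 0.02, n_starts = 5, seed = 0,
                    reltol = 1e-8, maxit = 2000) {
  stopifnot(
    inherits(data, "joint_spectrum"), inherits(cache, "selection_cache"),
    inherits(dfe, "dfe_model")
  )
  ns <- sample_sizes(data)
  if (cache$n1 != ns[1] || cache$n2 != ns[2]) {
    stop("cache sample sizes do not match the data; rebuild the cache")
  }
  if (is.list(theta_sel)) theta_sel <- theta_sel$theta_sel
  if (is.null(free)) free <- default_free_dfe(dfe$family)
  par_names <- c(free, if (misid) "p_misid")
  start_vals <- c(unclass(dfe)[free], if (misid) list(p_misid = p_misid_start))
  par0_t <- pack_params(start_vals, par_names)

  make_loglik <- function(dat, theta_scale = 1) {
    force(dat)
    force(theta_scale)
    function(par_t) {
      vals <- unpack_params(par_t, par_names)
      cur <- dfe
      cur[free] <- vals[free]
      p <- if (misid) vals[["p_misid"]] else 0
      fs <- tryCatch(
        expected_selected_afs(cache, cur, theta_sel * theta_scale, p),
        error = function(e) NULL
      )
      if (is.null(fs)) {
        return(-Inf)
      }
      suppressWarnings(poisson_loglik(fs, dat))
    }
  }
  ll <- make_loglik(data)
  opt <- multistart_optim(par0_t, function(p) -ll(p),
    n_starts = n_starts,
    seed = seed, reltol = reltol, maxit = maxit
  )
  est <- unpack_params(opt$par, par_names)
  dfe_hat <- dfe
  dfe_hat[free] <- est[free]
  boundary <- character(0)
  if ("w" %in% free && (est[["w"]] < 1e-4 || est[["w"]] > 1 - 1e-4)) boundary <- c(boundary, "w")
  if (misid && est[["p_misid"]] < 1e-6) boundary <- c(boundary, "p_misid")
  structure(
    list(
      params = est, dfe = dfe_hat, free = par_names, par_t = opt$par,
      loglik = -opt$value, converged = opt$converged, starts = n_starts,
      seed = seed, start_values = -opt$start_values,
      start_codes = opt$start_codes, boundary = boundary,
      theta_sel = theta_sel, loglik_factory = make_loglik,
      kind = "dfe"
    ),
    class = c("dfe_fit", "jointdfe_fit")
  )
}

#' @export
print.jointdfe_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit: logLik = %.4f, converged = %s\n", x$kind, x$loglik, x$converged
  ))
  print(round(x$params, 6))
  if (length(x$boundary)) {
    cat("boundary-pinned parameters:", paste(x$boundary, collapse = ", "), "\n")
  }
  invisible(x)
}
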