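# Simulation harness: precision studies (Poisson-sampled replicates under a
# known truth) and robustness studies (noise-free expected data fitted with
# deliberately misspecified models).

#' Default truth models for the simulation studies
#'
#' The precision and robustness studies use an isolation-with-migration
#' truth demography with divergence, exponential growth and asymmetric
#' migration, paired with a symmetric lognormal-mixture joint DFE with
#' `mu = 3.6`, `sigma = 5.1` (magnitudes of the kind inferred for human
#' population pairs). The demographic parameter values are this package's
#' choice of a realistic human-like history; see the methods vignette.
#'
#' @return a [demographic_model()] / [lognormal_mixture_dfe()].
#' @export
default_truth_demography <- function() {
  demographic_model("IM",
    s_frac = 0.8, nu1 = 3.0, nu2 = 3.2, T = 0.1,
    m12 = 1.0, m21 = 0.5
  )
}

#' @rdname default_truth_demography
#' @param w DFE correlation of the truth mixture.
#' @export
default_truth_dfe <- function(w = 0.9) {
  lognormal_mixture_dfe(mu = 3.6, sigma = 5.1, w = w)
}

#' Specification of a simulation experiment
#'
#' Bundles the truth models, sample configuration, mutation rate, replicate
#' count and base seed of one simulation experiment, together with the
#' (possibly misspecified) templates used in fitting. Per-replicate seeds
#' are derived deterministically from the base seed, so a spec reruns
#' bit-reproducibly.
#'
#' @param truth_demo truth [demographic_model()].
#' @param truth_dfe truth `dfe_model`.
#' @param h_truth dominance used when simulating selected data.
#' @param n1,n2 haploid sample sizes.
#' @param theta_ns population-scaled selected-class mutation rate.
#' @param replicates number of Poisson replicates.
#' @param seed base RNG seed.
#' @param fit_demo demography used in fitting: `"true"` (default) reuses
#'   the truth model, or a [demographic_model()] template to refit to the
#'   neutral expectation (model misspecification studies).
#' @param fit_dfe DFE template (with starting values) for fitting; default
#'   a lognormal mixture started at mu = 1, sigma = 2, w = 0.5.
#' @param h_fit dominance assumed in fitting (default additive, 0.5).
#' @param grid_points,gamma_bounds selection-cache resolution and domain.
#' @param p_misid_truth misidentification injected into simulated data.
#' @param ratio_NS selected-to-neutral mutation influx ratio.
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(truth_demo = default_truth_demography(),
                            truth_dfe = default_truth_dfe(),
                            h_truth = 0.5, n1 = 20, n2 = 20,
                            theta_ns = 13842.5, replicates = 10, seed = 1,
                            fit_demo = "true",
                            fit_dfe = lognormal_mixture_dfe(1, 2, 0.5),
                            h_fit = 0.5, grid_points = 25,
                            gamma_bounds = c(1e-4, 2000),
                            p_misid_truth = 0, ratio_NS = 2.31) {
  stopifnot(replicates >= 1, inherits(truth_demo, "demographic_model"), inherits(truth_dfe, "dfe_model"))
  structure(
    list(
      truth_demo = truth_demo, truth_dfe = truth_dfe, h_truth = h_truth,
      n1 = n1, n2 = n2, theta_ns = theta_ns, replicates = replicates,
      seed = seed, fit_demo = fit_demo, fit_dfe = fit_dfe, h_fit = h_fit,
      grid_points = grid_points, gamma_bounds = gamma_bounds,
      p_misid_truth = p_misid_truth, ratio_NS = ratio_NS
    ),
    class = "experiment_spec"
  )
}

replicate_seeds <- function(base, n) {
  (abs(base) %% 1000003L) * 1000L + seq_len(n)
}

# Build (or reuse) the cache for a demography/dominance pair; memo is an
# environment keyed by the parameter values.
cache_for <- function(demo, n1, n2, grid, h, memo = NULL, verbose = 0) {
  key <- paste(c(
    demo$id, signif(unlist(unclass(demo)[-1]), 12), n1, n2,
    signif(grid[c(1, length(grid))], 12), length(grid), h
  ), collapse = "|")
  if (!is.null(memo) && !is.null(memo[[key]])) {
    return(memo[[key]])
  }
  cache <- build_cache(demo, n1, n2, grid = grid, h = h, verbose = verbose)
  if (!is.null(memo)) memo[[key]] <- cache
  cache
}

resolve_fit_demo <- function(spec, memo = NULL) {
  if (identical(spec$fit_demo, "true")) {
    return(list(demo = spec$truth_demo, refit = NULL))
  }
  stopifnot(inherits(spec$fit_demo, "demographic_model"))
  # noise-free neutral expectation under the truth, fitted with the
  # (misspecified) template
  theta_neu <- spec$theta_ns / spec$ratio_NS
  neutral_truth <- expected_joint_afs(
    spec$truth_demo, selection_regime(0, 0), spec$n1, spec$n2
  )
  neutral_data <- respectrum(unclass(neutral_truth) * theta_neu, neutral_truth, "observed")
  fit <- fit_demography(neutral_data, spec$fit_demo,
    misid = FALSE,
    n_starts = 2, seed = spec$seed
  )
  list(demo = fit$demo, refit = fit)
}

#' Run a precision experiment (Poisson-sampled replicates)
#'
#' Computes the expected selected joint AFS under the truth models, then,
#' for each replicate, Poisson-samples an observed spectrum and refits the
#' DFE (via a selection cache built under the fitting demography and
#' dominance). Reports per-replicate estimates and summary statistics.
#'
#' @param spec an [experiment_spec()].
#' @param n_starts optimiser restarts per replicate fit.
#' @param verbose progress reporting passed to [build_cache()].
#' @return a tibble with one row per replicate (estimates, log-likelihood,
#'   convergence); summary medians are attached as attribute `summary`.
#' @export
run_precision_experiment <- function(spec, n_starts = 2, verbose = 0) {
  stopifnot(inherits(spec, "experiment_spec"))
  grid <- build_gamma_grid(spec$grid_points, spec$gamma_bounds)
  memo <- new.env(parent = emptyenv())
  truth_cache <- cache_for(spec$truth_demo, spec$n1, spec$n2, grid, spec$h_truth, memo, verbose)
  expected <- expected_selected_afs(
    truth_cache, spec$truth_dfe, spec$theta_ns, spec$p_misid_truth
  )
  fitd <- resolve_fit_demo(spec, memo)
  fit_cache <- cache_for(fitd$demo, spec$n1, spec$n2, grid, spec$h_fit, memo, verbose)
  seeds <- replicate_seeds(spec$seed, spec$replicates)
  rows <- lapply(seq_len(spec$replicates), function(r) {
    obs <- poisson_sample_afs(expected, seed = seeds[r])
    fit <- tryCatch(
      fit_dfe(obs, fit_cache, spec$fit_dfe, spec$theta_ns,
        n_starts = n_starts, seed = seeds[r]
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(
        replicate = r, seed = seeds[r], converged = FALSE,
        loglik = NA_real_
      ))
    }
    est <- as.list(fit$params)
    names(est) <- paste0(names(est), "_hat")
    tibble::tibble(
      replicate = r, seed = seeds[r], !!!est,
      loglik = fit$loglik, converged = fit$converged
    )
  })
  out <- do.call(rbind, rows)
  est_cols <- grep("_hat$", names(out), value = TRUE)
  attr(out, "summary") <- vapply(
    out[est_cols], stats::median,
    numeric(1),
    na.rm = TRUE
  )
  attr(out, "spec") <- spec
  out
}

#' Robustness scenario description
#'
#' One model-misspecification scenario of the robustness suite: the truth
#' DFE family/dominance/demography used to generate noise-free expected
#' data, the (possibly different) models used in fitting, and the sweep of
#' true correlation values.
#'
#' @param name scenario label.
#' @param truth_dfe_fn function mapping a correlation value to the truth
#'   `dfe_model` (for the bivariate family the value is `rho`).
#' @param w_values correlation sweep.
#' @param truth_demo,h_truth truth demography and dominance.
#' @param fit_demo `"true"` or a misspecified [demographic_model()]
#'   template to refit.
#' @param h_fit dominance assumed when fitting.
#' @return an object of class `robustness_scenario`.
#' @export
robustness_scenario <- function(name, truth_dfe_fn,
                                w_values = c(0.8, 0.9, 1.0),
                                truth_demo = default_truth_demography(),
                                h_truth = 0.5, fit_demo = "true", h_fit = 0.5) {
  stopifnot(is.function(truth_dfe_fn))
  structure(
    list(
      name = name, truth_dfe_fn = truth_dfe_fn, w_values = w_values,
      truth_demo = truth_demo, h_truth = h_truth, fit_demo = fit_demo,
      h_fit = h_fit
    ),
    class = "robustness_scenario"
  )
}

#' Standard robustness scenarios
#'
#' The four misspecification scenarios of the robustness study: refitting
#' with a no-migration demography, truth dominance of 0.25 and 0.75 fitted
#' as additive, a gamma-mixture truth (`alpha = 0.4`, `beta = 1400`) fitted
#' with the lognormal mixture, and symmetric / asymmetric bivariate
#' lognormal truths fitted with the symmetric mixture.
#'
#' @param w_values correlation sweep shared by the scenarios.
#' @return named list of [robustness_scenario()] objects.
#' @export
standard_robustness_scenarios <- function(w_values = c(0.8, 0.9, 1.0)) {
  list(
    misspec_demography = robustness_scenario(
      "misspec_demography",
      truth_dfe_fn = function(w) default_truth_dfe(w),
      w_values = w_values,
      fit_demo = demographic_model("split_no_mig", nu1 = 2, nu2 = 2, T = 0.1)
    ),
    dominance_low = robustness_scenario(
      "dominance_low",
      truth_dfe_fn = function(w) default_truth_dfe(w),
      w_values = w_values, h_truth = 0.25
    ),
    dominance_high = robustness_scenario(
      "dominance_high",
      truth_dfe_fn = function(w) default_truth_dfe(w),
      w_values = w_values, h_truth = 0.75
    ),
    gamma_truth = robustness_scenario(
      "gamma_truth",
      truth_dfe_fn = function(w) gamma_mixture_dfe(alpha = 0.4, beta = 1400, w = w),
      w_values = w_values
    ),
    bivariate_symmetric = robustness_scenario(
      "bivariate_symmetric",
      truth_dfe_fn = function(rho) bivariate_lognormal_dfe(3.6, 5.1, rho = min(rho, 1 - 1e-6)),
      w_values = w_values
    ),
    bivariate_asymmetric = robustness_scenario(
      "bivariate_asymmetric",
      truth_dfe_fn = function(rho) {
        bivariate_lognormal_dfe(3.6, 5.1, 4.5, 6.8, rho = min(rho, 1 - 1e-6))
      },
      w_values = w_values
    )
  )
}

#' Run the robustness suite (noise-free bias study)
#'
#' For each scenario and each true correlation, generates the noise-free
#' expected selected spectrum under the truth models and fits the
#' lognormal-mixture DFE with the scenario's fitting models (bias, not
#' variance, is of interest, so no Poisson sampling is applied). Caches are
#' shared across scenarios with identical demography/dominance.
#'
#' @param scenarios list of [robustness_scenario()] objects.
#' @param n1,n2 haploid sample sizes.
#' @param theta_ns selected-class mutation rate.
#' @param grid_points,gamma_bounds cache resolution and domain.
#' @param fit_dfe_template DFE template for fitting.
#' @param n_starts,seed optimiser control.
#' @param verbose progress reporting.
#' @return a tibble with one row per (scenario, w) pair: truth value and
#'   fitted `mu`, `sigma`, `w` estimates.
#' @export
run_robustness_suite <- function(scenarios, n1 = 20, n2 = 20,
                                 theta_ns = 13842.5, grid_points = 25,
                                 gamma_bounds = c(1e-4, 2000),
                                 fit_dfe_template = lognormal_mixture_dfe(1, 2, 0.5),
                                 n_starts = 2, seed = 1, verbose = 0) {
  grid <- build_gamma_grid(grid_points, gamma_bounds)
  memo <- new.env(parent = emptyenv())
  rows <- list()
  for (sc in scenarios) {
    stopifnot(inherits(sc, "robustness_scenario"))
    truth_cache <- cache_for(sc$truth_demo, n1, n2, grid, sc$h_truth, memo, verbose)
    spec0 <- experiment_spec(
      truth_demo = sc$truth_demo, n1 = n1, n2 = n2,
      theta_ns = theta_ns, seed = seed, fit_demo = sc$fit_demo,
      grid_points = grid_points, gamma_bounds = gamma_bounds
    )
    fitd <- resolve_fit_demo(spec0, memo)
    fit_cache <- cache_for(fitd$demo, n1, n2, grid, sc$h_fit, memo, verbose)
    for (w in sc$w_values) {
      truth_dfe <- sc$truth_dfe_fn(w)
      expected <- expected_selected_afs(truth_cache, truth_dfe, theta_ns, 0)
      data <- respectrum(unclass(expected), expected, "observed")
      fit <- fit_dfe(data, fit_cache, fit_dfe_template, theta_ns,
        misid = FALSE,
        n_starts = n_starts, seed = seed
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        scenario = sc$name, w_true = w,
        mu_hat = fit$params[["mu"]], sigma_hat = fit$params[["sigma"]],
        w_hat = fit$params[["w"]], loglik = fit$loglik,
        converged = fit$converged
      )
    }
  }
  do.call(rbind, rows)
}
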