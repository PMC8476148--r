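test_that("replicate seeds derive deterministically from the base seed", {
  s1 <- jointdfe:::replicate_seeds(42, 10)
  s2 <- jointdfe:::replicate_seeds(42, 10)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 10)
  expect_true(all(s1 < 2^31))
  expect_false(any(jointdfe:::replicate_seeds(43, 10) %in% s1))
})

test_that("a precision experiment reruns bit-reproducibly and recovers truth without noise", {
  spec <- experiment_spec(
    n1 = 8, n2 = 8, replicates = 2, grid_points = 8, seed = 5,
    truth_dfe = default_truth_dfe(0.9)
  )
  r1 <- run_precision_experiment(spec)
  r2 <- run_precision_experiment(spec)
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
  expect_true(all(r1$converged))
  # noise-free self-consistency: fitting the expected spectrum itself
  grid <- build_gamma_grid(8, c(1e-4, 2000))
  cache <- jointdfe:::cache_for(spec$truth_demo, 8, 8, grid, 0.5)
  expc <- expected_selected_afs(cache, spec$truth_dfe, spec$theta_ns)
  data <- joint_spectrum(unclass(expc), kind = "observed")
  fit <- fit_dfe(data, cache, lognormal_mixture_dfe(1, 2, 0.5), spec$theta_ns,
    misid = FALSE, n_starts = 2, seed = 1
  )
  expect_equal(unname(fit$params["mu"]), 3.6, tolerance = 1e-2)
  expect_equal(unname(fit$params["sigma"]), 5.1, tolerance = 1e-2)
  expect_lt(abs(fit$params[["w"]] - 0.9), 0.01)
})

test_that("robustness scenarios are assembled with the stated truth models", {
  sc <- standard_robustness_scenarios(c(0.8, 1.0))
  expect_named(sc, c(
    "misspec_demography", "dominance_low", "dominance_high",
    "gamma_truth", "bivariate_symmetric", "bivariate_asymmetric"
  ))
  expect_equal(sc$dominance_low$h_truth, 0.25)
  expect_equal(sc$dominance_high$h_truth, 0.75)
  g <- sc$gamma_truth$truth_dfe_fn(0.9)
  expect_s3_class(g, "dfe_gamma_mixture")
  expect_equal(g$alpha, 0.4)
  expect_equal(g$beta, 1400)
  b <- sc$bivariate_asymmetric$truth_dfe_fn(0.85)
  expect_equal(c(b$mu1, b$sigma1, b$mu2, b$sigma2), c(3.6, 5.1, 4.5, 6.8))
  expect_equal(b$rho, 0.85)
  expect_s3_class(sc$misspec_demography$fit_demo, "demographic_model")
  expect_equal(sc$misspec_demography$fit_demo$id, "split_no_mig")
})

test_that("divergence-time sweep: w is hardest to infer at tiny divergence", {
  # noise-free fits are exact, so probe the information content through the
  # spread of Poisson-replicate estimates at small vs moderate divergence
  ws <- lapply(c(1e-4, 1e-1), function(T) {
    demo <- demographic_model("IM",
      s_frac = 0.8, nu1 = 3.0, nu2 = 3.2, T = T,
      m12 = 1.0, m21 = 0.5
    )
    spec <- experiment_spec(
      truth_demo = demo, n1 = 8, n2 = 8, replicates = 4,
      grid_points = 8, seed = 11, truth_dfe = default_truth_dfe(0.9)
    )
    res <- run_precision_experiment(spec)
    res$w_hat
  })
  spread <- vapply(ws, function(x) diff(range(x)), 0)
  expect_gt(spread[1], spread[2])
})
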