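test_that("the Poisson composite log-likelihood matches the closed form and the pmf", {
  # all unmasked lambda = 1, data = 1: per-entry term is exactly -1
  ones <- joint_spectrum(matrix(1, 5, 5))
  obs <- joint_spectrum(matrix(1, 5, 5), kind = "observed")
  expect_equal(poisson_loglik(ones, obs), -(25 - 2))
  # random integer spectrum against a random positive model: per-entry
  # Poisson pmf log-sum oracle
  set.seed(9)
  lam <- matrix(runif(25, 0.1, 10), 5, 5)
  cnt <- matrix(rpois(25, 4), 5, 5)
  model <- joint_spectrum(lam)
  data <- joint_spectrum(cnt, kind = "observed")
  mask <- attr(model, "mask")
  oracle <- sum(dpois(cnt[!mask], lam[!mask], log = TRUE))
  expect_equal(poisson_loglik(model, data), oracle, tolerance = 1e-10)
  # additivity over disjoint entry subsets via complementary masks
  m1 <- matrix(FALSE, 5, 5)
  m1[, 1:2] <- TRUE
  m2 <- !m1
  part1 <- poisson_loglik(
    joint_spectrum(lam, mask = m1), joint_spectrum(cnt, mask = m1, kind = "observed")
  )
  part2 <- poisson_loglik(
    joint_spectrum(lam, mask = m2), joint_spectrum(cnt, mask = m2, kind = "observed")
  )
  corners <- dpois(cnt[1, 1], lam[1, 1], log = TRUE) + dpois(cnt[5, 5], lam[5, 5], log = TRUE)
  full <- sum(dpois(cnt, lam, log = TRUE))
  expect_equal(part1 + part2 + corners, full, tolerance = 1e-10)
  # zero model with observed counts
  lam0 <- lam
  lam0[2, 2] <- 0
  expect_warning(ll <- poisson_loglik(joint_spectrum(lam0), data), "zero expectation")
  expect_identical(ll, -Inf)
  expect_error(poisson_loglik(model, toy_observed(3, 3)), "different shapes")
})

test_that("theta profiling is the exact Poisson closed form", {
  demo <- tiny_demo()
  fs <- expected_joint_afs(demo, selection_regime(0, 0), 6, 6)
  data <- joint_spectrum(unclass(fs) * 1234.5, kind = "observed")
  fit <- fit_demography(data, demo, free = character(0), misid = FALSE, n_starts = 1)
  expect_equal(unname(fit$params["theta_neu"]), 1234.5, tolerance = 1e-10)
})

test_that("demographic parameters are recovered from noise-free data", {
  truth <- demographic_model("split_no_mig", nu1 = 1.8, nu2 = 0.9, T = 0.2)
  fs <- expected_joint_afs(truth, selection_regime(0, 0), 8, 8)
  data <- joint_spectrum(unclass(fs) * 5000, kind = "observed")
  start <- demographic_model("split_no_mig", nu1 = 1.2, nu2 = 1.2, T = 0.1)
  fit <- fit_demography(data, start, misid = FALSE, n_starts = 1, seed = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$params["nu1"]), 1.8, tolerance = 1e-2)
  expect_equal(unname(fit$params["nu2"]), 0.9, tolerance = 1e-2)
  expect_equal(unname(fit$params["T"]), 0.2, tolerance = 1e-2)
  expect_equal(unname(fit$params["theta_neu"]), 5000, tolerance = 1e-2)
  # likelihood-ratio sanity: truth never beats the fitted optimum
  ll_truth <- fit$loglik_factory(data)(jointdfe:::pack_params(
    list(nu1 = 1.8, nu2 = 0.9, T = 0.2), c("nu1", "nu2", "T")
  ))
  expect_lte(ll_truth, fit$loglik + 1e-5)
})

test_that("DFE parameters and misidentification are recovered from noise-free data", {
  cache <- tiny_cache()
  truth <- lognormal_mixture_dfe(3.6, 5.1, 0.9)
  expc <- expected_selected_afs(cache, truth, 5000, 0.015)
  data <- joint_spectrum(unclass(expc), kind = "observed")
  fit <- fit_dfe(data, cache, lognormal_mixture_dfe(1, 2, 0.5), 5000, n_starts = 2, seed = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$params["mu"]), 3.6, tolerance = 1e-2)
  expect_equal(unname(fit$params["sigma"]), 5.1, tolerance = 1e-2)
  expect_lt(abs(fit$params[["w"]] - 0.9), 0.01)
  expect_lt(abs(fit$params[["p_misid"]] - 0.015), 1e-3)
  # w at the boundary is flagged
  expc1 <- expected_selected_afs(cache, lognormal_mixture_dfe(3.6, 5.1, 1), 5000)
  data1 <- joint_spectrum(unclass(expc1), kind = "observed")
  fit1 <- fit_dfe(data1, cache, lognormal_mixture_dfe(3, 4, 0.8), 5000,
    misid = FALSE, n_starts = 1, seed = 2
  )
  expect_lt(abs(fit1$params[["w"]] - 1), 0.01)
  # mismatched sample sizes refused
  expect_error(
    fit_dfe(toy_observed(4, 4), cache, truth, 1000),
    "sample sizes"
  )
})

test_that("z-tests against w = 1 and Benjamini-Hochberg adjustment are exact", {
  out <- w_significance(c(1, 0.9), c(0.05, 0.05))
  expect_equal(out$p_value[1], 1)
  expect_equal(out$z[2], -2)
  expect_equal(out$p_value[2], 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(out$p_value[2], 0.0455, tolerance = 1e-3)
  # SEs engineered so the raw p-values are 0.01, 0.02, 0.04; the BH
  # adjustment then gives 0.03, 0.03, 0.04 by direct computation
  se <- 0.1 / qnorm(1 - c(0.01, 0.02, 0.04) / 2)
  bh <- w_significance(c(0.9, 0.9, 0.9), se)
  expect_equal(bh$p_value, c(0.01, 0.02, 0.04), tolerance = 1e-10)
  expect_equal(bh$p_adjusted, c(0.03, 0.03, 0.04), tolerance = 1e-10)
  expect_equal(
    w_significance(c(0.8, 0.8, 0.8), c(0.1, 0.1, 0.1))$p_adjusted,
    rep(2 * pnorm(-2), 3),
    tolerance = 1e-12
  )
  expect_error(w_significance(0.9, 0), "positive")
})

test_that("theta partitioning uses rate-weighted proportions that sum to one", {
  expect_equal(
    partition_theta(100, u = c(1, 1), d = c(3, 3), t = c(3, 3)),
    c(theta_deleterious = 50, theta_tolerated = 50)
  )
  expect_equal(
    partition_theta(1, u = 1, d = 3, t = 1),
    c(theta_deleterious = 0.75, theta_tolerated = 0.25)
  )
  # rate-weighted: u = (1, 2), d = (10, 0), t = (0, 10)
  expect_equal(
    unname(partition_theta(1, u = c(1, 2), d = c(10, 0), t = c(0, 10))),
    c(1 / 3, 2 / 3),
    tolerance = 1e-12
  )
  expect_error(partition_theta(1, u = c(1, 1), d = c(0, 0), t = c(0, 0)), "non-zero")
})
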