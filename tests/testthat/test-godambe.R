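# Godambe sandwich machinery on a small cached fit; the factor-of-1.5
# agreement with direct bootstrap refitting is exercised at scale in the
# acceptance suite.

godambe_fixture <- function() {
  memo_fixture("godambe_fit", function() {
    cache <- tiny_cache()
    truth <- lognormal_mixture_dfe(3.6, 5.1, 0.9)
    expc <- expected_selected_afs(cache, truth, 8000, 0.01)
    obs <- poisson_sample_afs(expc, seed = 21)
    fit <- fit_dfe(obs, cache, lognormal_mixture_dfe(1, 2, 0.5), 8000,
      n_starts = 2, seed = 1
    )
    list(cache = cache, expc = expc, obs = obs, fit = fit)
  })
}

test_that("identical bootstrap spectra give zero score variance and zero SEs", {
  fx <- godambe_fixture()
  boots <- bootstrap_set(rep(list(fx$obs), 20), fx$obs)
  expect_equal(boots$theta_scale, rep(1, 20))
  se <- suppressWarnings(godambe_se(fx$fit, fx$obs, boots))
  expect_true(all(se < 1e-8))
})

test_that("Godambe SEs are stable between finite-difference steps", {
  fx <- godambe_fixture()
  boots <- bootstrap_set(
    lapply(1:20, function(b) poisson_sample_afs(fx$expc, seed = 500 + b)),
    fx$obs
  )
  se2 <- godambe_se(fx$fit, fx$obs, boots, step = 1e-2)
  se3 <- godambe_se(fx$fit, fx$obs, boots, step = 1e-3)
  expect_true(all(se2 > 0))
  expect_lt(max(abs(se3 - se2) / se2), 0.1)
  expect_false(attr(se2, "step_sensitive"))
  # bootstrap theta rescaling defaults to the segregating-sites ratio
  expect_equal(
    boots$theta_scale,
    vapply(boots$spectra, spectrum_sum, 0) / spectrum_sum(fx$obs)
  )
})

test_that("too few bootstraps are flagged", {
  fx <- godambe_fixture()
  boots <- bootstrap_set(
    lapply(1:5, function(b) poisson_sample_afs(fx$expc, seed = 900 + b)),
    fx$obs
  )
  expect_warning(godambe_se(fx$fit, fx$obs, boots), "fewer than 20")
})
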