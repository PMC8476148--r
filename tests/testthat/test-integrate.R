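test_that("tail weights partition the DFE mass", {
  dfe <- lognormal_mixture_dfe(3.6, 5.1, 0.9)
  tw <- tail_weights(dfe, c(1e-4, 2000))
  expect_equal(tw$below + tw$within + tw$above, 1, tolerance = 1e-6)
  # Gaussian CDF of (ln 2000 - mu) / sigma and the lower analogue
  expect_equal(tw$above, 1 - pnorm((log(2000) - 3.6) / 5.1), tolerance = 1e-12)
  expect_equal(tw$above, 0.216, tolerance = 3e-3)
  expect_equal(tw$below, 0.006, tolerance = 2e-3)
  # cross-check by quadrature of the density
  above_q <- integrate(function(g) marginal_pdf(dfe, -g), 2000, Inf, rel.tol = 1e-9)$value
  expect_equal(tw$above, above_q, tolerance = 1e-6)
  # joint block decomposition sums to one for both model kinds
  for (dfe2 in list(dfe, bivariate_lognormal_dfe(3.6, 5.1, 4.5, 6.8, rho = 0.6))) {
    blocks <- tail_weights_joint(dfe2, c(1e-4, 2000))
    expect_equal(sum(unlist(blocks)), 1, tolerance = 1e-6)
  }
})

test_that("DFE weight accounting is normalised during integration", {
  cache <- tiny_cache()
  models <- list(
    lognormal_mixture_dfe(3.6, 5.1, 0.9),
    lognormal_mixture_dfe(-1, 2, 0.3),
    gamma_mixture_dfe(0.4, 1400, 0.8),
    bivariate_lognormal_dfe(3.6, 5.1, rho = 0.9),
    bivariate_lognormal_dfe(3.6, 5.1, 4.5, 6.8, rho = 0.5)
  )
  for (dfe in models) {
    fs <- expected_selected_afs(cache, dfe, 1000)
    expect_equal(attr(fs, "weight_total"), 1, tolerance = 1e-3)
  }
})

test_that("the fully correlated mixture reduces to the diagonal integral", {
  cache <- tiny_cache()
  dfe1 <- lognormal_mixture_dfe(3.6, 5.1, 1)
  fs <- expected_selected_afs(cache, dfe1, 1)
  # manual 1D diagonal trapezoid with identical tail handling
  nw <- jointdfe:::marginal_node_weights(dfe1, cache$grid)
  np <- length(cache$grid)
  manual <- Reduce(`+`, lapply(seq_len(np), function(k) nw$weights[k] * cache$spectra[k, k, , ])) +
    nw$below * unclass(cache$neutral) + nw$above * cache$spectra[np, np, , ]
  expect_equal(unclass(fs), pmax(manual, 0), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("expected selected spectrum is linear in theta_sel", {
  cache <- tiny_cache()
  dfe <- lognormal_mixture_dfe(3.6, 5.1, 0.9)
  a <- expected_selected_afs(cache, dfe, 1000, 0.02)
  b <- expected_selected_afs(cache, dfe, 2000, 0.02)
  expect_equal(unclass(b), 2 * unclass(a), tolerance = 1e-12)
})

test_that("a near-degenerate DFE at a grid node returns that node's spectrum", {
  cache <- tiny_cache()
  k <- 7
  dfe <- lognormal_mixture_dfe(log(cache$grid[k]), 0.01, 1)
  fs <- expected_selected_afs(cache, dfe, 1)
  expect_spectra_close(fs, cache_spectrum(cache, k, k), 0.02)
})

test_that("an uncorrelated bivariate model matches the independent mixture component", {
  cache <- tiny_cache()
  biv <- bivariate_lognormal_dfe(3.6, 5.1, rho = 0)
  mix0 <- lognormal_mixture_dfe(3.6, 5.1, 0)
  a <- expected_selected_afs(cache, biv, 500)
  b <- expected_selected_afs(cache, mix0, 500)
  expect_spectra_close(a, b, 1e-8)
})

test_that("increasing the DFE correlation increases shared high-frequency polymorphism", {
  cache <- memo_fixture("sym_cache10", function() {
    build_cache(symmetric_demo(0.1), 6, 6, grid = build_gamma_grid(12, c(1e-4, 2000)))
  })
  tops <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(w) {
    fs <- expected_selected_afs(cache, lognormal_mixture_dfe(3.6, 5.1, w), 1000)
    unclass(fs)[6, 6]
  }, 0)
  expect_true(all(diff(tops) >= 0))
})
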