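test_that("the gamma grid is log-spaced with exact endpoints", {
  g <- build_gamma_grid(50, c(1e-4, 2000))
  expect_length(g, 50)
  expect_equal(g[1], 1e-4)
  expect_equal(g[50], 2000)
  ratios <- g[-1] / g[-50]
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-12)
  expect_equal(build_gamma_grid(2, c(0.5, 7)), c(0.5, 7))
  expect_error(build_gamma_grid(10, c(2, 1)), "bounds")
  expect_error(build_gamma_grid(1, c(1, 2)))
})

test_that("cache construction is complete and consistent with fresh engine runs", {
  cache <- tiny_cache()
  np <- length(cache$grid)
  expect_equal(dim(cache$spectra)[1:2], c(np, np))
  expect_false(anyNA(cache$spectra))
  # diagonal node equals a fresh engine evaluation
  k <- 5
  fresh <- expected_joint_afs(
    cache$demo, selection_regime(-cache$grid[k], -cache$grid[k], cache$h),
    cache$n1, cache$n2,
    pts = cache$pts
  )
  expect_equal(cache$spectra[k, k, , ], unclass(fresh), tolerance = 1e-12, ignore_attr = TRUE)
  # smallest-magnitude node is numerically neutral
  expect_spectra_close(cache_spectrum(cache, 1, 1), cache$neutral, 0.01)
})

test_that("a symmetric demography caches transpose-symmetric spectra", {
  cache <- memo_fixture("sym_cache", function() {
    build_cache(symmetric_demo(0.1), 5, 5, grid = build_gamma_grid(6, c(0.1, 100)))
  })
  scale <- max(cache$spectra)
  for (i in 1:6) {
    for (j in 1:6) {
      tol <- if (i == j) 2e-3 else 1e-12 # diagonal symmetry is solver-exactness
      expect_lt(max(abs(cache$spectra[i, j, , ] - t(cache$spectra[j, i, , ]))) / scale, tol)
    }
  }
})

test_that("cache save/load round-trips bit-exactly and guards demography mismatches", {
  cache <- tiny_cache()
  path <- tempfile(fileext = ".rds")
  save_cache(cache, path)
  back <- load_cache(path)
  expect_identical(back$spectra, cache$spectra)
  expect_identical(back$grid, cache$grid)
  expect_true(check_cache(back, cache$demo, cache$n1, cache$n2))
  other <- demographic_model("split_mig", nu1 = 1.9, nu2 = 3, T = 0.15, m12 = 0.5, m21 = 0.2)
  expect_error(check_cache(back, other), "different demographic parameters")
  expect_error(check_cache(back, cache$demo, 8, 8), "sample sizes")
  unlink(path)
})
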