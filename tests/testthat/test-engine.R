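test_that("neutral single-population equilibrium is theta / i", {
  for (n in c(4, 10, 20)) {
    fs <- equilibrium_spectrum_1d(0, 0.5, n)
    expect_equal(fs, 1 / seq_len(n - 1), tolerance = 1e-3)
  }
  expect_error(equilibrium_spectrum_1d(0, 0.5, 1), ">= 2")
  expect_error(equilibrium_spectrum_1d(NaN, 0.5, 4), "finite")
  expect_error(equilibrium_spectrum_1d(5, 0.5, 4), "positive selection")
})

test_that("weak selection converges to the neutral spectrum", {
  demo <- tiny_demo()
  neutral <- expected_joint_afs(demo, selection_regime(0, 0), 6, 6)
  weak <- expected_joint_afs(demo, selection_regime(-1e-4, -1e-4), 6, 6)
  expect_spectra_close(weak, neutral, 0.01)
})

test_that("exchangeable populations give a symmetric spectrum", {
  fs <- expected_joint_afs(symmetric_demo(0.05), selection_regime(-2, -2), 6, 6)
  v <- unclass(fs)
  expect_lt(max(abs(v - t(v))) / max(v), 1e-3)
})

test_that("long isolation decouples the populations", {
  demo <- demographic_model("split_no_mig", nu1 = 1, nu2 = 1, T = 3)
  fs <- expected_joint_afs(demo, selection_regime(0, 0), 8, 8)
  v <- unclass(fs)
  # shared intermediate-frequency polymorphism decays to ~0
  shared <- v[4:6, 4:6]
  expect_lt(max(shared), 0.01 * v[2, 1])
  # each marginal (variants private to one population) approaches the
  # single-population equilibrium theta / i
  eq <- 1 / (1:7)
  expect_equal(v[2:8, 1], eq, tolerance = 0.02)
  expect_equal(v[1, 2:8], eq, tolerance = 0.02)
})

test_that("stronger negative selection never increases shared high-frequency variants", {
  demo <- symmetric_demo(0.1)
  gammas <- c(0, -1, -5, -20, -100)
  tops <- vapply(gammas, function(g) {
    fs <- expected_joint_afs(demo, selection_regime(g, g), 6, 6)
    unclass(fs)[6, 6] # entry (n1 - 1, n2 - 1)
  }, 0)
  expect_true(all(diff(tops) <= 1e-10))
})

test_that("invalid engine inputs are rejected", {
  demo <- tiny_demo()
  expect_error(expected_joint_afs(demo, selection_regime(0, 0), 1, 6), ">= 2")
  expect_error(selection_regime(2, 0), "positive selection")
  expect_error(demographic_model("split_mig", nu1 = -1), "nu1")
})
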