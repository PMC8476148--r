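test_that("marginal densities are correct and normalised", {
  ln <- lognormal_mixture_dfe(3.6, 5.1, 0.9)
  # direct evaluation of the lognormal density of |gamma| at gamma = -1
  expect_equal(marginal_pdf(ln, -1), 0.06097, tolerance = 1e-3)
  gm <- gamma_mixture_dfe(0.4, 1400, 0.9)
  for (dfe in list(ln, gm)) {
    total <- integrate(function(g) marginal_pdf(dfe, -g), 0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-5)
  }
  # gamma-family mean of |gamma| is alpha * beta = 560
  m <- integrate(function(g) g * marginal_pdf(gm, -g), 0, Inf, rel.tol = 1e-9)$value
  expect_equal(m, 0.4 * 1400, tolerance = 1e-4)
  expect_error(marginal_pdf(ln, 0.5), "gamma < 0")
})

test_that("bivariate lognormal joint density factorises, is symmetric and normalised", {
  ind <- bivariate_lognormal_dfe(1.2, 0.8, rho = 0)
  g <- -exp(seq(-3, 3, length.out = 7))
  for (a in g) {
    for (b in g) {
      expect_equal(joint_pdf(ind, a, b), marginal_pdf(ind, a) * marginal_pdf(ind, b, 2),
        tolerance = 1e-12
      )
    }
  }
  sym <- bivariate_lognormal_dfe(3.6, 5.1, rho = 0.7)
  expect_equal(joint_pdf(sym, -2, -30), joint_pdf(sym, -30, -2), tolerance = 1e-12)
  # 2D quadrature of the density over the negative quadrant (log scale)
  total <- pracma::integral2(
    function(z1, z2) {
      joint_pdf(sym, -exp(z1), -exp(z2)) * exp(z1) * exp(z2)
    },
    3.6 - 8 * 5.1, 3.6 + 8 * 5.1, 3.6 - 8 * 5.1, 3.6 + 8 * 5.1,
    reltol = 1e-8
  )$Q
  expect_equal(total, 1, tolerance = 1e-3)
  expect_error(joint_pdf(sym, 1, -1), "negative quadrant")
})

test_that("mixture sampling has correlation w and marginals equal to the base distribution", {
  n <- 1e5
  for (w in c(0, 0.25, 0.5, 0.75, 1)) {
    dfe <- lognormal_mixture_dfe(3.6, 5.1, w)
    p <- sample_pairs(dfe, n, seed = 100 + round(100 * w))
    if (w == 1) {
      expect_true(all(p[, 1] == p[, 2]))
    } else {
      r <- cor(log(-p[, 1]), log(-p[, 2]))
      expect_lt(abs(r - w), 0.02)
    }
  }
  # marginals of the mixture are the one-dimensional base distribution
  dfe <- lognormal_mixture_dfe(3.6, 5.1, 0.6)
  p <- sample_pairs(dfe, 1e4, seed = 7)
  ref <- -stats::rlnorm(1e4, 3.6, 5.1)
  ks <- suppressWarnings(stats::ks.test(log(-p[, 2]), log(-ref)))
  expect_gt(ks$p.value, 0.01)
  # reproducibility
  expect_identical(sample_pairs(dfe, 10, seed = 1), sample_pairs(dfe, 10, seed = 1))
})

test_that("dfe_correlation returns the mixture weight or log-scale rho", {
  expect_equal(dfe_correlation(lognormal_mixture_dfe(3.6, 5.1, 0.9)), 0.9)
  expect_equal(dfe_correlation(gamma_mixture_dfe(0.4, 1400, 0.25)), 0.25)
  expect_equal(dfe_correlation(bivariate_lognormal_dfe(1, 1, rho = 0)), 0)
  # Monte-Carlo correlation of log magnitudes matches w
  p <- sample_pairs(lognormal_mixture_dfe(3.6, 5.1, 0.5), 1e5, seed = 5)
  expect_lt(abs(cor(log(-p[, 1]), log(-p[, 2])) - 0.5), 0.02)
})
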