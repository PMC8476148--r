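test_that("joint_spectrum validates shape, mask and values", {
  fs <- joint_spectrum(matrix(1, 5, 6))
  expect_equal(unname(sample_sizes(fs)), c(4L, 5L))
  mask <- attr(fs, "mask")
  expect_true(mask[1, 1])
  expect_true(mask[5, 6])
  expect_equal(sum(mask), 2L)
  expect_equal(spectrum_sum(fs), 30 - 2)
  # n = 1 axes rejected
  expect_error(joint_spectrum(matrix(1, 2, 5)), "sample sizes >= 2")
  # negative and non-finite unmasked entries rejected
  bad <- matrix(1, 5, 5)
  bad[2, 2] <- -1
  expect_error(joint_spectrum(bad), "non-negative")
  bad[2, 2] <- NaN
  expect_error(joint_spectrum(bad), "finite")
})

test_that("projection is the hypergeometric kernel", {
  # identity at the same size
  fs <- toy_observed(4, 4)
  expect_equal(unclass(project(fs, 4, 4)), unclass(fs), tolerance = 1e-12)
  # one variant at derived count 2 of n = 4 projected to n = 2:
  # weights C(2,k) C(2,2-k) / C(4,2) = 1/6, 4/6, 1/6
  v <- matrix(0, 5, 5)
  v[3, 2] <- 1 # count 2 in pop 1, count 1 in pop 2
  fs <- joint_spectrum(v)
  pr <- project(fs, 2, 4)
  expect_equal(unclass(pr)[, 2], c(1 / 6, 4 / 6, 1 / 6), tolerance = 1e-12)
  # upward projection refused
  expect_error(project(fs, 6, 4), "upward")
  # composition: projecting in two steps equals projecting directly
  big <- toy_observed(8, 8)
  expect_equal(
    unclass(project(project(big, 6, 6), 3, 4)),
    unclass(project(big, 3, 4)),
    tolerance = 1e-12
  )
})

test_that("misidentification transform conserves mass, with identity and reversal limits", {
  fs <- toy_observed(5, 4)
  expect_equal(unclass(misid_transform(fs, 0)), unclass(fs), ignore_attr = TRUE)
  rev <- misid_transform(fs, 1)
  v <- unclass(fs)
  expect_equal(unclass(rev), v[nrow(v):1, ncol(v):1], ignore_attr = TRUE)
  for (p in c(0.05, 0.3, 0.77)) {
    expect_equal(spectrum_sum(misid_transform(fs, p)), spectrum_sum(fs), tolerance = 1e-12)
  }
  expect_error(misid_transform(fs, 1.2), "\\[0, 1\\]")
})

test_that("Poisson sampling is reproducible and respects zero expectations", {
  v <- matrix(c(0, 3, 5, 0, 2, 0, 8, 1, 0.5, 0, 4, 0, 1, 2, 0, 6), 4, 4)
  fs <- joint_spectrum(v)
  a <- poisson_sample_afs(fs, seed = 3)
  b <- poisson_sample_afs(fs, seed = 3)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(unclass(a)[unclass(fs) == 0] == 0))
  expect_true(all(unclass(a) == round(unclass(a))))
  # law of large numbers on one entry
  mask <- attr(fs, "mask")
  draws <- vapply(1:400, function(s) unclass(poisson_sample_afs(fs, seed = 1e6 + s))[3, 2], 0)
  lambda <- v[3, 2]
  expect_lt(abs(mean(draws) - lambda), 3 * sqrt(lambda / 400))
})
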