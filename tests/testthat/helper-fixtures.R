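# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; sizes are kept small so the default suite stays fast.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small asymmetric split-with-migration model used across tests
tiny_demo <- function() {
  demographic_model("split_mig", nu1 = 2, nu2 = 3, T = 0.15, m12 = 0.5, m21 = 0.2)
}

# symmetric model for transpose/exchangeability properties
symmetric_demo <- function(T = 0.1) {
  demographic_model("split_mig", nu1 = 1, nu2 = 1, T = T, m12 = 1, m21 = 1)
}

tiny_cache <- function() {
  memo_fixture("tiny_cache", function() {
    build_cache(tiny_demo(), 6, 6, grid = build_gamma_grid(12, c(1e-4, 2000)), h = 0.5)
  })
}

# a deterministic small observed spectrum for I/O and likelihood tests
toy_observed <- function(n1 = 4, n2 = 4, seed = 42) {
  set.seed(seed)
  joint_spectrum(matrix(rpois((n1 + 1) * (n2 + 1), 5), n1 + 1, n2 + 1),
    kind = "observed"
  )
}

expect_spectra_close <- function(a, b, tol, ignore_mask = TRUE) {
  mask <- attr(a, "mask") | attr(b, "mask")
  ra <- unclass(a)[!mask]
  rb <- unclass(b)[!mask]
  expect_lt(max(abs(ra - rb) / pmax(abs(rb), 1e-300)), tol)
}
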