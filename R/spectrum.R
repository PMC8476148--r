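#' Two-population joint allele frequency spectrum
#'
#' A `joint_spectrum` is an `(n1+1) x (n2+1)` matrix whose entry `[i+1, j+1]`
#' holds the number (or expectation) of variants observed at derived-allele
#' count `i` in population 1 and `j` in population 2. The absorbing corners
#' `(0, 0)` and `(n1, n2)` carry no information about segregating variation
#' and are always masked; masked entries are excluded from all likelihood
#' sums and summaries.
#'
#' @param values numeric matrix of non-negative counts or expectations.
#' @param mask optional logical matrix of the same shape; `TRUE` marks an
#'   entry as excluded. The corners are masked regardless.
#' @param kind one of `"neutral"`, `"selected"`, `"expected"`, `"observed"`.
#' @return an object of class `joint_spectrum`.
#' @examples
#' fs <- joint_spectrum(matrix(1, 5, 5))
#' sample_sizes(fs)
#' @export
joint_spectrum <- function(values, mask = NULL,
                           kind = c("expected", "observed", "neutral", "selected")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("spectrum values must be numeric")
  n1 <- nrow(values) - 1L
  n2 <- ncol(values) - 1L
  if (n1 < 2L || n2 < 2L) {
    stop("a two-population spectrum requires haploid sample sizes >= 2 on both axes")
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(values))) stop("mask shape must match values")
    mask <- mask != 0
  }
  mask[1L, 1L] <- TRUE
  mask[n1 + 1L, n2 + 1L] <- TRUE
  if (any(!is.finite(values[!mask]))) stop("unmasked entries must be finite")
  if (any(values[!mask] < 0)) stop("unmasked entries must be non-negative")
  structure(values,
    mask = mask, kind = kind,
    class = c("joint_spectrum", "matrix", "array")
  )
}

#' @export
print.joint_spectrum <- function(x, ...) {
  ns <- sample_sizes(x)
  cat(sprintf(
    "joint_spectrum (%s): n1 = %d, n2 = %d, %d unmasked entries, total mass %.6g\n",
    attr(x, "kind"), ns[1], ns[2], sum(!attr(x, "mask")), spectrum_sum(x)
  ))
  invisible(x)
}

#' @rdname joint_spectrum
#' @param x a `joint_spectrum`.
#' @export
sample_sizes <- function(x) {
  stopifnot(inherits(x, "joint_spectrum"))
  c(n1 = nrow(x) - 1L, n2 = ncol(x) - 1L)
}

#' Sum of unmasked spectrum entries (number of segregating sites)
#'
#' @param x a `joint_spectrum`.
#' @return scalar sum over unmasked entries.
#' @export
spectrum_sum <- function(x) {
  stopifnot(inherits(x, "joint_spectrum"))
  sum(x[!attr(x, "mask")])
}

# Internal: rebuild a joint_spectrum from a plain matrix, keeping metadata.
respectrum <- function(values, template, kind = attr(template, "kind")) {
  joint_spectrum(values, mask = attr(template, "mask"), kind = kind)
}

#' Project a joint spectrum down to smaller sample sizes
#'
#' Each axis is downsampled independently with the exact hypergeometric
#' kernel: a variant at derived count `i` of `n` contributes
#' `choose(i, k) * choose(n - i, m - k) / choose(n, m)` to count `k` of the
#' projected size `m`. Projecting to the current size is the identity; no
#' missing-data imputation is performed.
#'
#' @param x a `joint_spectrum`.
#' @param n1,n2 target haploid sample sizes (each `<=` the current size).
#' @return the projected `joint_spectrum`.
#' @export
project <- function(x, n1, n2) {
  stopifnot(inherits(x, "joint_spectrum"))
  ns <- sample_sizes(x)
  if (n1 > ns[1] || n2 > ns[2]) stop("cannot project upward to a larger sample size")
  if (n1 < 2 || n2 < 2) stop("projected sample sizes must be >= 2")
  P1 <- projection_matrix(ns[[1]], n1)
  P2 <- projection_matrix(ns[[2]], n2)
  vals <- t(P1) %*% unclass(x) %*% P2
  # an entry of the projected spectrum is excluded only if all source mass
  # that could reach it is masked; with default corner-only masks this
  # reduces to the standard corner mask
  joint_spectrum(vals, kind = attr(x, "kind"))
}

# Hypergeometric projection matrix: (n+1) x (m+1), column k gives the
# distribution over source counts mapping to projected count k.
projection_matrix <- function(n, m) {
  outer(0:n, 0:m, function(i, k) {
    exp(lchoose(i, k) + lchoose(n - i, m - k) - lchoose(n, m))
  })
}

#' Apply ancestral-state misidentification to a spectrum
#'
#' With probability `p` the ancestral/derived assignment of a variant is
#' flipped, which moves mass from entry `(i, j)` to `(n1 - i, n2 - j)`:
#' `F'(i, j) = (1 - p) F(i, j) + p F(n1 - i, n2 - j)`. The unmasked total is
#' conserved because the corner mask is symmetric under reversal.
#'
#' @param x a `joint_spectrum`.
#' @param p misidentification probability in `[0, 1]`.
#' @return the transformed `joint_spectrum`.
#' @export
misid_transform <- function(x, p) {
  stopifnot(inherits(x, "joint_spectrum"))
  if (!is.finite(p) || p < 0 || p > 1) stop("misidentification probability must lie in [0, 1]")
  v <- unclass(x)
  flipped <- v[nrow(v):1, ncol(v):1, drop = FALSE]
  respectrum((1 - p) * v + p * flipped, x)
}

#' Poisson-sample an observed spectrum from an expected spectrum
#'
#' Draws independent Poisson counts for every unmasked entry, the generative
#' model of the Poisson Random Field: the observed spectrum used throughout
#' the simulation studies.
#'
#' @param expected a `joint_spectrum` of expectations.
#' @param seed optional integer seed for reproducibility.
#' @return an observed `joint_spectrum` of integer counts.
#' @export
poisson_sample_afs <- function(expected, seed = NULL) {
  stopifnot(inherits(expected, "joint_spectrum"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  mask <- attr(expected, "mask")
  v <- unclass(expected)
  draws <- v
  draws[!mask] <- stats::rpois(sum(!mask), v[!mask])
  draws[mask] <- 0
  joint_spectrum(draws, mask = mask, kind = "observed")
}
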