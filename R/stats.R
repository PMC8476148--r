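#' Significance of DFE correlations against perfect correlation
#'
#' Two-tailed z-tests of each estimated DFE correlation `w` against the
#' null `w = 1`, using Godambe standard deviations, with
#' Benjamini-Hochberg false-discovery-rate adjustment across exactly the
#' family of estimates supplied (pooling across data subsets is the
#' caller's responsibility).
#'
#' @param w_hat numeric vector of estimated correlations.
#' @param se matching vector of standard errors (all `> 0`).
#' @param labels optional names for the output rows.
#' @return a tibble with `w_hat`, `se`, `z`, `p_value`, `p_adjusted`.
#' @examples
#' w_significance(c(0.9, 0.99), c(0.05, 0.02))
#' @export
w_significance <- function(w_hat, se, labels = NULL) {
  stopifnot(length(w_hat) == length(se))
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be positive and finite")
  z <- (w_hat - 1) / se
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(
    label = if (is.null(labels)) as.character(seq_along(w_hat)) else labels,
    w_hat = w_hat, se = se, z = z, p_value = p,
    p_adjusted = stats::p.adjust(p, method = "BH")
  )
}

#' Partition a selected-class mutation rate across mutation classes
#'
#' Splits the selected (e.g. nonsynonymous) population-scaled mutation rate
#' between deleterious and tolerated classes using rate-weighted proportions
#' over the 12 nucleotide-change types:
#' `p_del = sum(u * d) / sum(u * (d + t))` and analogously for tolerated,
#' so the two proportions sum to one.
#'
#' @param theta_NS selected-class population-scaled mutation rate.
#' @param u per-type mutation rates (length 12, or any number of types).
#' @param d per-type counts of deleterious-class sites.
#' @param t per-type counts of tolerated-class sites.
#' @return named vector `c(theta_deleterious, theta_tolerated)`.
#' @examples
#' partition_theta(100, u = c(1, 2), d = c(10, 0), t = c(0, 10))
#' @export
partition_theta <- function(theta_NS, u, d, t) {
  stopifnot(length(u) == length(d), length(d) == length(t))
  if (any(u <= 0)) stop("mutation rates must be positive")
  if (any(d < 0) || any(t < 0) || sum(d + t) == 0) stop("class counts must be non-negative with at least one non-zero")
  denom <- sum(u * (d + t))
  p_del <- sum(u * d) / denom
  c(theta_deleterious = p_del * theta_NS, theta_tolerated = (1 - p_del) * theta_NS)
}
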