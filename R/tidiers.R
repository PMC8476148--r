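#' Tidy a fitted demographic or DFE model
#'
#' @param x a `jointdfe_fit`.
#' @param se optional named vector of standard errors (e.g. from
#'   [godambe_se()]) to attach; both the standard error and the 1.96-fold
#'   half-width of a 95% interval are reported, since conventions differ.
#' @param ... unused.
#' @return a tibble with one row per estimated parameter.
#' @importFrom generics tidy
#' @export
tidy.jointdfe_fit <- function(x, se = NULL, ...) {
  out <- tibble::tibble(
    term = names(x$params),
    estimate = unname(x$params)
  )
  if (!is.null(se)) {
    out$std.error <- unname(se[match(out$term, names(se))])
    out$ci95_half_width <- 1.96 * out$std.error
  }
  out
}

#' Glance at a fitted demographic or DFE model
#'
#' @param x a `jointdfe_fit`.
#' @param ... unused.
#' @return a one-row tibble of fit-level summaries.
#' @importFrom generics glance
#' @export
glance.jointdfe_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    logLik = x$loglik,
    converged = x$converged,
    n_starts = x$starts,
    seed = x$seed,
    boundary = paste(x$boundary %||% character(0), collapse = ",")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
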