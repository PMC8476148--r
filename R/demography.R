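#' Two-population demographic models
#'
#' Constructs a demographic model description in the diffusion units used
#' throughout the package: population sizes relative to the ancestral size
#' `Na`, divergence times in units of `2 Na` generations, and migration
#' rates as `2 Na m` (the expected number of migrant lineages per
#' generation, scaled).
#'
#' Supported models:
#' \describe{
#'   \item{`equilibrium`}{no split; both axes sample the same ancestral
#'     equilibrium population (mostly useful for testing).}
#'   \item{`split_mig`}{the ancestral population splits `T` time units ago
#'     into populations of constant relative sizes `nu1`, `nu2`, exchanging
#'     migrants at (possibly asymmetric) rates `m12` (into 1 from 2) and
#'     `m21`.}
#'   \item{`split_no_mig`}{`split_mig` with both migration rates zero.}
#'   \item{`IM`}{isolation-with-migration: a fraction `s_frac` of the
#'     ancestral population founds population 1 (the rest founds population
#'     2), then each grows (or shrinks) exponentially to its final size
#'     `nu1`, `nu2` over time `T`, with migration.}
#'   \item{`IM_pre`}{`IM` preceded by an instantaneous ancestral size change
#'     to `nu_pre` lasting `T_pre` before the split.}
#' }
#'
#' @param id model identifier, see Details.
#' @param nu1,nu2 final sizes of populations 1 and 2 relative to `Na`.
#' @param T divergence time in units of `2 Na` generations.
#' @param m12,m21 population-scaled migration rates (`2 Na m`).
#' @param s_frac fraction of the ancestral population founding population 1
#'   (IM-type models only), in (0, 1).
#' @param nu_pre,T_pre ancestral instantaneous-growth size and duration
#'   (`IM_pre` only).
#' @return an object of class `demographic_model`.
#' @examples
#' demographic_model("split_mig", nu1 = 1, nu2 = 1, T = 0.1, m12 = 1, m21 = 1)
#' @export
demographic_model <- function(id = c("equilibrium", "split_mig", "split_no_mig", "IM", "IM_pre"),
                              nu1 = 1, nu2 = 1, T = 0, m12 = 0, m21 = 0,
                              s_frac = 0.5, nu_pre = 1, T_pre = 0) {
  id <- match.arg(id)
  if (id == "split_no_mig") {
    m12 <- 0
    m21 <- 0
  }
  stopifnot(
    is.finite(nu1), nu1 > 0, is.finite(nu2), nu2 > 0,
    is.finite(T), T >= 0, is.finite(T_pre), T_pre >= 0,
    is.finite(m12), m12 >= 0, is.finite(m21), m21 >= 0,
    is.finite(nu_pre), nu_pre > 0,
    is.finite(s_frac), s_frac > 0, s_frac < 1
  )
  structure(
    list(
      id = id, nu1 = nu1, nu2 = nu2, T = T, m12 = m12, m21 = m21,
      s_frac = s_frac, nu_pre = nu_pre, T_pre = T_pre
    ),
    class = "demographic_model"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf(
    "demographic_model '%s': nu1 = %g, nu2 = %g, T = %g, m12 = %g, m21 = %g",
    x$id, x$nu1, x$nu2, x$T, x$m12, x$m21
  ))
  if (x$id %in% c("IM", "IM_pre")) cat(sprintf(", s_frac = %g", x$s_frac))
  if (x$id == "IM_pre") cat(sprintf(", nu_pre = %g, T_pre = %g", x$nu_pre, x$T_pre))
  cat("\n")
  invisible(x)
}

#' Per-population selection regime
#'
#' Population-scaled selection coefficients `gamma = 2 Na s`, with genotype
#' fitnesses 1, `1 + 2hs`, `1 + 2s` for dominance coefficient `h`. `gamma1`
#' acts in the ancestral population and in population 1 after the split;
#' `gamma2` acts in population 2 from the split onward. The package models
#' deleterious mutations, so gammas must be `<= 0` (zero is the neutral
#' boundary).
#'
#' @param gamma1,gamma2 population-scaled selection coefficients (`<= 0`).
#' @param h dominance coefficient in `[0, 1]`; 0.5 is additive.
#' @return an object of class `selection_regime`.
#' @export
selection_regime <- function(gamma1 = 0, gamma2 = gamma1, h = 0.5) {
  stopifnot(is.finite(gamma1), is.finite(gamma2), is.finite(h), h >= 0, h <= 1)
  if (gamma1 > 0 || gamma2 > 0) {
    stop("positive selection coefficients are not supported (deleterious-only model)")
  }
  structure(list(gamma1 = gamma1, gamma2 = gamma2, h = h),
    class = "selection_regime"
  )
}
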