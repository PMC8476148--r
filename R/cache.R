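#' Log-spaced grid of selection-coefficient magnitudes
#'
#' `n_points` magnitudes logarithmically spaced between the bounds
#' (inclusive), with a constant ratio between consecutive points. The grid
#' stores positive magnitudes; cached spectra are computed at
#' `gamma = -magnitude` (deleterious-only).
#'
#' @param n_points number of grid points (`>= 2`).
#' @param bounds length-2 vector `c(min_mag, max_mag)`, `0 < min < max`.
#' @return strictly increasing numeric vector of length `n_points`.
#' @examples
#' g <- build_gamma_grid(50, c(1e-4, 2000))
#' range(g)
#' @export
build_gamma_grid <- function(n_points, bounds = c(1e-4, 2000)) {
  stopifnot(n_points >= 2, length(bounds) == 2)
  if (!(bounds[1] > 0 && bounds[2] > bounds[1])) {
    stop("gamma grid bounds must satisfy 0 < min_mag < max_mag")
  }
  exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_points))
}

#' Build a cache of expected spectra over selection-coefficient pairs
#'
#' Runs the diffusion engine once per ordered pair of grid magnitudes
#' (`n_points^2` spectra at `theta = 1`) plus once for the neutral spectrum,
#' under a fixed demographic model, sample configuration and dominance.
#' The DFE integration step then only reweights these cached spectra, so
#' the expensive engine work is done once per demographic fit. For a
#' symmetric demographic model the transpose identity
#' `F(g1, g2) = t(F(g2, g1))` halves the number of engine runs; results are
#' identical to independent evaluation of every node.
#'
#' @param demo a [demographic_model()].
#' @param n1,n2 haploid sample sizes.
#' @param grid magnitudes from [build_gamma_grid()].
#' @param h dominance coefficient.
#' @param pts optional engine extrapolation grid sizes.
#' @param verbose print progress every `verbose` nodes (0 = silent).
#' @return an object of class `selection_cache`.
#' @export
build_cache <- function(demo, n1, n2, grid = build_gamma_grid(50), h = 0.5,
                        pts = NULL, verbose = 0) {
  stopifnot(inherits(demo, "demographic_model"))
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0)) {
    stop("gamma grid must be strictly increasing positive magnitudes")
  }
  if (is.null(pts)) pts <- default_pts(n1, n2)
  np <- length(grid)
  spectra <- array(NA_real_, c(np, np, n1 + 1L, n2 + 1L))
  symmetric <- n1 == n2 && demo$nu1 == demo$nu2 && demo$m12 == demo$m21 &&
    (!(demo$id %in% c("IM", "IM_pre")) || demo$s_frac == 0.5)
  mask <- NULL
  done <- 0L
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (symmetric && j < i) next
      sel <- selection_regime(-grid[i], -grid[j], h)
      fs <- tryCatch(
        expected_joint_afs(demo, sel, n1, n2, pts = pts),
        error = function(e) {
          stop(sprintf(
            "engine failure at cache node (gamma1 = %g, gamma2 = %g): %s",
            -grid[i], -grid[j], conditionMessage(e)
          ))
        }
      )
      if (is.null(mask)) mask <- attr(fs, "mask")
      spectra[i, j, , ] <- unclass(fs)
      if (symmetric && j > i) spectra[j, i, , ] <- t(unclass(fs))
      done <- done + 1L
      if (verbose > 0 && done %% verbose == 0) {
        message(sprintf("cache: %d engine runs done", done))
      }
    }
  }
  neutral <- expected_joint_afs(demo, selection_regime(0, 0, h), n1, n2, pts = pts)
  structure(
    list(
      grid = grid, spectra = spectra, neutral = neutral,
      demo = demo, n1 = n1, n2 = n2, h = h, pts = pts, mask = mask,
      version = as.character(utils::packageVersion("jointdfe")),
      created = format(Sys.time(), tz = "UTC")
    ),
    class = "selection_cache"
  )
}

#' @export
print.selection_cache <- function(x, ...) {
  cat(sprintf(
    "selection_cache: %d x %d grid over |gamma| in [%g, %g], n1 = %d, n2 = %d, h = %g, demo '%s'\n",
    length(x$grid), length(x$grid), min(x$grid), max(x$grid), x$n1, x$n2, x$h, x$demo$id
  ))
  invisible(x)
}

#' Extract one cached spectrum
#'
#' @param cache a `selection_cache`.
#' @param i,j grid indices (gamma1, gamma2).
#' @return the cached `joint_spectrum`.
#' @export
cache_spectrum <- function(cache, i, j) {
  stopifnot(inherits(cache, "selection_cache"))
  joint_spectrum(cache$spectra[i, j, , ], mask = cache$mask, kind = "expected")
}

#' Save / load a selection cache
#'
#' The cache is stored as a single self-describing RDS container carrying
#' the grid, demographic parameters, sample sizes, dominance, engine
#' settings and format version alongside the packed spectra; loading
#' reproduces every value bit-exactly. [check_cache()] refuses a cache
#' whose demographic parameters differ from the current fit.
#'
#' @param cache a `selection_cache`.
#' @param path file path.
#' @return `load_cache` returns the `selection_cache`.
#' @export
save_cache <- function(cache, path) {
  stopifnot(inherits(cache, "selection_cache"))
  saveRDS(cache, path)
  invisible(path)
}

#' @rdname save_cache
#' @export
load_cache <- function(path) {
  cache <- readRDS(path)
  if (!inherits(cache, "selection_cache")) stop("file does not contain a selection cache")
  cache
}

#' @rdname save_cache
#' @param demo the demographic model of the current fit.
#' @param n1,n2 sample sizes of the current fit.
#' @export
check_cache <- function(cache, demo, n1 = NULL, n2 = NULL) {
  stopifnot(inherits(cache, "selection_cache"))
  if (!isTRUE(all.equal(unclass(cache$demo), unclass(demo), tolerance = 1e-10))) {
    stop("cache was built under different demographic parameters than the current fit; rebuild it")
  }
  if (!is.null(n1) && (cache$n1 != n1 || cache$n2 != n2)) {
    stop("cache sample sizes do not match the data")
  }
  invisible(TRUE)
}
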