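# Frequency-spectrum text format (dadi dialect): an optional block of
# '#' comment lines, a header line "d1 d2 [folded|unfolded]" with d = n+1,
# the d1*d2 spectrum values flattened in row-major order (population 1 is
# the slow axis), and a final line of d1*d2 mask indicators (1 = masked).

#' Read a joint spectrum from a frequency-spectrum text file
#'
#' @param path file path.
#' @return a `joint_spectrum` (kind `"observed"`).
#' @export
read_afs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines_kept <- lines[keep]
  line_no <- which(keep)
  if (length(lines_kept) < 1) stop("empty spectrum file: ", path)
  header <- strsplit(trimws(lines_kept[1]), "\\s+")[[1]]
  if (length(header) < 2) {
    stop(sprintf("%s:%d: malformed header '%s'", path, line_no[1], lines_kept[1]))
  }
  d1 <- suppressWarnings(as.integer(header[1]))
  d2 <- suppressWarnings(as.integer(header[2]))
  if (is.na(d1) || is.na(d2) || d1 < 3 || d2 < 3) {
    stop(sprintf("%s:%d: invalid spectrum dimensions in header", path, line_no[1]))
  }
  folded <- length(header) >= 3 && header[3] == "folded"
  if (folded) stop("folded spectra are not supported (ancestral state is handled via the misidentification parameter)")
  tokens <- unlist(strsplit(trimws(lines_kept[-1]), "\\s+"))
  need <- d1 * d2
  if (length(tokens) < 2 * need) {
    stop(sprintf(
      "%s: expected %d values plus %d mask entries, found %d tokens",
      path, need, need, length(tokens)
    ))
  }
  vals <- as.numeric(tokens[seq_len(need)])
  if (any(is.na(vals))) stop(sprintf("%s: non-numeric spectrum values", path))
  maskv <- as.integer(tokens[need + seq_len(need)])
  if (any(is.na(maskv)) || any(!maskv %in% c(0L, 1L))) {
    stop(sprintf("%s: mask line must contain 0/1 indicators", path))
  }
  values <- matrix(vals, d1, d2, byrow = TRUE)
  mask <- matrix(maskv == 1L, d1, d2, byrow = TRUE)
  joint_spectrum(values, mask = mask, kind = "observed")
}

#' Write a joint spectrum to a frequency-spectrum text file
#'
#' Output is bit-exact reproducible: values are written with 17 significant
#' digits, so a write/read round-trip restores every double exactly. A
#' comment header records provenance.
#'
#' @param x a `joint_spectrum`.
#' @param path file path.
#' @param comment extra provenance comment lines (without the leading '#').
#' @return `path`, invisibly.
#' @export
write_afs <- function(x, path, comment = character(0)) {
  stopifnot(inherits(x, "joint_spectrum"))
  mask <- attr(x, "mask")
  if (all(mask)) warning("writing an all-masked spectrum")
  d <- dim(x)
  header <- sprintf("%d %d unfolded", d[1], d[2])
  vals <- paste(sprintf("%.17g", as.vector(t(unclass(x)))), collapse = " ")
  maskline <- paste(as.integer(as.vector(t(mask))), collapse = " ")
  provenance <- c(
    sprintf("# jointdfe %s joint allele frequency spectrum", as.character(utils::packageVersion("jointdfe"))),
    if (length(comment)) paste("#", comment)
  )
  writeLines(c(provenance, header, vals, maskline), path)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML (or JSON) configuration with a fixed schema: top-level keys
#' `paths`, `demography`, `dfe`, `engine`, `theta`, `seed`, `logging` (all
#' optional); unknown keys are rejected with their location to catch
#' typos early.
#'
#' @param path configuration file path.
#' @return named list with the resolved configuration and defaults filled.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("paths", "demography", "dfe", "engine", "theta", "seed", "logging")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop(sprintf(
      "%s: unknown configuration key(s): %s (allowed: %s)",
      path, paste(unknown, collapse = ", "), paste(allowed, collapse = ", ")
    ))
  }
  if (is.null(cfg$seed)) {
    warning("no seed in run configuration; defaulting to 0 for reproducibility")
    cfg$seed <- 0L
  }
  if (is.null(cfg$logging)) cfg$logging <- "info"
  cfg
}
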