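# Physical constants used throughout. Energies on the AFM side are in joules
# (SI), energies on the simulation side in kJ/mol; keep the two Boltzmann
# constants separate so no silent unit mixing can occur.

#' @keywords internal
.kB_J <- 1.380649e-23      # J/K

#' @keywords internal
.kB_kJmol <- 0.0083144621  # kJ/(mol K)

#' @keywords internal
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
.check_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (strict && x <= 0) .stopf("'%s' must be strictly positive (got %g)", name, x)
  if (!strict && x < 0) .stopf("'%s' must be non-negative (got %g)", name, x)
  invisible(x)
}
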