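# Containers for AFM indentation data.

#' A single force-distance approach curve
#'
#' Distances are the tip-sample coordinate in nm (decreasing towards and
#' through contact along the approach), forces in nN (positive in
#' compression). Instrument metadata travels with the curve.
#'
#' @param distance Numeric vector, nm.
#' @param force Numeric vector, nN; same length as `distance`.
#' @param spring_constant Cantilever spring constant K (N/m).
#' @param velocity Approach velocity (m/s).
#' @param tip_radius Tip radius (nm).
#' @param label Free-text condition label.
#' @return Object of class `force_curve`.
#' @export
force_curve <- function(distance, force, spring_constant = 0.060,
                        velocity = 1e-6, tip_radius = 20, label = "") {
  if (length(distance) != length(force))
    .stopf("distance and force must have equal length")
  .check_scalar_pos(spring_constant, "spring_constant")
  .check_scalar_pos(velocity, "velocity")
  structure(list(distance = as.numeric(distance),
                 force = as.numeric(force),
                 meta = list(spring_constant = spring_constant,
                             velocity = velocity,
                             tip_radius = tip_radius,
                             label = label)),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("force_curve: %d samples, distance %.4g..%.4g nm, K = %.3g N/m%s\n",
              length(x$force), max(x$distance), min(x$distance),
              x$meta$spring_constant,
              if (nzchar(x$meta$label)) paste0(" [", x$meta$label, "]") else ""))
  invisible(x)
}

#' A population of breakthrough (yield) forces
#'
#' @param forces Numeric vector of yield forces in nN (all > 0), or, for a
#'   normalized sample, unit-less normalized forces.
#' @param condition Label of the membrane/compound condition.
#' @param normalized Logical; whether forces were divided by a reference
#'   median.
#' @param reference_median The reference median (nN) used for normalization,
#'   or `NULL`.
#' @return Object of class `yield_force_sample`.
#' @export
yield_force_sample <- function(forces, condition = "", normalized = FALSE,
                               reference_median = NULL) {
  forces <- as.numeric(forces)
  if (any(!is.finite(forces)) || any(forces <= 0))
    .stopf("all yield forces must be finite and > 0")
  if (normalized && is.null(reference_median))
    .stopf("a normalized sample must record its reference median")
  structure(list(forces = forces, condition = condition,
                 normalized = normalized,
                 reference_median = reference_median),
            class = "yield_force_sample")
}

#' @export
print.yield_force_sample <- function(x, ...) {
  unit <- if (x$normalized) "(normalized)" else "nN"
  cat(sprintf("yield_force_sample: n = %d, median = %.3g %s%s\n",
              length(x$forces), stats::median(x$forces), unit,
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else ""))
  invisible(x)
}
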