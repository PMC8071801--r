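# Synthetic AFM approach curves with stochastic breakthrough events.
#
# The curve is built in approach order along a decreasing tip-sample
# coordinate d (nm): a zero-mean noisy baseline, a contact ramp whose slope
# is the series stiffness of cantilever and membrane film, a breakthrough
# plateau at a force drawn from the nucleation-model yield-force density
# (rendered over the apparent membrane thickness), and finally hard-wall
# substrate contact at the cantilever-limited slope.

#' Specification for synthetic force curves
#'
#' @param params A [nucleation_params()] object; supplies the cantilever
#'   stiffness, approach velocity and the yield-force distribution.
#' @param contact_stiffness Stiffness of the membrane-on-substrate elastic
#'   foundation (N/m); the observed contact slope is the series combination
#'   with the cantilever spring.
#' @param membrane_thickness_apparent Length of the breakthrough jump (nm).
#' @param noise_sd Force noise standard deviation (N).
#' @param sampling_step Distance between samples (nm). The default emulates
#'   kHz-range force sampling at a 1 um/s approach.
#' @param approach_range Total approach distance covered before substrate
#'   overshoot (nm); the membrane contact point sits at half the range.
#' @return Object of class `curve_synth_spec`.
#' @export
curve_synth_spec <- function(params,
                             contact_stiffness = 1.0,
                             membrane_thickness_apparent = 4.0,
                             noise_sd = 3e-11,
                             sampling_step = 0.05,
                             approach_range = 400) {
  stopifnot(inherits(params, "nucleation_params"))
  .check_scalar_pos(contact_stiffness, "contact_stiffness")
  .check_scalar_pos(membrane_thickness_apparent, "membrane_thickness_apparent")
  .check_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  .check_scalar_pos(sampling_step, "sampling_step")
  .check_scalar_pos(approach_range, "approach_range")
  structure(list(params = params,
                 contact_stiffness = contact_stiffness,
                 membrane_thickness_apparent = membrane_thickness_apparent,
                 noise_sd = noise_sd,
                 sampling_step = sampling_step,
                 approach_range = approach_range),
            class = "curve_synth_spec")
}

#' Generate one synthetic approach curve
#'
#' @param spec A [curve_synth_spec()].
#' @param seed Integer seed; output is a pure function of `(spec, seed,
#'   breakthrough_force)`.
#' @param breakthrough_force Optional fixed breakthrough force(s) in N. A
#'   vector produces stacked breakthrough events (e.g. a double bilayer).
#'   `NULL` (default) draws one force from the nucleation-model density.
#' @return A [force_curve()]; ground truth is attached as attribute
#'   `"truth"`: a list with `breakthrough_force_nN`, `contact_index`, and
#'   `plateau_ranges` (list of index ranges in approach order).
#' @export
generate_force_curve <- function(spec, seed, breakthrough_force = NULL) {
  stopifnot(inherits(spec, "curve_synth_spec"))
  p <- spec$params
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (is.null(breakthrough_force)) {
    # inverse-transform draw from the yield-force density, on this stream
    lam <- p$attempt_freq / (p$spring_constant * p$velocity)
    cbar <- .reduced_barrier_const(p)
    u <- .invert_survival_integral(-log(stats::runif(1)) / lam, cbar)
    fb_nN <- (threshold_force(p) + u) * 1e9
  } else {
    fb_nN <- breakthrough_force * 1e9
  }
  K <- p$spring_constant                     # N/m == nN/nm
  k_ser <- K * spec$contact_stiffness / (K + spec$contact_stiffness)
  step <- spec$sampling_step
  d_c <- spec$approach_range / 2             # contact point (nm)

  d <- seq(spec$approach_range, d_c + step, by = -step)
  f <- numeric(length(d))
  contact_index <- length(d) + 1L
  plateau_ranges <- list()
  d_cur <- d_c; f_cur <- 0
  for (j in seq_along(fb_nN)) {
    # ramp up to the j-th breakthrough force
    n_ramp <- max(1L, ceiling((fb_nN[j] - f_cur) / (k_ser * step)))
    d_ramp <- d_cur - step * (0:(n_ramp - 1))
    f_ramp <- f_cur + k_ser * (d_cur - d_ramp)
    # plateau across the apparent membrane thickness
    n_plat <- max(3L, round(spec$membrane_thickness_apparent / step))
    d_plat <- d_ramp[n_ramp] - step * (1:n_plat)
    f_plat <- rep(fb_nN[j], n_plat)
    i0 <- length(d) + n_ramp + 1L
    plateau_ranges[[j]] <- c(i0, i0 + n_plat - 1L)
    d <- c(d, d_ramp, d_plat)
    f <- c(f, f_ramp, f_plat)
    d_cur <- d_plat[n_plat]; f_cur <- fb_nN[j]
  }
  # hard-wall substrate: slope limited by the cantilever spring
  n_sub <- max(5L, ceiling(1.5 / (K * step)))
  d_sub <- d_cur - step * (1:n_sub)
  f_sub <- f_cur + K * (d_cur - d_sub)
  d <- c(d, d_sub); f <- c(f, f_sub)
  f <- f + stats::rnorm(length(f), 0, spec$noise_sd * 1e9)
  curve <- force_curve(d, f,
                       spring_constant = K, velocity = p$velocity,
                       tip_radius = p$tip_radius * 1e9,
                       label = "synthetic")
  attr(curve, "truth") <- list(breakthrough_force_nN = fb_nN,
                               contact_index = contact_index,
                               plateau_ranges = plateau_ranges)
  curve
}

#' Write and read synthetic force curves
#'
#' Curves are stored as two-column whitespace-delimited text (distance nm,
#' force nN) preceded by `# key=value` metadata lines. Ground-truth
#' breakthrough forces of a batch go to a sidecar TSV.
#'
#' @param curve A [force_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  hdr <- c(sprintf("# spring_constant=%.10g", curve$meta$spring_constant),
           sprintf("# velocity=%.10g", curve$meta$velocity),
           sprintf("# tip_radius=%.10g", curve$meta$tip_radius),
           sprintf("# label=%s", curve$meta$label),
           "# columns=distance_nm force_nN")
  writeLines(hdr, path)
  utils::write.table(data.frame(curve$distance, curve$force), path,
                     append = TRUE, col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a batch of curves plus a ground-truth sidecar
#'
#' @param curves List of [force_curve()] objects (typically from
#'   [generate_force_curve()]).
#' @param dir Output directory (created if needed).
#' @return Character vector of curve file paths, invisibly.
#' @export
write_force_curves <- function(curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(curves))
  truth <- data.frame(file = character(0), breakthrough_force_nN = numeric(0))
  for (i in seq_along(curves)) {
    fn <- sprintf("curve_%04d.txt", i)
    paths[i] <- file.path(dir, fn)
    write_force_curve(curves[[i]], paths[i])
    tr <- attr(curves[[i]], "truth")
    if (!is.null(tr))
      truth <- rbind(truth, data.frame(file = fn,
                                       breakthrough_force_nN = tr$breakthrough_force_nN[1]))
  }
  if (nrow(truth))
    utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}
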