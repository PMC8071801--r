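# Synthetic umbrella-sampling data along the pore chain coordinate.
#
# Samples in each window are drawn independently from the biased Boltzmann
# density exp(-beta (G(xi) + k/2 (xi - xi0)^2)) by inverse-CDF on a fine
# grid. This exercises the WHAM estimator exactly as time-series data would,
# without simulating correlated dynamics.

#' A generating free-energy profile along the chain coordinate
#'
#' @param grid Strictly increasing chain-coordinate values in `[0, 1]`.
#' @param values Free energy (kJ/mol) at each grid point; shifted so the
#'   minimum is 0.
#' @param temperature Temperature (K) the profile refers to.
#' @return Object of class `pmf_spec`.
#' @export
pmf_spec <- function(grid, values, temperature = 323) {
  grid <- as.numeric(grid); values <- as.numeric(values)
  if (length(grid) != length(values) || length(grid) < 2)
    .stopf("grid and values must be equal-length vectors (>= 2)")
  if (any(diff(grid) <= 0)) .stopf("grid must be strictly increasing")
  if (any(grid < 0 | grid > 1)) .stopf("grid must lie in [0, 1]")
  if (any(!is.finite(values))) .stopf("values must be finite")
  .check_scalar_pos(temperature, "temperature")
  structure(list(grid = grid, values = values - min(values),
                 temperature = temperature),
            class = "pmf_spec")
}

#' Sigmoidal pore-formation profile
#'
#' A smooth profile emulating the canonical shape of a pore-formation free
#' energy along the chain coordinate: a minimum near the flat-membrane state
#' (around 0.25), a rise through partial-defect states, and a plateau at
#' `dg_pore` for the open pore. A quadratic wall left of the minimum keeps
#' the very-low-coordinate states unfavourable.
#'
#' @param dg_pore Plateau height (kJ/mol), default 65.
#' @param center,width Location/steepness of the sigmoidal rise.
#' @param well Position of the flat-membrane minimum.
#' @param wall Curvature (kJ/mol per unit coordinate squared) of the wall
#'   left of the minimum.
#' @param grid Evaluation grid.
#' @param temperature Temperature (K).
#' @return A [pmf_spec()].
#' @export
pmf_sigmoid <- function(dg_pore = 65, center = 0.55, width = 0.07,
                        well = 0.25, wall = 200,
                        grid = seq(0, 1, by = 0.005), temperature = 323) {
  v <- dg_pore * stats::plogis((grid - center) / width) +
    wall * pmax(0, well - grid)^2
  pmf_spec(grid, v, temperature)
}

#' The 24-window umbrella layout
#'
#' Non-uniform window centers 0.065-0.625 in steps of 0.08 (force constant
#' 5000 kJ/mol) and 0.7-1.0 in steps of 0.02 (force constant 10000 kJ/mol).
#'
#' @return List with `centers` and `force_constants`.
#' @export
default_umbrella_layout <- function() {
  list(centers = c(seq(0.065, 0.625, by = 0.08), seq(0.70, 1.00, by = 0.02)),
       force_constants = c(rep(5000, 8), rep(10000, 16)))
}

#' Generate an umbrella-sampling dataset from a known profile
#'
#' For each window, draws `n_per_window` independent samples from the biased
#' Boltzmann density under the generating profile plus harmonic bias
#' `k/2 (xi - xi0)^2`. Windows whose sampled supports do not overlap their
#' neighbours trigger a warning naming the gap.
#'
#' @param pmf A [pmf_spec()] (the generating truth).
#' @param centers,force_constants Window centers (chain coordinate) and
#'   harmonic force constants (kJ/mol per unit coordinate squared); defaults
#'   to [default_umbrella_layout()].
#' @param n_per_window Samples per window.
#' @param seed Integer seed.
#' @return Object of class `umbrella_dataset`: `windows` (list of
#'   `center`, `force_constant`, `samples`), `temperature`.
#' @export
generate_umbrella_dataset <- function(pmf,
                                      centers = default_umbrella_layout()$centers,
                                      force_constants = default_umbrella_layout()$force_constants,
                                      n_per_window = 5000, seed = 1) {
  stopifnot(inherits(pmf, "pmf_spec"))
  if (length(centers) != length(force_constants))
    .stopf("centers and force_constants must have equal length")
  if (any(centers < min(pmf$grid) | centers > max(pmf$grid)))
    .stopf("pmf grid does not cover all window centers")
  if (any(force_constants <= 0)) .stopf("force constants must be > 0")
  beta <- 1 / (.kB_kJmol * pmf$temperature)
  xg <- seq(min(pmf$grid), max(pmf$grid), length.out = 4001)
  gg <- stats::spline(pmf$grid, pmf$values, xout = xg)$y
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  windows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    logw <- -beta * (gg + 0.5 * force_constants[i] * (xg - centers[i])^2)
    w <- exp(logw - max(logw))
    # trapezoidal CDF: a running point-mass sum would shift every sample by
    # half a grid step, which the steep biases amplify into a profile tilt
    cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2 * diff(xg)))
    cdf <- cdf / cdf[length(cdf)]
    # strictly increasing CDF for interpolation
    keep <- c(TRUE, diff(cdf) > 0)
    xi <- stats::approx(cdf[keep], xg[keep], xout = stats::runif(n_per_window),
                        rule = 2)$y
    windows[[i]] <- list(center = centers[i],
                         force_constant = force_constants[i],
                         samples = xi)
  }
  ds <- structure(list(windows = windows, temperature = pmf$temperature),
                  class = "umbrella_dataset")
  .check_window_overlap(ds)
  ds
}

#' @keywords internal
.check_window_overlap <- function(ds) {
  rng <- t(vapply(ds$windows, function(w)
    stats::quantile(w$samples, c(0.001, 0.999), names = FALSE), numeric(2)))
  ord <- order(vapply(ds$windows, `[[`, 0, "center"))
  rng <- rng[ord, , drop = FALSE]
  for (i in seq_len(nrow(rng) - 1L)) {
    if (rng[i, 2] < rng[i + 1L, 1])
      .warnf("umbrella windows %d and %d (centers %.3g, %.3g) have no sampled overlap: gap [%.3g, %.3g]",
             ord[i], ord[i + 1L],
             ds$windows[[ord[i]]]$center, ds$windows[[ord[i + 1L]]]$center,
             rng[i, 2], rng[i + 1L, 1])
  }
  invisible(ds)
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  ns <- vapply(x$windows, function(w) length(w$samples), 0L)
  cat(sprintf("umbrella_dataset: %d windows, %d..%d samples/window, T = %g K\n",
              length(x$windows), min(ns), max(ns), x$temperature))
  invisible(x)
}

#' Write / read an umbrella dataset
#'
#' Per-window two-column text files (time index, chain coordinate) plus a
#' metadata file listing `filename center force_constant` per line --
#' dialect-compatible with common umbrella-sampling post-processing tools.
#'
#' @param ds An `umbrella_dataset`.
#' @param dir Output directory.
#' @return Path of the metadata file, invisibly.
#' @export
write_umbrella_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "umbrella_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- character(length(ds$windows))
  for (i in seq_along(ds$windows)) {
    w <- ds$windows[[i]]
    fn <- sprintf("window_%02d.dat", i)
    utils::write.table(data.frame(seq_along(w$samples), w$samples),
                       file.path(dir, fn), col.names = FALSE,
                       row.names = FALSE, quote = FALSE)
    meta[i] <- sprintf("%s %.10g %.10g", fn, w$center, w$force_constant)
  }
  mpath <- file.path(dir, "windows.dat")
  writeLines(c(sprintf("# temperature=%.10g", ds$temperature),
               "# columns: file center force_constant", meta), mpath)
  invisible(mpath)
}

#' @rdname write_umbrella_dataset
#' @param meta_path Path to the `windows.dat` metadata file.
#' @param temperature Temperature (K); taken from the metadata header when
#'   present.
#' @param equilibration_fraction Fraction of each series discarded from the
#'   start (default 0, matching already-equilibrated synthetic draws; use
#'   0.5 for raw time series where the first half equilibrates).
#' @export
read_umbrella_dataset <- function(meta_path, temperature = NULL,
                                  equilibration_fraction = 0) {
  lines <- readLines(meta_path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  tline <- grep("temperature=", hdr, value = TRUE)
  if (is.null(temperature)) {
    if (!length(tline)) .stopf("temperature not in metadata; pass it explicitly")
    temperature <- as.numeric(sub(".*temperature=", "", tline[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  windows <- lapply(body, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) != 3L) .stopf("malformed metadata line: '%s'", ln)
    d <- utils::read.table(file.path(dirname(meta_path), tok[1]))
    xi <- d[[2]]
    drop <- floor(equilibration_fraction * length(xi))
    xi <- xi[seq.int(drop + 1L, length(xi))]
    if (!length(xi)) .stopf("window '%s' empty after equilibration discard", tok[1])
    list(center = as.numeric(tok[2]), force_constant = as.numeric(tok[3]),
         samples = xi)
  })
  structure(list(windows = windows, temperature = temperature),
            class = "umbrella_dataset")
}
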