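# Analysis of AFM approach curves: baseline correction, contact-point
# detection, breakthrough detection on a smoothed first derivative, and
# summary statistics of yield-force populations.

#' Read force curves from text files
#'
#' Supported dialects: `"breakthrough"` (the package's two-column
#' whitespace-delimited format with `# key=value` metadata header) and
#' `"csv"` (comma-separated with named columns `distance` and `force`,
#' optional metadata columns ignored). Malformed numeric rows abort with the
#' offending line number.
#'
#' @param paths Character vector of files, or a single directory (all
#'   `*.txt`/`*.csv` inside are read; a `ground_truth.tsv` sidecar is
#'   skipped).
#' @param format `"breakthrough"` or `"csv"`.
#' @return List of [force_curve()] objects (possibly empty, with a warning
#'   for header-only files).
#' @export
read_force_curves <- function(paths, format = c("breakthrough", "csv")) {
  format <- match.arg(format)
  if (length(paths) == 1L && dir.exists(paths)) {
    ext <- if (format == "csv") "\\.csv$" else "\\.txt$"
    paths <- list.files(paths, pattern = ext, full.names = TRUE)
    paths <- paths[basename(paths) != "ground_truth.tsv"]
  }
  out <- list()
  for (pth in paths) {
    if (!file.exists(pth)) .stopf("file not found: %s", pth)
    cv <- if (format == "breakthrough") .read_curve_breakthrough(pth)
          else .read_curve_csv(pth)
    if (is.null(cv)) next
    out[[length(out) + 1L]] <- cv
  }
  out
}

#' @keywords internal
.read_curve_breakthrough <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- strsplit(hdr, "=", fixed = TRUE)
  meta <- stats::setNames(lapply(kv, function(z) paste(z[-1], collapse = "=")),
                          vapply(kv, `[[`, "", 1L))
  for (key in c("spring_constant", "velocity")) {
    if (is.null(meta[[key]]))
      .stopf("%s: missing metadata key '%s'", basename(path), key)
  }
  body <- which(!is_hdr & nzchar(trimws(lines)))
  if (!length(body)) {
    .warnf("%s: no data rows, skipping", basename(path))
    return(NULL)
  }
  toks <- strsplit(trimws(lines[body]), "\\s+")
  bad_len <- which(lengths(toks) != 2L)
  if (length(bad_len))
    .stopf("%s: malformed row at line %d", basename(path), body[bad_len[1]])
  num <- suppressWarnings(vapply(toks, function(z) as.numeric(z), numeric(2)))
  bad <- which(apply(is.na(num), 2, any))
  if (length(bad))
    .stopf("%s: non-numeric value at line %d", basename(path), body[bad[1]])
  force_curve(num[1, ], num[2, ],
              spring_constant = as.numeric(meta$spring_constant),
              velocity = as.numeric(meta$velocity),
              tip_radius = if (!is.null(meta$tip_radius))
                as.numeric(meta$tip_radius) else NA_real_,
              label = if (!is.null(meta$label)) meta$label else "")
}

#' @keywords internal
.read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("distance", "force"))
    if (is.null(df[[col]])) .stopf("%s: missing column '%s'", basename(path), col)
  if (!nrow(df)) {
    .warnf("%s: no data rows, skipping", basename(path))
    return(NULL)
  }
  bad <- which(!is.finite(df$distance) | !is.finite(df$force))
  if (length(bad))
    .stopf("%s: non-numeric value at data row %d", basename(path), bad[1])
  force_curve(df$distance, df$force,
              spring_constant = if (!is.null(df$spring_constant))
                df$spring_constant[1] else 0.060,
              velocity = if (!is.null(df$velocity)) df$velocity[1] else 1e-6)
}

# Baseline region: the pre-contact portion of the approach, by default the
# first `fraction` of samples in approach order (largest distances).
#' @keywords internal
.baseline_idx <- function(curve, fraction = 0.3) {
  n <- length(curve$force)
  nb <- max(20L, floor(fraction * n))
  if (nb > n) .stopf("curve too short for baseline estimation (%d samples)", n)
  seq_len(nb)
}

#' Baseline-correct a force curve
#'
#' Fits a straight line to the pre-contact region (by default the first 30%
#' of samples in approach order, at least 20 samples) and subtracts it from
#' the whole curve, removing both constant offset and linear tilt. Errors if
#' the detected contact point falls inside the baseline region.
#'
#' @param curve A [force_curve()].
#' @param fraction Fraction of samples (approach order) used as baseline.
#' @return The corrected [force_curve()] (ground-truth attribute preserved).
#' @export
baseline_correct <- function(curve, fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  idx <- .baseline_idx(curve, fraction)
  ft <- stats::lm.fit(cbind(1, curve$distance[idx]), curve$force[idx])
  corrected <- curve
  corrected$force <- curve$force -
    (ft$coefficients[1] + ft$coefficients[2] * curve$distance)
  cp <- suppressWarnings(detect_contact_point(corrected))
  if (!is.na(cp) && cp <= max(idx))
    .stopf("baseline region (first %d samples) overlaps detected contact at index %d",
           max(idx), cp)
  attr(corrected, "truth") <- attr(curve, "truth")
  corrected
}

#' Detect the contact point of a baseline-corrected curve
#'
#' The contact point is the first sample (in approach order) from which the
#' cantilever deflection persistently increases: the first index of
#' `persist` consecutive samples above `z` times the baseline noise SD.
#'
#' @param curve Baseline-corrected [force_curve()].
#' @param noise_sd Baseline force noise SD (nN); estimated robustly (MAD)
#'   from the baseline region when `NULL`.
#' @param z Threshold in noise SDs (default 3).
#' @param persist Number of consecutive super-threshold samples required.
#' @return Integer index into the curve, or `NA` (with a warning) when no
#'   contact is found; such curves are excluded from statistics.
#' @export
detect_contact_point <- function(curve, noise_sd = NULL, z = 3, persist = 5L) {
  stopifnot(inherits(curve, "force_curve"))
  idx <- .baseline_idx(curve)
  if (is.null(noise_sd)) noise_sd <- stats::mad(curve$force[idx])
  thr <- max(z * noise_sd, 1e-6)  # floor keeps noiseless curves well-defined
  above <- curve$force > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= persist)
  if (!length(hit)) {
    .warnf("no contact point found")
    return(NA_integer_)
  }
  as.integer(ends[hit[1]] - r$lengths[hit[1]] + 1L)
}

#' @keywords internal
.sg_derivative <- function(force, step, window, order = 2L) {
  n <- length(force)
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (window < order + 2L) .stopf("curve too short for derivative smoothing")
  signal::sgolayfilt(force, p = order, n = window, m = 1L) / step
}

#' Detect breakthrough events
#'
#' Breakthrough events are the force plateaus between the two kinks of a
#' punch-through: maximal runs of samples, after the contact point and above
#' the contact noise level, whose smoothed first derivative of force with
#' respect to indentation drops below a threshold (force no longer climbing
#' while indentation advances). The derivative is computed on a
#' Savitzky-Golay smoothed curve; run starts use a lower threshold than run
#' continuation (hysteresis) to suppress spurious events on the noisy ramp.
#' The yield force of an event is the mean raw force over its samples.
#'
#' @param curve Baseline-corrected [force_curve()].
#' @param derivative_threshold Slope threshold (nN/nm) below which a sample
#'   counts as plateau. Default `NULL` chooses half the estimated contact
#'   ramp slope, with entry into an event requiring a quarter of the ramp
#'   slope.
#' @param min_points Minimum run length for an event (default 3).
#' @param window Savitzky-Golay window (odd number of samples); default
#'   `NULL` spans about 2.5 nm of indentation, clamped to `[7, 101]`.
#' @param order Savitzky-Golay polynomial order (default 2).
#' @param noise_sd Baseline noise SD (nN); MAD-estimated when `NULL`.
#' @return List of `breakthrough_event` objects, each with `index_range`,
#'   `yield_force` (nN) and `jump_distance` (nm), in approach order. Empty
#'   list when nothing is detected.
#' @export
detect_breakthrough <- function(curve, derivative_threshold = NULL,
                                min_points = 3L, window = NULL, order = 2L,
                                noise_sd = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  cp <- detect_contact_point(curve, noise_sd = noise_sd)
  if (is.na(cp)) .stopf("no contact point: cannot search for breakthroughs")
  step <- stats::median(abs(diff(curve$distance)))
  if (is.null(window)) {
    window <- round(2.5 / step)
    window <- max(7L, min(101L, window))
    if (window %% 2L == 0L) window <- window + 1L
  }
  if (is.null(noise_sd)) noise_sd <- stats::mad(curve$force[.baseline_idx(curve)])
  # slope w.r.t. indentation (indentation increases as distance decreases)
  slope <- .sg_derivative(curve$force, step, window, order)
  n <- length(slope)
  contact <- seq.int(cp, n)
  k_ramp <- stats::median(slope[contact][slope[contact] > 0], na.rm = TRUE)
  if (!is.finite(k_ramp) || k_ramp <= 0)
    return(list())
  thr_stay <- if (is.null(derivative_threshold)) 0.5 * k_ramp
              else derivative_threshold
  thr_enter <- if (is.null(derivative_threshold)) 0.25 * k_ramp else thr_stay
  in_contact <- logical(n)
  in_contact[contact] <- curve$force[contact] > max(5 * noise_sd, 1e-6)
  low <- abs(slope) < thr_stay & in_contact
  seed_pt <- abs(slope) < thr_enter & in_contact
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  events <- list()
  for (j in which(r$values & r$lengths >= min_points)) {
    i0 <- starts[j]; i1 <- ends[j]
    if (!any(seed_pt[i0:i1])) next  # hysteresis: require a confident core
    # a genuine plateau is flat on average; noise dips on the ramp retain a
    # substantial fraction of the ramp slope
    if (mean(slope[i0:i1]) >= thr_enter) next
    ev <- structure(list(index_range = c(i0, i1),
                         yield_force = mean(curve$force[i0:i1]),
                         jump_distance = curve$distance[i0] - curve$distance[i1]),
                    class = "breakthrough_event")
    events[[length(events) + 1L]] <- ev
  }
  events
}

#' Extract yield forces from a batch of curves
#'
#' Applies baseline correction, contact detection and breakthrough detection
#' to each curve; when a curve shows several events, the first (in approach
#' order) enters the statistics. Curves without contact or without events are
#' dropped.
#'
#' @param curves List of [force_curve()] objects.
#' @param condition Label for the resulting sample.
#' @param ... Passed to [detect_breakthrough()].
#' @return A [yield_force_sample()]; attribute `"n_curves"` records how many
#'   curves were analysed and kept.
#' @export
extract_yield_forces <- function(curves, condition = "", ...) {
  forces <- numeric(0)
  kept <- 0L
  for (cv in curves) {
    ev <- tryCatch({
      bc <- baseline_correct(cv)
      detect_breakthrough(bc, ...)
    }, error = function(e) list())
    if (length(ev)) {
      forces <- c(forces, ev[[1]]$yield_force)
      kept <- kept + 1L
    }
  }
  if (!length(forces)) .stopf("no breakthrough events found in %d curves",
                              length(curves))
  out <- yield_force_sample(forces, condition = condition)
  attr(out, "n_curves") <- c(analysed = length(curves), kept = kept)
  out
}

#' Normalize yield forces by a reference median
#'
#' Divides every force by the median of a reference sample (typically the
#' same membrane without added compound), so that samples taken with
#' different cantilevers become comparable.
#'
#' @param sample,reference [yield_force_sample()] objects (nN).
#' @return A normalized [yield_force_sample()] with `reference_median`
#'   recorded.
#' @export
normalize_yield_forces <- function(sample, reference) {
  stopifnot(inherits(sample, "yield_force_sample"),
            inherits(reference, "yield_force_sample"))
  m <- stats::median(reference$forces)
  if (!is.finite(m) || m <= 0)
    .stopf("reference median must be positive (got %g)", m)
  yield_force_sample(sample$forces / m, condition = sample$condition,
                     normalized = TRUE, reference_median = m)
}

#' Empirical cumulative distribution of a yield-force sample
#'
#' @param sample A [yield_force_sample()] or numeric vector.
#' @return A data frame with columns `force` (sorted unique values) and
#'   `cumprob` (right-continuous ECDF); the sample median is attached as
#'   attribute `"median"`.
#' @export
ecdf_table <- function(sample) {
  x <- if (inherits(sample, "yield_force_sample")) sample$forces else sample
  if (!length(x)) .stopf("empty sample")
  fn <- stats::ecdf(x)
  xs <- sort(unique(x))
  out <- data.frame(force = xs, cumprob = fn(xs))
  attr(out, "median") <- stats::median(x)
  out
}

#' Box-plot summary of a yield-force sample
#'
#' Quartiles, median, whisker limits at 1.5 IQR beyond the box (about 2.7
#' standard deviations from the mean for normal data), and the outliers
#' beyond the whiskers.
#'
#' @param sample A [yield_force_sample()] or numeric vector with at least 5
#'   values.
#' @return List with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`, `n`.
#' @export
boxplot_stats <- function(sample) {
  x <- if (inherits(sample, "yield_force_sample")) sample$forces else sample
  if (length(x) < 5) .stopf("need at least 5 values (got %d)", length(x))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = lo, whisker_hi = hi,
       outliers = x[x < lo | x > hi], n = length(x))
}
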