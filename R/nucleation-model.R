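# Continuum nucleation model of membrane rupture under an AFM tip.
#
# A loaded tip of radius R presses on a supported bilayer. Thermal
# fluctuations open a circular hole of radius r_h whose energy is
#
#   U(r_h) = 2 pi r_h Gamma + pi r_h^2 (S - F / (2 pi R)),
#
# with Gamma the line tension of the hole rim and S the spreading pressure
# (the interfacial free-energy change per unit area on removing the membrane
# patch between tip and substrate). Once the applied force F exceeds the
# spreading force 2 pi R S, U passes through a maximum at the critical radius
# r_c = 2 pi R Gamma / (F - 2 pi R S), giving the activation barrier
#
#   dU(F) = 2 pi^2 Gamma^2 R / (F - 2 pi R S).
#
# Under a constant loading rate dF/dt = K v (cantilever stiffness times
# approach velocity) with attempt frequency A, rupture is a first-passage
# process with hazard h(F) = (A / (K v)) exp(-dU(F) / kT), survival
# s(F) = exp(-int h dF') and yield-force density P(F) = h(F) s(F).

#' Physical parameter set of the continuum nucleation model
#'
#' Bundles the membrane parameters (line tension, spreading pressure) with
#' the instrument parameters (tip radius, cantilever spring constant,
#' approach velocity, attempt frequency) and the temperature. All values are
#' SI.
#'
#' @param line_tension Line tension Gamma of the hole rim (N). Typical
#'   supported-bilayer values are a few times 1e-12 N.
#' @param spreading_pressure Spreading pressure S (N/m); sets the threshold
#'   (spreading) force `2*pi*R*S` below which no hole is stable.
#' @param tip_radius Cantilever tip radius R (m), typically 20e-9.
#' @param spring_constant Cantilever spring constant K (N/m).
#' @param velocity Approach velocity v (m/s).
#' @param attempt_freq Attempt frequency A (1/s) for hole nucleation, bounded
#'   above by the cantilever resonance frequency.
#' @param temperature Absolute temperature (K).
#'
#' @return An object of class `nucleation_params`.
#' @examples
#' p <- nucleation_params(line_tension = 6.93e-12, spreading_pressure = 9.49e-3)
#' threshold_force(p)
#' @export
nucleation_params <- function(line_tension,
                              spreading_pressure,
                              tip_radius = 20e-9,
                              spring_constant = 0.060,
                              velocity = 1e-6,
                              attempt_freq = 3000,
                              temperature = 298) {
  fields <- list(line_tension = line_tension,
                 spreading_pressure = spreading_pressure,
                 tip_radius = tip_radius,
                 spring_constant = spring_constant,
                 velocity = velocity,
                 attempt_freq = attempt_freq,
                 temperature = temperature)
  for (nm in names(fields)) .check_scalar_pos(fields[[nm]], nm)
  structure(fields, class = "nucleation_params")
}

#' @export
print.nucleation_params <- function(x, ...) {
  cat("Continuum nucleation model parameters\n")
  cat(sprintf("  line tension       Gamma = %.4g N (%.3g x10^-3 nN)\n",
              x$line_tension, x$line_tension * 1e12))
  cat(sprintf("  spreading pressure S     = %.4g N/m (%.3g x10^-3 N/m)\n",
              x$spreading_pressure, x$spreading_pressure * 1e3))
  cat(sprintf("  tip radius R = %.3g nm, spring K = %.3g N/m, velocity = %.3g m/s\n",
              x$tip_radius * 1e9, x$spring_constant, x$velocity))
  cat(sprintf("  attempt freq A = %.3g Hz, T = %.4g K\n",
              x$attempt_freq, x$temperature))
  cat(sprintf("  threshold force 2*pi*R*S = %.4g nN\n", threshold_force(x) * 1e9))
  invisible(x)
}

#' Spreading (threshold) force `2*pi*R*S`
#'
#' The minimum force below which a hole under the tip cannot grow.
#'
#' @param params A [nucleation_params()] object.
#' @return Force in N.
#' @export
threshold_force <- function(params) {
  stopifnot(inherits(params, "nucleation_params"))
  2 * pi * params$tip_radius * params$spreading_pressure
}

#' Energy of a circular hole under the loaded tip
#'
#' `U(r_h) = 2 pi r_h Gamma + pi r_h^2 (S - F/(2 pi R))`.
#'
#' @param r_h Hole radius (m); vectorised.
#' @param force Applied force F (N).
#' @param params A [nucleation_params()] object.
#' @return Energy in J.
#' @export
hole_energy <- function(r_h, force, params) {
  stopifnot(inherits(params, "nucleation_params"))
  if (any(r_h < 0)) .stopf("'r_h' must be non-negative")
  2 * pi * r_h * params$line_tension +
    pi * r_h^2 * (params$spreading_pressure - force / (2 * pi * params$tip_radius))
}

#' Critical hole radius
#'
#' Radius at which the hole energy is maximal,
#' `r_c = 2 pi R Gamma / (F - 2 pi R S)`; defined only above the spreading
#' force.
#'
#' @param force Applied force F (N); vectorised.
#' @inheritParams hole_energy
#' @return Radius in m.
#' @export
critical_radius <- function(force, params) {
  stopifnot(inherits(params, "nucleation_params"))
  fs <- threshold_force(params)
  if (any(force <= fs))
    .stopf("force (%g N) is at or below spreading force 2*pi*R*S = %g N",
           min(force), fs)
  2 * pi * params$tip_radius * params$line_tension / (force - fs)
}

#' Activation barrier for hole nucleation
#'
#' `dU(F) = 2 pi^2 Gamma^2 R / (F - 2 pi R S)`, the hole energy evaluated at
#' the critical radius. Strictly decreasing in F.
#'
#' @inheritParams critical_radius
#' @return Energy in J.
#' @export
nucleation_barrier <- function(force, params) {
  stopifnot(inherits(params, "nucleation_params"))
  fs <- threshold_force(params)
  if (any(force <= fs))
    .stopf("force (%g N) is at or below spreading force 2*pi*R*S = %g N",
           min(force), fs)
  2 * pi^2 * params$line_tension^2 * params$tip_radius / (force - fs)
}

# Inner integral of the survival exponent in closed form:
#   I(u) = int_0^u exp(-c/u') du' = u exp(-c/u) - c E1(c/u),
# with u = F - 2 pi R S and c = 2 pi^2 Gamma^2 R / kT. E1 is the exponential
# integral; for c/u beyond ~700 both terms underflow to 0, which is the
# correct limit.
#' @keywords internal
.survival_integral <- function(u, cbar) {
  out <- numeric(length(u))
  pos <- u > 0
  x <- cbar / u[pos]
  e1 <- ifelse(x > 700, 0, pracma::expint(x))
  out[pos] <- u[pos] * exp(-pmin(x, 700)) - cbar * e1
  pmax(out, 0)
}

#' @keywords internal
.reduced_barrier_const <- function(params) {
  2 * pi^2 * params$line_tension^2 * params$tip_radius /
    (.kB_J * params$temperature)
}

#' Survival probability under dynamic loading
#'
#' Probability that the membrane is still intact when the ramped force
#' reaches F: `s(F) = exp(-(A/(K v)) int_{2 pi R S}^{F} exp(-dU/kT) dF')`.
#' Returns 1 for forces at or below the spreading force. The integral is
#' evaluated in closed form via the exponential integral.
#'
#' @inheritParams critical_radius
#' @return Probability in (0, 1]; vectorised over `force`.
#' @export
yield_survival <- function(force, params) {
  stopifnot(inherits(params, "nucleation_params"))
  fs <- threshold_force(params)
  lam <- params$attempt_freq / (params$spring_constant * params$velocity)
  cbar <- .reduced_barrier_const(params)
  u <- pmax(force - fs, 0)
  exp(-lam * .survival_integral(u, cbar))
}

#' Probability density of the yield force
#'
#' Density of the force at which breakthrough occurs under a constant loading
#' rate `K v`: `P(F) = (A/(K v)) exp(-dU(F)/kT) s(F)` for F above the
#' spreading force, 0 otherwise. Integrates to 1 on (2 pi R S, Inf).
#'
#' @inheritParams critical_radius
#' @return Density per N; vectorised over `force`.
#' @export
yield_force_pdf <- function(force, params) {
  stopifnot(inherits(params, "nucleation_params"))
  fs <- threshold_force(params)
  lam <- params$attempt_freq / (params$spring_constant * params$velocity)
  cbar <- .reduced_barrier_const(params)
  u <- force - fs
  out <- numeric(length(force))
  pos <- u > 0
  x <- pmin(cbar / u[pos], 700)
  out[pos] <- lam * exp(-x) * exp(-lam * .survival_integral(u[pos], cbar))
  out
}

# Inverse of the survival exponent: solve I(u) = y for u > 0. Uses a
# log-log interpolated first guess from a doubling bracket, then Newton
# steps (I'(u) = exp(-c/u)). Vectorised over y.
#' @keywords internal
.invert_survival_integral <- function(y, cbar) {
  stopifnot(all(y >= 0))
  out <- numeric(length(y))
  pos <- y > 0
  if (!any(pos)) return(out)
  yp <- y[pos]
  # bracket: below u0 the integral underflows; expand upward by doubling
  u_lo <- cbar / 690
  u_hi <- max(u_lo * 2, cbar)
  while (.survival_integral(u_hi, cbar) < max(yp)) u_hi <- u_hi * 2
  grid_u <- exp(seq(log(u_lo), log(u_hi), length.out = 600))
  grid_I <- .survival_integral(grid_u, cbar)
  keep <- grid_I > 0
  grid_u <- grid_u[keep]; grid_I <- grid_I[keep]
  yp_cl <- pmin(pmax(yp, min(grid_I)), max(grid_I))
  u <- exp(stats::approx(log(grid_I), log(grid_u), xout = log(yp_cl))$y)
  for (i in 1:6) {  # Newton refinement; I is smooth and convex in u
    f <- .survival_integral(u, cbar) - yp
    u <- pmax(u - f / exp(-pmin(cbar / u, 700)), u_lo / 2)
  }
  out[pos] <- u
  out
}

#' Sample yield forces from the nucleation-model density
#'
#' Draws breakthrough forces by inverse-transform sampling of the
#' first-passage density. Every draw is strictly above the spreading force
#' `2*pi*R*S`.
#'
#' @param params A [nucleation_params()] object.
#' @param n Number of forces to draw (>= 1).
#' @param seed Integer seed; the sampler is a pure function of
#'   `(params, n, seed)`.
#' @return A [yield_force_sample()] with forces in nN.
#' @examples
#' p <- nucleation_params(6.93e-12, 9.49e-3)
#' s <- sample_yield_forces(p, 1000, seed = 1)
#' median(s$forces)  # nN
#' @export
sample_yield_forces <- function(params, n, seed) {
  stopifnot(inherits(params, "nucleation_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    .stopf("'n' must be a positive count")
  n <- as.integer(n)
  fs <- threshold_force(params)
  lam <- params$attempt_freq / (params$spring_constant * params$velocity)
  cbar <- .reduced_barrier_const(params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  uu <- stats::runif(n)
  yy <- -log(uu) / lam             # target values of the survival integral
  u <- .invert_survival_integral(yy, cbar)
  yield_force_sample((fs + u) * 1e9, condition = "synthetic")
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Fitting

#' @keywords internal
.nucleation_nll <- function(logpar, forces_N, params) {
  p <- params
  p$line_tension <- exp(logpar[1])
  p$spreading_pressure <- exp(logpar[2])
  fs <- threshold_force(p)
  # barrier penalty instead of a hard failure when the threshold crosses data
  if (fs >= min(forces_N))
    return(1e8 * (1 + (fs - min(forces_N)) / min(forces_N)))
  d <- yield_force_pdf(forces_N, p)
  if (any(d <= 0) || any(!is.finite(d))) return(1e8)
  -sum(log(d))
}

#' @keywords internal
.nucleation_hist_obj <- function(logpar, mids_N, dens_perN, params) {
  p <- params
  p$line_tension <- exp(logpar[1])
  p$spreading_pressure <- exp(logpar[2])
  if (threshold_force(p) >= max(mids_N)) return(1e40)
  sum((yield_force_pdf(mids_N, p) - dens_perN)^2)
}

#' @keywords internal
.nucleation_init <- function(forces_N, params) {
  s0 <- 0.8 * min(forces_N) / (2 * pi * params$tip_radius)
  fs0 <- 2 * pi * params$tip_radius * s0
  umed <- stats::median(forces_N) - fs0
  lam <- params$attempt_freq / (params$spring_constant * params$velocity)
  target <- log(2) / lam
  # choose Gamma so that the model median matches the sample median
  g <- function(logc) .survival_integral(umed, exp(logc)) - target
  lo <- log(umed) - 25; hi <- log(umed * 650)
  logc <- tryCatch(stats::uniroot(g, c(lo, hi))$root, error = function(e) log(umed))
  cbar <- exp(logc)
  gamma0 <- sqrt(cbar * .kB_J * params$temperature /
                   (2 * pi^2 * params$tip_radius))
  c(log(gamma0), log(s0))
}

#' Fit the continuum nucleation model to a yield-force sample
#'
#' Estimates the line tension Gamma and spreading pressure S from a
#' population of breakthrough forces, holding the instrument parameters
#' (R, K, v, A) and the temperature fixed. The default is maximum likelihood
#' on the raw forces; `method = "histogram"` performs a least-squares fit of
#' the model density to a normalized histogram (Freedman-Diaconis bin width),
#' mirroring the common practice of fitting binned yield-force data.
#'
#' @param sample A [yield_force_sample()] (forces in nN) or numeric vector of
#'   forces in nN.
#' @param params A [nucleation_params()] carrying the fixed instrument
#'   parameters; its `line_tension`/`spreading_pressure` entries are ignored
#'   unless used as starting values.
#' @param init Optional starting values `c(line_tension, spreading_pressure)`
#'   in SI; by default a moment-style initialisation from the sample minimum
#'   and median.
#' @param method `"mle"` (default) or `"histogram"`.
#' @return An object of class `nucleation_fit` with elements `line_tension`,
#'   `spreading_pressure` (SI), `se` (asymptotic standard errors, MLE only),
#'   `objective`, `converged`, `method`, `n`.
#' @export
fit_nucleation <- function(sample, params, init = NULL,
                           method = c("mle", "histogram")) {
  method <- match.arg(method)
  forces_nN <- if (inherits(sample, "yield_force_sample")) sample$forces else sample
  if (length(forces_nN) < 10) .stopf("need at least 10 forces to fit")
  forces_N <- forces_nN * 1e-9
  start <- if (is.null(init)) .nucleation_init(forces_N, params)
           else log(init)
  if (method == "mle") {
    opt <- stats::optim(start, .nucleation_nll, forces_N = forces_N,
                        params = params, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12),
                        hessian = TRUE)
    se <- rep(NA_real_, 2)
    cv <- tryCatch(solve(opt$hessian), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) > 0)) {
      # delta method from log-parameters
      se <- exp(opt$par) * sqrt(diag(cv))
    }
    objective <- -opt$value
  } else {
    hh <- graphics_free_hist(forces_N)
    opt <- stats::optim(start, .nucleation_hist_obj, mids_N = hh$mids,
                        dens_perN = hh$density, params = params,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    se <- rep(NA_real_, 2)
    objective <- opt$value
  }
  structure(list(line_tension = exp(opt$par[1]),
                 spreading_pressure = exp(opt$par[2]),
                 se = stats::setNames(se, c("line_tension", "spreading_pressure")),
                 objective = objective,
                 converged = opt$convergence == 0,
                 method = method,
                 n = length(forces_N)),
            class = "nucleation_fit")
}

# Freedman-Diaconis histogram without plotting.
#' @keywords internal
graphics_free_hist <- function(x) {
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  list(mids = h$mids, density = h$density)
}

#' @export
print.nucleation_fit <- function(x, ...) {
  cat(sprintf("Nucleation-model fit (%s, n = %d, converged: %s)\n",
              x$method, x$n, x$converged))
  cat(sprintf("  Gamma = %.4g x10^-3 nN (se %.2g)\n",
              x$line_tension * 1e12, x$se[1] * 1e12))
  cat(sprintf("  S     = %.4g x10^-3 N/m (se %.2g)\n",
              x$spreading_pressure * 1e3, x$se[2] * 1e3))
  invisible(x)
}

#' Bootstrap confidence intervals for the nucleation-model fit
#'
#' Case-resampling bootstrap: the yield-force sample is resampled with
#' replacement and refit; percentile intervals are reported. Refit failures
#' are counted and dropped.
#'
#' @inheritParams fit_nucleation
#' @param n_boot Number of bootstrap replicates (>= 1; >= 50 recommended).
#' @param seed Integer seed.
#' @param level Interval coverage, default 0.95.
#' @return List with `line_tension` and `spreading_pressure` percentile
#'   intervals (SI), the replicate matrix, and `n_failed`.
#' @export
bootstrap_nucleation <- function(sample, params, n_boot = 200, seed = 1,
                                 level = 0.95, method = "mle") {
  forces_nN <- if (inherits(sample, "yield_force_sample")) sample$forces else sample
  if (n_boot < 1) .stopf("'n_boot' must be >= 1")
  if (n_boot < 2) .warnf("n_boot = 1 gives a degenerate interval")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(forces_nN), replace = TRUE)
    ft <- tryCatch(fit_nucleation(forces_nN[idx], params, method = method),
                   error = function(e) NULL)
    if (!is.null(ft) && ft$converged)
      reps[b, ] <- c(ft$line_tension, ft$spreading_pressure)
  }
  ok <- stats::complete.cases(reps)
  a <- (1 - level) / 2
  qs <- function(j) stats::quantile(reps[ok, j], c(a, 1 - a), names = FALSE)
  list(line_tension = qs(1), spreading_pressure = qs(2),
       replicates = reps[ok, , drop = FALSE], n_failed = sum(!ok),
       level = level)
}
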