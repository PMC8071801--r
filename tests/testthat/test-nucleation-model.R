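# Continuum nucleation model: analytic identities, closed-form survival
# integral against adaptive quadrature, sampler fidelity, and fitting.

test_that("threshold force and hole-energy identities hold", {
  p <- ref_params()
  expect_equal(threshold_force(p), 2 * pi * 20e-9 * 9.49e-3)
  F <- 4e-9
  rc <- critical_radius(F, p)
  expect_equal(rc, 2 * pi * 20e-9 * 6.93e-12 / (F - threshold_force(p)))
  # the barrier is the hole energy at the critical radius
  expect_equal(nucleation_barrier(F, p), hole_energy(rc, F, p))
  # and the critical radius is a genuine maximum of the hole energy
  eps <- rc * 1e-4
  grad <- (hole_energy(rc + eps, F, p) - hole_energy(rc - eps, F, p)) / (2 * eps)
  expect_lt(abs(grad) * rc / nucleation_barrier(F, p), 1e-6)
  expect_lt(hole_energy(rc * 1.3, F, p), hole_energy(rc, F, p))
  expect_lt(hole_energy(rc * 0.7, F, p), hole_energy(rc, F, p))
})

test_that("barrier is strictly decreasing in force and errors below threshold", {
  p <- ref_params()
  fs <- threshold_force(p)
  F <- seq(fs * 1.05, fs * 4, length.out = 50)
  expect_true(all(diff(nucleation_barrier(F, p)) < 0))
  expect_error(nucleation_barrier(fs, p), "spreading force")
  expect_error(critical_radius(fs * 0.9, p), "spreading force")
  expect_error(hole_energy(-1e-9, 1e-9, p), "non-negative")
})

test_that("closed-form survival matches adaptive quadrature on random parameters", {
  set.seed(42)
  for (i in 1:10) {
    p <- nucleation_params(line_tension = runif(1, 3e-12, 1.1e-11),
                           spreading_pressure = runif(1, 3e-3, 1.5e-2),
                           tip_radius = runif(1, 1e-8, 4e-8))
    fs <- threshold_force(p)
    lam <- p$attempt_freq / (p$spring_constant * p$velocity)
    for (F in fs + c(0.3, 1, 3) * 1e-9) {
      hazard <- function(g) {
        out <- numeric(length(g))
        up <- g > fs
        out[up] <- lam * exp(-nucleation_barrier(g[up], p) /
                               (1.380649e-23 * p$temperature))
        out
      }
      expo <- pracma::integral(hazard, fs, F, reltol = 1e-12)
      expect_equal(yield_survival(F, p), exp(-expo), tolerance = 1e-8)
    }
  }
})

test_that("yield-force pdf is the negative survival derivative and normalizes", {
  p <- ref_params()
  fs <- threshold_force(p)
  F <- fs + 1.5e-9
  eps <- 1e-14
  dnum <- -(yield_survival(F + eps, p) - yield_survival(F - eps, p)) / (2 * eps)
  expect_equal(yield_force_pdf(F, p), dnum, tolerance = 1e-5)
  F_hi <- fs * 2
  while (yield_survival(F_hi, p) > 1e-10) F_hi <- F_hi * 2
  total <- stats::integrate(yield_force_pdf, fs, F_hi, params = p,
                            rel.tol = 1e-9, subdivisions = 500L)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_equal(yield_force_pdf(fs * 0.5, p), 0)
  expect_equal(yield_survival(fs, p), 1)
})

test_that("sampler matches the analytic distribution and is pure", {
  p <- ref_params()
  s1 <- sample_yield_forces(p, 5000, seed = 7)
  s2 <- sample_yield_forces(p, 5000, seed = 7)
  expect_identical(s1$forces, s2$forces)
  expect_s3_class(s1, "yield_force_sample")
  expect_true(all(s1$forces * 1e-9 > threshold_force(p)))
  # empirical exceedance matches the survival function at several forces
  probes_nN <- stats::quantile(s1$forces, c(0.2, 0.5, 0.8), names = FALSE)
  for (q in probes_nN) {
    emp <- mean(s1$forces > q)
    expect_equal(emp, yield_survival(q * 1e-9, p),
                 tolerance = 4 / sqrt(5000))
  }
  # sampling does not disturb the global RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(sample_yield_forces(p, 10, seed = 1))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("maximum-likelihood fit recovers generating parameters within 5%", {
  p <- ref_params()
  s <- sample_yield_forces(p, 5000, seed = 1)
  ft <- fit_nucleation(s, p)
  expect_true(ft$converged)
  expect_lt(abs(ft$line_tension / 6.93e-12 - 1), 0.05)
  expect_lt(abs(ft$spreading_pressure / 9.49e-3 - 1), 0.05)
  expect_true(all(is.finite(ft$se)) && all(ft$se > 0))
})

test_that("histogram fit recovers generating parameters within 10%", {
  p <- ref_params()
  s <- sample_yield_forces(p, 5000, seed = 1)
  ft <- fit_nucleation(s, p, method = "histogram")
  expect_lt(abs(ft$line_tension / 6.93e-12 - 1), 0.10)
  expect_lt(abs(ft$spreading_pressure / 9.49e-3 - 1), 0.10)
  expect_true(all(is.na(ft$se)))
})

test_that("fit validates input and supports explicit initial values", {
  p <- ref_params()
  expect_error(fit_nucleation(c(1, 2, 3), p), "at least 10")
  s <- sample_yield_forces(p, 400, seed = 3)
  ft <- fit_nucleation(s, p, init = c(5e-12, 8e-3))
  expect_true(ft$converged)
  expect_lt(abs(ft$line_tension / 6.93e-12 - 1), 0.2)
})

test_that("bootstrap interval covers the generating parameters", {
  p <- ref_params()
  s <- sample_yield_forces(p, 800, seed = 5)
  ci <- bootstrap_nucleation(s, p, n_boot = 50, seed = 2)
  expect_equal(ci$n_failed, 0)
  expect_true(ci$line_tension[1] <= 6.93e-12 && 6.93e-12 <= ci$line_tension[2])
  expect_true(ci$spreading_pressure[1] <= 9.49e-3 &&
                9.49e-3 <= ci$spreading_pressure[2])
  expect_error(bootstrap_nucleation(s, p, n_boot = 0), ">= 1")
})

test_that("parameter constructor rejects non-positive values", {
  expect_error(nucleation_params(-1e-12, 9e-3), "strictly positive")
  expect_error(nucleation_params(1e-12, 9e-3, temperature = 0),
               "strictly positive")
  expect_error(nucleation_params(c(1e-12, 2e-12), 9e-3), "single finite")
})
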