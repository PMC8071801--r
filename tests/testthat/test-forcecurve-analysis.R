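# Curve analysis: baseline correction, contact and breakthrough detection,
# yield-force statistics, and file-format error handling.

test_that("baseline correction removes offset and tilt", {
  spec <- curve_synth_spec(ref_params())
  cv <- generate_force_curve(spec, seed = 21)
  tilted <- cv
  tilted$force <- cv$force + 0.5 - 0.002 * cv$distance
  bc <- baseline_correct(tilted)
  tr <- attr(cv, "truth")
  pre <- 1:(tr$contact_index - 1)
  # least squares zeroes the mean over the fitted region exactly
  fitted_region <- 1:floor(0.3 * length(cv$force))
  expect_lt(abs(mean(bc$force[fitted_region])), 1e-10)
  # and the whole pre-contact region is left flat and near zero
  expect_lt(abs(coef(lm(bc$force[pre] ~ bc$distance[pre]))[2]), 1e-3)
  expect_lt(abs(mean(bc$force[pre])), 6 * spec$noise_sd * 1e9 / sqrt(length(pre)))
  expect_identical(attr(bc, "truth"), tr)
})

test_that("contact point detection finds the ramp onset", {
  spec <- curve_synth_spec(ref_params())
  cv <- baseline_correct(generate_force_curve(spec, seed = 31))
  tr <- attr(cv, "truth")
  cp <- detect_contact_point(cv)
  # the 3-sigma noise crossing sits ~3*noise/(k_ser*step) ~ 32 samples up
  # the ramp from the geometric contact point
  expect_lt(abs(cp - tr$contact_index), 60)
  flatc <- force_curve(seq(100, 1, by = -0.5), rnorm(199, 0, 0.03))
  expect_warning(cp2 <- detect_contact_point(flatc), "no contact")
  expect_true(is.na(cp2))
})

test_that("breakthrough detection recovers a single clean event", {
  spec <- curve_synth_spec(ref_params())
  cv <- baseline_correct(generate_force_curve(spec, seed = 41))
  tr <- attr(cv, "truth")
  ev <- detect_breakthrough(cv)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$yield_force, tr$breakthrough_force_nN, tolerance = 0.03)
  expect_gt(ev[[1]]$jump_distance, 1)
  rg_true <- tr$plateau_ranges[[1]]
  expect_lt(abs(ev[[1]]$index_range[1] - rg_true[1]), 30)
})

test_that("stacked events are both detected in approach order", {
  spec <- curve_synth_spec(ref_params())
  cv <- baseline_correct(generate_force_curve(spec, seed = 51,
                                              breakthrough_force = c(2e-9, 4e-9)))
  ev <- detect_breakthrough(cv)
  expect_gte(length(ev), 2)
  expect_equal(ev[[1]]$yield_force, 2, tolerance = 0.05)
  expect_equal(ev[[2]]$yield_force, 4, tolerance = 0.05)
  expect_lt(ev[[1]]$index_range[2], ev[[2]]$index_range[1])
})

test_that("extract_yield_forces keeps the first event per curve", {
  spec <- curve_synth_spec(ref_params())
  curves <- lapply(1:40, function(i) generate_force_curve(spec, seed = 60 + i))
  ys <- extract_yield_forces(curves, condition = "test")
  nk <- attr(ys, "n_curves")
  expect_equal(unname(nk["analysed"]), 40)
  expect_gte(unname(nk["kept"]), 38)
  truths <- vapply(curves, function(cv)
    attr(cv, "truth")$breakthrough_force_nN[1], 0)
  expect_equal(median(ys$forces), median(truths), tolerance = 0.05)
  expect_error(extract_yield_forces(list()), "no breakthrough")
})

test_that("normalization divides by the reference median", {
  a <- yield_force_sample(c(2, 3, 4, 5, 6), condition = "a")
  b <- yield_force_sample(c(4, 6, 8, 10, 12), condition = "b")
  nb <- normalize_yield_forces(b, a)
  expect_true(nb$normalized)
  expect_equal(nb$reference_median, 4)
  expect_equal(median(nb$forces), 2)
  expect_error(yield_force_sample(c(1, -2)), "finite and > 0")
})

test_that("ecdf table and boxplot stats match reference implementations", {
  set.seed(8)
  x <- rlnorm(200, 1, 0.3)
  et <- ecdf_table(x)
  expect_equal(et$force, sort(unique(x)))
  expect_equal(et$cumprob, stats::ecdf(x)(et$force))
  expect_equal(attr(et, "median"), median(x))
  bs <- boxplot_stats(x)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(c(bs$q1, bs$median, bs$q3), q)
  expect_equal(bs$whisker_hi, q[3] + 1.5 * (q[3] - q[1]))
  expect_equal(sort(bs$outliers), sort(x[x < bs$whisker_lo | x > bs$whisker_hi]))
  expect_error(boxplot_stats(c(1, 2, 3)), "at least 5")
})

test_that("malformed curve files abort with the offending line", {
  dir <- tmp_dir()
  bad <- file.path(dir, "bad.txt")
  writeLines(c("# spring_constant=0.06", "# velocity=1e-6",
               "10 0.1", "9 oops", "8 0.3"), bad)
  expect_error(read_force_curves(bad), "line 4")
  short <- file.path(dir, "short.txt")
  writeLines(c("# spring_constant=0.06", "# velocity=1e-6",
               "10 0.1 0.2"), short)
  expect_error(read_force_curves(short), "malformed row")
  nometa <- file.path(dir, "nometa.txt")
  writeLines(c("# velocity=1e-6", "10 0.1"), nometa)
  expect_error(read_force_curves(nometa), "spring_constant")
  empty <- file.path(dir, "empty.txt")
  writeLines(c("# spring_constant=0.06", "# velocity=1e-6"), empty)
  expect_warning(out <- read_force_curves(empty), "no data rows")
  expect_length(out, 0)
})

test_that("csv dialect reads named columns", {
  dir <- tmp_dir()
  f <- file.path(dir, "c.csv")
  write.csv(data.frame(distance = c(10, 9, 8), force = c(0, 0.1, 0.2)),
            f, row.names = FALSE)
  cv <- read_force_curves(f, format = "csv")[[1]]
  expect_s3_class(cv, "force_curve")
  expect_equal(cv$force, c(0, 0.1, 0.2))
  write.csv(data.frame(d = 1:3, force = 1:3), f, row.names = FALSE)
  expect_error(read_force_curves(f, format = "csv"), "distance")
})
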