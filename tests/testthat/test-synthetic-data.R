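# Generators: force curves, umbrella datasets, membrane snapshots, and
# their file round-trips.

test_that("force-curve generator is pure and matches its ground truth", {
  spec <- curve_synth_spec(ref_params())
  c1 <- generate_force_curve(spec, seed = 11)
  c2 <- generate_force_curve(spec, seed = 11)
  expect_identical(c1, c2)
  tr <- attr(c1, "truth")
  expect_true(tr$breakthrough_force_nN * 1e-9 > threshold_force(ref_params()))
  # mean raw force over the true plateau reproduces the drawn force
  rg <- tr$plateau_ranges[[1]]
  plat <- c1$force[rg[1]:rg[2]]
  n_plat <- rg[2] - rg[1] + 1
  expect_equal(mean(plat), tr$breakthrough_force_nN,
               tolerance = 4 * (spec$noise_sd * 1e9) / sqrt(n_plat) /
                 tr$breakthrough_force_nN)
  # pre-contact baseline is centred on zero
  expect_lt(abs(mean(c1$force[1:(tr$contact_index - 1)])),
            4 * spec$noise_sd * 1e9 / sqrt(tr$contact_index - 1))
  # generation does not disturb the global RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_force_curve(spec, seed = 1))
  expect_identical(before, runif(3))
})

test_that("fixed and stacked breakthrough forces are honoured", {
  spec <- curve_synth_spec(ref_params(), noise_sd = 0)
  cv <- generate_force_curve(spec, seed = 1, breakthrough_force = 2.5e-9)
  tr <- attr(cv, "truth")
  expect_equal(tr$breakthrough_force_nN, 2.5)
  cv2 <- generate_force_curve(spec, seed = 1,
                              breakthrough_force = c(2e-9, 4e-9))
  tr2 <- attr(cv2, "truth")
  expect_length(tr2$plateau_ranges, 2)
  rg <- tr2$plateau_ranges[[2]]
  expect_equal(unique(cv2$force[rg[1]:rg[2]]), 4)
})

test_that("force curves round-trip through the text format", {
  spec <- curve_synth_spec(ref_params())
  curves <- lapply(1:3, function(i) generate_force_curve(spec, seed = i))
  dir <- tmp_dir()
  write_force_curves(curves, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  back <- read_force_curves(dir)
  expect_length(back, 3)
  expect_equal(back[[1]]$distance, curves[[1]]$distance, tolerance = 1e-10)
  expect_equal(back[[1]]$force, curves[[1]]$force, tolerance = 1e-10)
  expect_equal(back[[1]]$meta$spring_constant, 0.060)
})

test_that("umbrella boundary window reproduces the truncated-Gaussian law", {
  ds <- generate_umbrella_dataset(flat_pmf(), centers = 1.0,
                                  force_constants = 10000,
                                  n_per_window = 2e5, seed = 3)
  x <- ds$windows[[1]]$samples
  sg <- sqrt(0.0083144621 * 323 / 10000)
  m_exact <- 1 - sg * dnorm(0) / pnorm(0)       # half-normal below 1
  s_exact <- sg * sqrt(1 - 2 / pi)
  expect_equal(mean(x), m_exact, tolerance = 4 * s_exact / sqrt(2e5) / m_exact)
  expect_equal(sd(x), s_exact, tolerance = 0.01)
  expect_true(all(x <= 1 & x >= 0))
})

test_that("umbrella generator is pure and warns on non-overlapping windows", {
  tr <- pmf_sigmoid()
  d1 <- suppressWarnings(generate_umbrella_dataset(tr, n_per_window = 200,
                                                   seed = 5))
  d2 <- suppressWarnings(generate_umbrella_dataset(tr, n_per_window = 200,
                                                   seed = 5))
  expect_identical(d1, d2)
  expect_warning(
    generate_umbrella_dataset(flat_pmf(), centers = c(0.2, 0.8),
                              force_constants = c(5000, 5000),
                              n_per_window = 100, seed = 1),
    "no sampled overlap")
  expect_error(
    generate_umbrella_dataset(flat_pmf(), centers = 1.5,
                              force_constants = 5000, n_per_window = 10,
                              seed = 1),
    "cover")
})

test_that("umbrella datasets round-trip with equilibration discard", {
  ds <- generate_umbrella_dataset(pmf_sigmoid(), n_per_window = 100, seed = 2)
  dir <- tmp_dir()
  write_umbrella_dataset(ds, dir)
  back <- read_umbrella_dataset(file.path(dir, "windows.dat"))
  expect_equal(back$temperature, 323)
  expect_length(back$windows, 24)
  expect_equal(back$windows[[5]]$samples, ds$windows[[5]]$samples,
               tolerance = 1e-9)
  expect_equal(back$windows[[5]]$center, ds$windows[[5]]$center)
  half <- read_umbrella_dataset(file.path(dir, "windows.dat"),
                                equilibration_fraction = 0.5)
  expect_length(half$windows[[1]]$samples, 50)
  expect_equal(half$windows[[1]]$samples, ds$windows[[1]]$samples[51:100],
               tolerance = 1e-9)
})

test_that("membrane snapshot generator is pure and honours its spec", {
  spec <- snapshot_spec()
  s1 <- generate_membrane_snapshot(spec, seed = 4)
  s2 <- generate_membrane_snapshot(spec, seed = 4)
  expect_identical(s1, s2)
  tb <- table(s1$positions$species)
  expect_equal(unname(tb["phos_p"]), 128)
  expect_equal(unname(tb["phos_o"]), 384)
  expect_equal(unname(tb["tail"]), 1024)
  # a pore removes core tails at the box centre and adds water there
  sp <- generate_membrane_snapshot(snapshot_spec(pore_radius = 1.2), seed = 4)
  core <- sp$positions$species == "tail"
  d2 <- (sp$positions$x - 3.2)^2 + (sp$positions$y - 3.2)^2
  expect_true(all(d2[core] >= 1.2^2))
  wcore <- sp$positions$species == "water_o" & abs(sp$positions$z) < 1.0
  expect_gt(sum(wcore & d2 < 1.2^2), 50)
})

test_that("snapshots round-trip through CSV and PDB", {
  sn <- generate_membrane_snapshot(snapshot_spec(n_lipids_per_leaflet = 8,
                                                 tails_per_lipid = 2),
                                   seed = 9)
  dir <- tmp_dir()
  csv <- file.path(dir, "snap.csv")
  write_snapshot_csv(sn, csv)
  back <- read_snapshot_csv(csv)
  expect_equal(back$box, sn$box)
  expect_equal(back$positions$z, sn$positions$z, tolerance = 1e-9)
  expect_equal(as.character(back$positions$species),
               as.character(sn$positions$species))
  pdb <- file.path(dir, "snap.pdb")
  write_snapshot_pdb(sn, pdb)
  bp <- read_snapshot_pdb(pdb)
  expect_equal(bp$box, sn$box, tolerance = 1e-3)
  # PDB stores 3 decimals in Angstrom = 1e-4 nm resolution
  expect_equal(bp$positions$x, sn$positions$x, tolerance = 1e-3)
  expect_equal(bp$positions$z, sn$positions$z, tolerance = 1e-3)
  expect_equal(as.character(bp$positions$species),
               as.character(sn$positions$species))
})
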