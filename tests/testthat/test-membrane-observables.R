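# Chain coordinate, defect-following cylinder placement, thickness, area
# per lipid, and cylindrical density maps.

test_that("one polar atom per slice gives exactly the single-atom occupancy", {
  sn <- one_atom_per_slice_snapshot()
  p <- chain_coord_params(center = c(3, 3))
  expect_identical(chain_coordinate(sn, p), 0.75)
  p2 <- chain_coord_params(center = c(3, 3), zeta = 0.5)
  expect_identical(chain_coordinate(sn, p2), 0.5)
})

test_that("chain coordinate separates flat membranes from water columns", {
  flat <- generate_membrane_snapshot(snapshot_spec(), seed = 1)
  xi_flat <- chain_coordinate(flat)
  expect_gt(xi_flat, 0.15)
  expect_lt(xi_flat, 0.35)
  pore <- generate_membrane_snapshot(snapshot_spec(pore_radius = 1.0), seed = 1)
  expect_gte(chain_coordinate(pore), 0.85)
})

test_that("empty and oversized-cylinder cases are handled", {
  empty <- membrane_snapshot(
    data.frame(x = 1, y = 1, z = 0, species = "tail"), box = c(6, 6, 7))
  expect_warning(xi <- chain_coordinate(empty), "no polar")
  expect_identical(xi, 0)
  sn <- one_atom_per_slice_snapshot()
  tall <- chain_coord_params(n_slices = 100, center = c(3, 3))
  expect_error(chain_coordinate(sn, tall), "exceeds the box")
})

test_that("cylinder placement follows the defect and breaks ties towards low x then y", {
  # two identical single-atom columns; every grid point within reach of
  # either column scores the same, so the lowest-x (then lowest-y) grid
  # point in range must win
  z <- -1.5 + 0.05 + 0.1 * (0:29)
  pos <- rbind(data.frame(x = 1, y = 1, z = z, species = "water_o"),
               data.frame(x = 5, y = 3, z = z, species = "water_o"))
  sn <- membrane_snapshot(pos, box = c(6, 6, 4), periodic = TRUE)
  ctr <- optimize_cylinder_center(sn)
  # (0, 0.4) is the first grid point whose cylinder of radius 1.2 reaches
  # the column at (1, 1): (0-1)^2 + (0.4-1)^2 = 1.36 <= 1.44
  expect_equal(ctr, c(0, 0.4))
})

test_that("cylinder placement respects lateral periodicity", {
  z <- -1.5 + 0.05 + 0.1 * (0:29)
  sn <- membrane_snapshot(
    data.frame(x = 0.05, y = 5.95, z = z, species = "water_o"),
    box = c(6, 6, 4), periodic = TRUE)
  p <- chain_coord_params(center = "auto")
  expect_identical(chain_coordinate(sn, p), 0.75)
})

test_that("thickness and area per lipid match the constructed geometry", {
  sn <- generate_membrane_snapshot(snapshot_spec(), seed = 2)
  expect_equal(membrane_thickness(sn), 2 * 1.9, tolerance = 0.08 / 3.8)
  expect_equal(area_per_lipid(sn), 6.4 * 6.4 / 64)
  asym <- membrane_snapshot(
    data.frame(x = c(1, 2, 3), y = 1, z = c(1.9, 1.9, -1.9),
               species = "phos_p"), box = c(6, 6, 7))
  expect_warning(apl <- area_per_lipid(asym), "asymmetric")
  expect_equal(apl, 36 / 1.5)
  lone <- membrane_snapshot(
    data.frame(x = 1, y = 1, z = 1.9, species = "phos_p"), box = c(6, 6, 7))
  expect_error(membrane_thickness(lone), "both leaflets")
})

test_that("cylindrical density conserves binned mass and finds bulk water", {
  sn <- generate_membrane_snapshot(snapshot_spec(), seed = 3)
  ctr <- c(3.2, 3.2)
  map <- cylindrical_density(sn, center = ctr)
  vol <- outer(pi * diff(map$r_edges^2), diff(map$z_edges))
  total <- sum(map$density * vol)
  # direct mass of the atoms inside the map's cylinder
  p <- sn$positions
  dx <- pmin(abs(p$x - ctr[1]), 6.4 - abs(p$x - ctr[1]))
  dy <- pmin(abs(p$y - ctr[2]), 6.4 - abs(p$y - ctr[2]))
  masses <- c(water_o = 18.015, phos_p = 30.974, phos_o = 15.999,
              tail = 14.027, arg = 58.0)
  inside <- sqrt(dx^2 + dy^2) <= max(map$r_edges) & abs(p$z) <= 3.5
  expect_equal(total, sum(masses[as.character(p$species[inside])]),
               tolerance = 1e-6)
  # water-only map approaches bulk water density far from the membrane
  wmap <- cylindrical_density(sn, species = "water_o", center = ctr)
  zmid <- (wmap$z_edges[-1] + wmap$z_edges[-length(wmap$z_edges)]) / 2
  bulk <- mean(wmap$density[, abs(zmid) > 2.6])
  expect_equal(bulk, 33 * 18.015, tolerance = 0.1)
})

test_that("density maps round-trip through TSV plus JSON sidecar", {
  sn <- generate_membrane_snapshot(snapshot_spec(n_lipids_per_leaflet = 8),
                                   seed = 5)
  map <- cylindrical_density(sn, center = c(3.2, 3.2), n_r = 6, n_z = 8)
  dir <- tmp_dir()
  pth <- file.path(dir, "map.tsv")
  write_density_map(map, pth)
  df <- read.delim(pth)
  expect_equal(nrow(df), 6 * 8)
  expect_equal(df$density, as.vector(map$density))
  side <- jsonlite::read_json(paste0(pth, ".json"), simplifyVector = TRUE)
  expect_equal(side$r_edges, map$r_edges)
  expect_equal(side$center, c(3.2, 3.2))
})
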