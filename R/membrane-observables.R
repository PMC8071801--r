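# Observables on membrane snapshots: the pore chain coordinate, membrane
# thickness, area per lipid, and cylindrical density maps around a defect.

#' Parameters of the chain coordinate
#'
#' The chain coordinate probes the connectivity of a polar transmembrane
#' defect: a membrane-spanning cylinder of radius `cylinder_radius` is cut
#' into `n_slices` slices of `slice_thickness`, and the coordinate is the
#' mean slice occupancy, where a slice holding N polar heavy atoms (water
#' oxygens and lipid phosphate oxygens) contributes
#' `occ(N) = 1 - (1 - zeta)^N`: 0 when empty, `zeta` for the first atom,
#' saturating towards 1. Values around 0.25 indicate a flat membrane (only
#' the headgroup-region slices are polar), values above about 0.85 a
#' continuous membrane-spanning polar defect.
#'
#' @param cylinder_radius Cylinder radius (nm), default 1.2.
#' @param n_slices Number of slices, default 30.
#' @param slice_thickness Slice thickness (nm), default 0.1.
#' @param zeta Occupancy contributed by the first polar atom in a slice,
#'   in (0, 1]; default 0.75.
#' @param center Lateral cylinder position `c(x, y)` in nm, or `"auto"` to
#'   place it on the strongest polar defect via
#'   [optimize_cylinder_center()].
#' @return Object of class `chain_coord_params`.
#' @export
chain_coord_params <- function(cylinder_radius = 1.2, n_slices = 30,
                               slice_thickness = 0.1, zeta = 0.75,
                               center = "auto") {
  .check_scalar_pos(cylinder_radius, "cylinder_radius")
  .check_scalar_pos(slice_thickness, "slice_thickness")
  if (n_slices < 1) .stopf("'n_slices' must be >= 1")
  if (zeta <= 0 || zeta > 1) .stopf("'zeta' must be in (0, 1]")
  structure(list(cylinder_radius = cylinder_radius,
                 n_slices = as.integer(n_slices),
                 slice_thickness = slice_thickness, zeta = zeta,
                 center = center),
            class = "chain_coord_params")
}

#' @keywords internal
.polar_species <- c("water_o", "phos_o")

#' @keywords internal
.lateral_dist2 <- function(x, y, cx, cy, box, periodic) {
  dx <- x - cx; dy <- y - cy
  if (periodic) {
    dx <- dx - round(dx / box[1]) * box[1]
    dy <- dy - round(dy / box[2]) * box[2]
  }
  dx^2 + dy^2
}

#' @keywords internal
.chain_coord_at <- function(px, py, pz, cx, cy, params, box, periodic) {
  half <- params$n_slices * params$slice_thickness / 2
  d2 <- .lateral_dist2(px, py, cx, cy, box, periodic)
  inside <- d2 <= params$cylinder_radius^2 & pz >= -half & pz < half
  if (!any(inside)) return(0)
  slice <- floor((pz[inside] + half) / params$slice_thickness) + 1L
  counts <- tabulate(slice, params$n_slices)
  mean(1 - (1 - params$zeta)^counts)
}

#' Chain coordinate of a snapshot
#'
#' @param snapshot A [membrane_snapshot()].
#' @param params A [chain_coord_params()].
#' @return The chain coordinate in `[0, 1]`. An empty snapshot returns 0
#'   with a warning.
#' @export
chain_coordinate <- function(snapshot, params = chain_coord_params()) {
  stopifnot(inherits(snapshot, "membrane_snapshot"),
            inherits(params, "chain_coord_params"))
  if (params$n_slices * params$slice_thickness > snapshot$box[3])
    .stopf("cylinder height (%g nm) exceeds the box",
           params$n_slices * params$slice_thickness)
  p <- snapshot$positions[snapshot$positions$species %in% .polar_species, ]
  if (!nrow(p)) {
    .warnf("snapshot contains no polar heavy atoms; chain coordinate is 0")
    return(0)
  }
  center <- params$center
  if (identical(center, "auto"))
    center <- optimize_cylinder_center(snapshot, params)
  .chain_coord_at(p$x, p$y, p$z, center[1], center[2], params,
                  snapshot$box, snapshot$periodic)
}

#' Place the cylinder on the strongest polar defect
#'
#' Grid-searches the lateral box for the position maximizing the chain
#' coordinate, emulating a defect-following cylinder for static snapshots.
#' Ties are broken deterministically towards the lowest x, then lowest y.
#'
#' @inheritParams chain_coordinate
#' @param grid_step Lateral grid spacing (nm), default 0.1.
#' @return Lateral position `c(x, y)` in nm.
#' @export
optimize_cylinder_center <- function(snapshot, params = chain_coord_params(),
                                     grid_step = 0.1) {
  stopifnot(inherits(snapshot, "membrane_snapshot"))
  .check_scalar_pos(grid_step, "grid_step")
  p <- snapshot$positions[snapshot$positions$species %in% .polar_species, ]
  gx <- seq(0, snapshot$box[1] - 1e-9, by = grid_step)
  gy <- seq(0, snapshot$box[2] - 1e-9, by = grid_step)
  if (!nrow(p)) return(c(gx[1], gy[1]))
  # restrict to polar atoms that can ever fall inside the cylinder
  half <- params$n_slices * params$slice_thickness / 2
  p <- p[p$z >= -half & p$z < half, ]
  if (!nrow(p)) return(c(gx[1], gy[1]))
  best <- -Inf; best_xy <- c(gx[1], gy[1])
  for (cx in gx) for (cy in gy) {
    v <- .chain_coord_at(p$x, p$y, p$z, cx, cy, params,
                         snapshot$box, snapshot$periodic)
    if (v > best + 1e-12) { best <- v; best_xy <- c(cx, cy) }
    # ties keep the earlier (lower x, then lower y) candidate
  }
  best_xy
}

#' Membrane thickness
#'
#' Mean distance between the phosphate atoms of the opposite leaflets:
#' `|mean z(upper P) - mean z(lower P)|`, with leaflets assigned by the sign
#' of z.
#'
#' @param snapshot A [membrane_snapshot()].
#' @return Thickness in nm.
#' @export
membrane_thickness <- function(snapshot) {
  stopifnot(inherits(snapshot, "membrane_snapshot"))
  z <- snapshot$positions$z[snapshot$positions$species == "phos_p"]
  up <- z[z > 0]; lo <- z[z <= 0]
  if (!length(up) || !length(lo))
    .stopf("both leaflets need at least one phosphate atom (upper: %d, lower: %d)",
           length(up), length(lo))
  abs(mean(up) - mean(lo))
}

#' Area per lipid
#'
#' Lateral box area divided by the number of lipids per leaflet (counted as
#' phosphate P atoms; leaflets are averaged when slightly asymmetric).
#'
#' @param snapshot A [membrane_snapshot()].
#' @return Area per lipid in nm^2.
#' @export
area_per_lipid <- function(snapshot) {
  stopifnot(inherits(snapshot, "membrane_snapshot"))
  z <- snapshot$positions$z[snapshot$positions$species == "phos_p"]
  n_up <- sum(z > 0); n_lo <- sum(z <= 0)
  if (n_up + n_lo == 0) .stopf("snapshot contains no phosphate atoms")
  n <- (n_up + n_lo) / 2
  if (n_up != n_lo)
    .warnf("leaflets are asymmetric (%d vs %d phosphates); using the mean",
           n_up, n_lo)
  snapshot$box[1] * snapshot$box[2] / n
}

#' @keywords internal
.default_masses <- c(water_o = 18.015, phos_p = 30.974, phos_o = 15.999,
                     tail = 14.027, arg = 58.0)

#' Cylindrical density map around a defect
#'
#' Mass density as a function of lateral distance r and vertical distance z
#' from the defect center, averaged over snapshots. Each atom contributes
#' its species mass; histogram counts are normalized by the true annular bin
#' volume `pi (r_out^2 - r_in^2) dz`, so integrating the map over bin
#' volumes recovers the binned mass exactly.
#'
#' @param snapshots A [membrane_snapshot()] or list of them.
#' @param species Character vector of species to include (default: all).
#' @param center Lateral center `c(x, y)` in nm, or `"auto"` to center on
#'   the polar defect of the first snapshot.
#' @param r_max Maximum lateral distance (nm); default half the smaller
#'   lateral box length.
#' @param n_r,n_z Number of radial / vertical bins.
#' @param masses Named vector of atomic masses (amu) per species; water
#'   oxygens carry the full water mass.
#' @return List with `r_edges`, `z_edges` (nm), `density` (amu/nm^3 matrix,
#'   rows = r bins, cols = z bins), and `center`.
#' @export
cylindrical_density <- function(snapshots, species = NULL, center = "auto",
                                r_max = NULL, n_r = 24, n_z = 30,
                                masses = .default_masses) {
  if (inherits(snapshots, "membrane_snapshot")) snapshots <- list(snapshots)
  if (!length(snapshots)) .stopf("need at least one snapshot")
  if (n_r < 1 || n_z < 1) .stopf("bin counts must be >= 1")
  s1 <- snapshots[[1]]
  if (identical(center, "auto"))
    center <- optimize_cylinder_center(s1)
  if (is.null(r_max)) r_max <- min(s1$box[1:2]) / 2
  r_edges <- seq(0, r_max, length.out = n_r + 1L)
  z_edges <- seq(-s1$box[3] / 2, s1$box[3] / 2, length.out = n_z + 1L)
  acc <- matrix(0, n_r, n_z)
  for (sn in snapshots) {
    p <- sn$positions
    if (!is.null(species)) p <- p[p$species %in% species, ]
    if (!nrow(p)) next
    r <- sqrt(.lateral_dist2(p$x, p$y, center[1], center[2], sn$box,
                             sn$periodic))
    ir <- findInterval(r, r_edges, rightmost.closed = TRUE)
    iz <- findInterval(p$z, z_edges, rightmost.closed = TRUE)
    ok <- ir >= 1 & ir <= n_r & iz >= 1 & iz <= n_z
    m <- masses[as.character(p$species)]
    idx <- (iz[ok] - 1L) * n_r + ir[ok]
    sums <- rowsum(m[ok], idx)
    acc[as.integer(rownames(sums))] <- acc[as.integer(rownames(sums))] + sums[, 1]
  }
  dz <- diff(z_edges)[1]
  vol <- outer(pi * (r_edges[-1]^2 - r_edges[-(n_r + 1)]^2), rep(dz, n_z))
  list(r_edges = r_edges, z_edges = z_edges,
       density = acc / vol / length(snapshots), center = center)
}

#' Write a density map as TSV plus metadata JSON
#'
#' @param map Result of [cylindrical_density()].
#' @param path Output TSV (columns `r`, `z`, `density`); a `.json` sidecar
#'   stores edges and center.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  rm_ <- (map$r_edges[-1] + map$r_edges[-length(map$r_edges)]) / 2
  zm <- (map$z_edges[-1] + map$z_edges[-length(map$z_edges)]) / 2
  df <- expand.grid(r = rm_, z = zm)
  df$density <- as.vector(map$density)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(r_edges = map$r_edges, z_edges = map$z_edges,
                            center = map$center),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}
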