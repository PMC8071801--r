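# Toy membrane snapshots: two jittered phosphate planes, hydrating water
# above and below the slab (penetrating the headgroup region), optional
# water-filled cylindrical pore, and disordered tail atoms in the core.

#' Specification of a toy membrane snapshot
#'
#' @param n_lipids_per_leaflet Lipids per leaflet (default 64, i.e. 128
#'   lipids total).
#' @param box Box lengths `c(Lx, Ly, Lz)` in nm.
#' @param leaflet_z Height of the phosphate planes above/below the membrane
#'   mid-plane (nm); the planes sit at `+leaflet_z` and `-leaflet_z`.
#' @param pore_radius Radius (nm) of a water-filled transmembrane cylinder,
#'   or `NULL` for an intact membrane. Must fit inside half the lateral box.
#' @param water_density Water number density (per nm^3) in the aqueous
#'   region, default 33 (liquid water).
#' @param water_margin Depth (nm) below each phosphate plane down to which
#'   water penetrates the headgroup region (hydration of glycerol/phosphate
#'   moieties), default 0.8.
#' @param jitter_sd SD (nm) of the vertical jitter of phosphate atoms.
#' @param tails_per_lipid Tail pseudo-atoms per lipid placed uniformly in
#'   the hydrophobic core (for density maps), default 8.
#' @return Object of class `snapshot_spec`.
#' @export
snapshot_spec <- function(n_lipids_per_leaflet = 64,
                          box = c(6.4, 6.4, 7.0),
                          leaflet_z = 1.9,
                          pore_radius = NULL,
                          water_density = 33,
                          water_margin = 0.8,
                          jitter_sd = 0.1,
                          tails_per_lipid = 8) {
  if (length(box) != 3 || any(box <= 0)) .stopf("'box' must be 3 positive lengths")
  .check_scalar_pos(leaflet_z, "leaflet_z")
  if (2 * leaflet_z >= box[3]) .stopf("slab (2*leaflet_z) must fit inside the box")
  if (!is.null(pore_radius)) {
    .check_scalar_pos(pore_radius, "pore_radius", strict = FALSE)
    if (pore_radius > min(box[1:2]) / 2)
      .stopf("pore_radius (%g nm) exceeds half the lateral box", pore_radius)
  }
  .check_scalar_pos(water_density, "water_density")
  .check_scalar_pos(water_margin, "water_margin", strict = FALSE)
  structure(list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 box = as.numeric(box), leaflet_z = leaflet_z,
                 pore_radius = pore_radius, water_density = water_density,
                 water_margin = water_margin, jitter_sd = jitter_sd,
                 tails_per_lipid = as.integer(tails_per_lipid)),
            class = "snapshot_spec")
}

#' Construct a membrane snapshot container
#'
#' @param positions Data frame with columns `x`, `y`, `z` (nm) and `species`
#'   (one of `"phos_p"`, `"phos_o"`, `"water_o"`, `"tail"`, `"arg"`).
#' @param box Box lengths (nm).
#' @param periodic Whether lateral minimum-image conventions apply.
#' @return Object of class `membrane_snapshot`.
#' @export
membrane_snapshot <- function(positions, box, periodic = TRUE) {
  need <- c("x", "y", "z", "species")
  if (!all(need %in% names(positions)))
    .stopf("positions must have columns %s", paste(need, collapse = ", "))
  structure(list(positions = positions, box = as.numeric(box),
                 periodic = isTRUE(periodic)),
            class = "membrane_snapshot")
}

#' @export
print.membrane_snapshot <- function(x, ...) {
  tb <- table(x$positions$species)
  cat(sprintf("membrane_snapshot: %d atoms in %.3g x %.3g x %.3g nm box (%s)\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3],
              paste(names(tb), tb, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Generate a toy membrane snapshot
#'
#' Phosphate P atoms (with three satellite phosphate O atoms each) sit on
#' two laterally uniform, vertically jittered planes; water oxygens fill the
#' aqueous region down to `water_margin` below each phosphate plane; tail
#' pseudo-atoms fill the hydrophobic core. If `pore_radius` is set, a
#' water-filled cylinder at the box center crosses the slab.
#'
#' @param spec A [snapshot_spec()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @return A [membrane_snapshot()].
#' @export
generate_membrane_snapshot <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "snapshot_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  Lx <- spec$box[1]; Ly <- spec$box[2]; Lz <- spec$box[3]
  nL <- spec$n_lipids_per_leaflet
  zs <- c(rep(spec$leaflet_z, nL), rep(-spec$leaflet_z, nL))
  px <- stats::runif(2 * nL, 0, Lx); py <- stats::runif(2 * nL, 0, Ly)
  pz <- zs + stats::rnorm(2 * nL, 0, spec$jitter_sd)
  P <- data.frame(x = px, y = py, z = pz, species = "phos_p")
  # satellite phosphate oxygens
  nO <- 3L * 2L * nL
  base <- P[rep(seq_len(2 * nL), each = 3L), ]
  O <- data.frame(x = base$x + stats::rnorm(nO, 0, 0.12),
                  y = base$y + stats::rnorm(nO, 0, 0.12),
                  z = base$z + stats::rnorm(nO, 0, 0.12),
                  species = "phos_o")
  # bulk + hydration water: |z| > leaflet_z - water_margin
  z_lo <- spec$leaflet_z - spec$water_margin
  vol_water <- Lx * Ly * (Lz - 2 * z_lo)
  nW <- stats::rpois(1, spec$water_density * vol_water)
  # uniform in the two aqueous slabs above and below the core
  half <- Lz / 2 - z_lo
  wz <- (z_lo + stats::runif(nW, 0, half)) * sample(c(-1, 1), nW, replace = TRUE)
  W <- data.frame(x = stats::runif(nW, 0, Lx), y = stats::runif(nW, 0, Ly),
                  z = wz, species = "water_o")
  # tails in the core
  nT <- spec$tails_per_lipid * 2L * nL
  Tl <- data.frame(x = stats::runif(nT, 0, Lx), y = stats::runif(nT, 0, Ly),
                   z = stats::runif(nT, -z_lo, z_lo), species = "tail")
  pos <- rbind(P, O, W, Tl)
  if (!is.null(spec$pore_radius) && spec$pore_radius > 0) {
    r <- spec$pore_radius
    vol_pore <- pi * r^2 * 2 * z_lo
    nP <- stats::rpois(1, spec$water_density * vol_pore)
    rr <- r * sqrt(stats::runif(nP)); th <- stats::runif(nP, 0, 2 * pi)
    pore <- data.frame(x = Lx / 2 + rr * cos(th), y = Ly / 2 + rr * sin(th),
                       z = stats::runif(nP, -z_lo, z_lo), species = "water_o")
    # remove tails inside the pore cylinder
    d2 <- (pos$x - Lx / 2)^2 + (pos$y - Ly / 2)^2
    pos <- pos[!(pos$species == "tail" & d2 < r^2), ]
    pos <- rbind(pos, pore)
  }
  pos$x <- pos$x %% Lx
  pos$y <- pos$y %% Ly
  membrane_snapshot(pos, spec$box, periodic = TRUE)
}

# --- file formats ----------------------------------------------------------

#' @keywords internal
.species_to_pdb <- list(phos_p = c("P", "P"), phos_o = c("O1", "O"),
                        water_o = c("OW", "O"), tail = c("C1", "C"),
                        arg = c("CZ", "C"))

#' Write / read a snapshot as minimal PDB
#'
#' Atom names encode the species (P = phosphate phosphorus, O1 = phosphate
#' oxygen, OW = water oxygen, C1 = tail carbon); the box goes into a CRYST1
#' record. Coordinates are converted nm <-> Angstrom; z is stored relative
#' to the box center.
#'
#' @param snapshot A [membrane_snapshot()].
#' @param path Output `.pdb` file.
#' @return `path`, invisibly.
#' @export
write_snapshot_pdb <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "membrane_snapshot"))
  p <- snapshot$positions
  nm <- t(vapply(as.character(p$species), function(s)
    .species_to_pdb[[s]], character(2)))
  xyz <- as.vector(t(cbind(p$x, p$y, p$z + snapshot$box[3] / 2) * 10))
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   snapshot$box[1] * 10, snapshot$box[2] * 10,
                   snapshot$box[3] * 10, 90, 90, 90)
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = xyz, elety = nm[, 1],
                   resno = seq_len(nrow(p)), resid = rep("MOL", nrow(p)),
                   elesy = nm[, 2])
  writeLines(c(cryst, readLines(tmp, warn = FALSE)), path)
  unlink(tmp)
  invisible(path)
}

#' @rdname write_snapshot_pdb
#' @export
read_snapshot_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) .stopf("%s: missing CRYST1 box record", basename(path))
  box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33))) / 10
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  name2sp <- c(P = "phos_p", O1 = "phos_o", OW = "water_o", C1 = "tail",
               CZ = "arg")
  sp <- name2sp[trimws(at$elety)]
  if (any(is.na(sp))) .stopf("%s: unknown atom name(s): %s", basename(path),
                             paste(unique(at$elety[is.na(sp)]), collapse = ", "))
  pos <- data.frame(x = at$x / 10, y = at$y / 10, z = at$z / 10 - box[3] / 2,
                    species = unname(sp))
  membrane_snapshot(pos, box, periodic = TRUE)
}

#' Write / read a snapshot as internal CSV
#'
#' Columns `x, y, z, species` (nm) plus a `# box=Lx Ly Lz` header line.
#'
#' @inheritParams write_snapshot_pdb
#' @export
write_snapshot_csv <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "membrane_snapshot"))
  writeLines(sprintf("# box=%.10g %.10g %.10g", snapshot$box[1],
                     snapshot$box[2], snapshot$box[3]), path)
  suppressWarnings(utils::write.table(snapshot$positions, path, append = TRUE,
                                      sep = ",", row.names = FALSE,
                                      quote = FALSE))
  invisible(path)
}

#' @rdname write_snapshot_csv
#' @export
read_snapshot_csv <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (!grepl("^# box=", l1)) .stopf("%s: missing '# box=' header", basename(path))
  box <- as.numeric(strsplit(sub("^# box=", "", l1), "\\s+")[[1]])
  pos <- utils::read.csv(path, comment.char = "#")
  membrane_snapshot(pos, box, periodic = TRUE)
}
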