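# Shared fixtures. Expensive objects are built once per session.

# Reference membrane composition used throughout: line tension 6.93e-3 nN,
# spreading pressure 9.49e-3 N/m, with the default instrument parameters
# (R = 20 nm, K = 0.060 N/m, v = 1 um/s, A = 3 kHz, T = 298 K).
ref_params <- function() nucleation_params(6.93e-12, 9.49e-3)

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

# Fresh directory under the session tempdir; removed with the session.
tmp_dir <- function() {
  d <- tempfile("poreforce-test-")
  dir.create(d)
  d
}

# A flat generating profile on [0, 1] at the simulation temperature.
flat_pmf <- function() pmf_spec(seq(0, 1, 0.005), rep(0, 201))

# Sigmoid profile whose plateau sits 65 kJ/mol above the flat-state
# minimum, i.e. whose pore_free_energy() functional is 65.0 by design.
pmf_65 <- function() pmf_sigmoid(dg_pore = 66.128)

# Snapshot with exactly one polar atom in each of the default 30 slices of
# the chain-coordinate cylinder, at lateral position (cx, cy).
one_atom_per_slice_snapshot <- function(cx = 3, cy = 3, box = c(6, 6, 4)) {
  z <- -1.5 + 0.05 + 0.1 * (0:29)
  membrane_snapshot(
    data.frame(x = cx, y = cy, z = z, species = "water_o"),
    box = box, periodic = TRUE)
}
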