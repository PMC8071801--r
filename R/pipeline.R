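# End-to-end orchestration: a YAML (or list) config names a sequence of
# stages; each stage block mirrors the corresponding constructor arguments.
# Quantity-bearing keys carry explicit unit suffixes (radius_nm, noise_sd_N)
# to keep unit errors out of configs.

#' Run an analysis pipeline from a configuration
#'
#' Stages (run in the order given): `simulate_curves`, `analyze_curves`,
#' `fit_nucleation`, `simulate_umbrella`, `wham`, `pore_prob`,
#' `snapshot_obs`. Every stage reads its parameters from the identically
#' named config block; file-producing stages write under `output_dir`. The
#' run is deterministic for a fixed `(config, seed)`.
#'
#' @param config Path to a YAML file or an equivalent named list. Top-level
#'   keys: `stages` (character vector, may be empty), `seed` (integer),
#'   `output_dir`, plus one block per stage.
#' @param output_dir Overrides `config$output_dir` when given.
#' @param log_level One of `"info"` (one message per stage), `"quiet"`
#'   (silent) or `"debug"` (adds the stage parameter blocks).
#' @return A named list report (one entry per executed stage, plus the seed
#'   and package version), invisibly written as `report.json` in the output
#'   directory when one is set. A failing stage aborts with an error naming
#'   the stage.
#' @export
run_pipeline <- function(config, output_dir = NULL,
                         log_level = c("info", "quiet", "debug")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  log_level <- match.arg(log_level)
  stages <- config$stages
  if (is.null(stages)) stages <- character(0)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  out_dir <- if (!is.null(output_dir)) output_dir else config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  report <- list(seed = seed,
                 package_version = as.character(utils::packageVersion("poreforce")))
  state <- new.env(parent = emptyenv())
  for (st in stages) {
    if (log_level != "quiet") message(sprintf("[poreforce] stage %s", st))
    if (log_level == "debug")
      message(sprintf("[poreforce]   params: %s",
                      jsonlite::toJSON(config[[st]], auto_unbox = TRUE)))
    handler <- switch(st,
                      simulate_curves   = .stage_simulate_curves,
                      analyze_curves    = .stage_analyze_curves,
                      fit_nucleation    = .stage_fit_nucleation,
                      simulate_umbrella = .stage_simulate_umbrella,
                      wham              = .stage_wham,
                      pore_prob         = .stage_pore_prob,
                      snapshot_obs      = .stage_snapshot_obs,
                      .stopf("unknown pipeline stage '%s'", st))
    res <- tryCatch(handler(config[[st]], seed, out_dir, state),
                    error = function(e)
                      stop(structure(class = c("pipeline_error", "error",
                                               "condition"),
                                     list(message = sprintf("stage '%s' failed: %s",
                                                            st, conditionMessage(e)),
                                          call = NULL))))
    report[[st]] <- res
  }
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  invisible(report)
}

#' @keywords internal
.params_from_block <- function(b) {
  nucleation_params(
    line_tension = b$line_tension_N %||% 6.93e-12,
    spreading_pressure = b$spreading_pressure_Nm %||% 9.49e-3,
    tip_radius = (b$radius_nm %||% 20) * 1e-9,
    spring_constant = b$spring_Nm %||% 0.060,
    velocity = b$velocity_ms %||% 1e-6,
    attempt_freq = b$attempt_hz %||% 3000,
    temperature = b$temperature_K %||% 298)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.stage_simulate_curves <- function(b, seed, out_dir, state) {
  p <- .params_from_block(b)
  spec <- curve_synth_spec(p,
                           contact_stiffness = b$contact_stiffness_Nm %||% 1.0,
                           membrane_thickness_apparent = b$thickness_nm %||% 4,
                           noise_sd = b$noise_sd_N %||% 3e-11,
                           sampling_step = b$sampling_step_nm %||% 0.05,
                           approach_range = b$approach_range_nm %||% 400)
  n <- b$n_curves %||% 50
  curves <- lapply(seq_len(n), function(i)
    generate_force_curve(spec, seed = seed + i))
  state$curves <- curves
  if (!is.null(out_dir))
    write_force_curves(curves, file.path(out_dir, "curves"))
  list(n_curves = n, seed = seed)
}

#' @keywords internal
.stage_analyze_curves <- function(b, seed, out_dir, state) {
  curves <- if (!is.null(b$input_dir)) read_force_curves(b$input_dir)
            else state$curves
  if (is.null(curves)) .stopf("no curves: give 'input_dir' or run simulate_curves")
  sample <- extract_yield_forces(curves, condition = b$condition %||% "run")
  state$yield <- sample
  bx <- boxplot_stats(sample)
  if (!is.null(out_dir)) {
    utils::write.table(data.frame(yield_force_nN = sample$forces),
                       file.path(out_dir, "yield_forces.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(seed = seed, ecdf = ecdf_table(sample),
                              boxplot = bx),
                         file.path(out_dir, "yield_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(seed = seed, n = length(sample$forces),
       median_nN = stats::median(sample$forces),
       boxplot = bx[c("median", "q1", "q3")])
}

#' @keywords internal
.stage_fit_nucleation <- function(b, seed, out_dir, state) {
  sample <- if (!is.null(b$forces_tsv)) {
    yield_force_sample(utils::read.delim(b$forces_tsv)[[1]])
  } else state$yield
  if (is.null(sample)) .stopf("no yield forces: give 'forces_tsv' or run analyze_curves")
  p <- .params_from_block(b)
  ft <- fit_nucleation(sample, p, method = b$method %||% "mle")
  res <- list(seed = seed,
              line_tension_1e3_nN = ft$line_tension * 1e12,
              spreading_pressure_1e3_Nm = ft$spreading_pressure * 1e3,
              line_tension_N = ft$line_tension,
              spreading_pressure_Nm = ft$spreading_pressure,
              se = as.list(ft$se), method = ft$method,
              converged = ft$converged, n = ft$n)
  if (!is.null(out_dir))
    jsonlite::write_json(res, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  res
}

#' @keywords internal
.stage_simulate_umbrella <- function(b, seed, out_dir, state) {
  pmf <- pmf_sigmoid(dg_pore = b$dg_pore_kJmol %||% 65,
                     temperature = b$temperature_K %||% 323)
  ds <- generate_umbrella_dataset(pmf, n_per_window = b$n_per_window %||% 2000,
                                  seed = seed)
  state$umbrella <- ds
  state$umbrella_truth <- pmf
  if (!is.null(out_dir))
    write_umbrella_dataset(ds, file.path(out_dir, "umbrella"))
  list(seed = seed, n_windows = length(ds$windows),
       n_per_window = length(ds$windows[[1]]$samples))
}

#' @keywords internal
.stage_wham <- function(b, seed, out_dir, state) {
  ds <- if (!is.null(b$meta_file))
    read_umbrella_dataset(b$meta_file,
                          equilibration_fraction = b$equilibration_fraction %||% 0)
  else state$umbrella
  if (is.null(ds)) .stopf("no umbrella data: give 'meta_file' or run simulate_umbrella")
  prof <- bayesian_bootstrap_pmf(ds, rounds = b$bootstrap_rounds %||% 50,
                                 seed = seed, n_bins = b$n_bins %||% 200)
  state$pmf <- prof
  dg <- pore_free_energy(prof)
  if (!is.null(out_dir)) write_pmf(prof, file.path(out_dir, "pmf.tsv"))
  list(seed = seed, dg_pore_kJmol = dg$value, dg_pore_err_kJmol = dg$err)
}

#' @keywords internal
.stage_pore_prob <- function(b, seed, out_dir, state) {
  dg <- b$dg_pore_kJmol %||%
    (if (!is.null(state$pmf)) pore_free_energy(state$pmf)$value else
       .stopf("no 'dg_pore_kJmol' given and no PMF computed"))
  temp <- b$temperature_K %||% 300
  a_sim <- b$area_sim_nm2 %||% 45
  rows <- lapply(b$geometries, function(g) {
    area <- switch(g$type,
                   sphere = sphere_area(g$radius_nm),
                   guv = sphere_area(g$radius_nm),
                   disc = disc_area(g$diameter_nm),
                   .stopf("unknown geometry type '%s'", g$type))
    dge <- area_scaled_dg(dg, area, a_sim, temp)
    list(label = g$label %||% g$type, area_nm2 = area,
         dg_exp_kJmol = dge, p_open = pore_probability(dge, temp))
  })
  res <- list(seed = seed, dg_pore_kJmol = dg, temperature_K = temp,
              table = rows)
  if (!is.null(out_dir))
    jsonlite::write_json(res, file.path(out_dir, "pore_probability.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  res
}

#' @keywords internal
.stage_snapshot_obs <- function(b, seed, out_dir, state) {
  spec <- snapshot_spec(n_lipids_per_leaflet = b$n_lipids_per_leaflet %||% 64,
                        box = unlist(b$box_nm) %||% c(6.4, 6.4, 7.0),
                        leaflet_z = b$leaflet_z_nm %||% 1.9,
                        pore_radius = b$pore_radius_nm,
                        water_margin = b$water_margin_nm %||% 0.8)
  sn <- generate_membrane_snapshot(spec, seed = seed)
  res <- list(seed = seed,
              thickness_nm = membrane_thickness(sn),
              area_per_lipid_nm2 = area_per_lipid(sn),
              chain_coordinate = chain_coordinate(sn))
  if (!is.null(out_dir)) {
    write_snapshot_csv(sn, file.path(out_dir, "snapshot.csv"))
    dm <- cylindrical_density(sn, species = "water_o")
    write_density_map(dm, file.path(out_dir, "water_density.tsv"))
  }
  res
}
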