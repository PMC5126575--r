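# End-to-end orchestration: each pipeline entry point runs one stage on a
# scenario, writes its output files plus a run manifest, and returns the
# paths. A thin command-line wrapper over these functions ships in
# inst/cli/chainheat.R.

#' Write a run manifest
#'
#' Records command, scenario name, seed, output directory, package version
#' and timestamp next to every output set, so a run can be reproduced
#' bit-identically for the deterministic stages.
#'
#' @param command Stage name.
#' @param scenario Scenario name or config path.
#' @param seed Integer seed used.
#' @param out_dir Output directory.
#' @return Path of the written `manifest.json`, invisibly.
#' @export
write_run_manifest <- function(command, scenario, seed, out_dir) {
  manifest <- list(
    command = command, scenario = scenario, seed = seed,
    output_dir = normalizePath(out_dir),
    package_version = as.character(utils::packageVersion("chainheat")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

resolve_scenario <- function(scenario) {
  if (inherits(scenario, "scenario_preset")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1L) {
    if (file.exists(scenario)) return(read_scenario(scenario))
    return(make_preset(scenario))
  }
  stop("scenario must be a preset object, preset name or YAML config path")
}

#' Run a chain-formation simulation and write its outputs
#'
#' Wraps [run_simulation()]: writes `trajectory.xyz`, `trajectory.csv`,
#' `statistics.csv` and `manifest.json` into `out_dir`.
#'
#' @param scenario A `scenario_preset`, preset name, or YAML config path.
#' @param out_dir Output directory (created if absent).
#' @param seed Optional seed override.
#' @param total_time Optional simulated-duration override in s.
#' @param n_particles Optional particle-count override.
#' @return The `chain_simulation` object, invisibly, with attribute `files`.
#' @export
simulate_chains <- function(scenario, out_dir, seed = NULL, total_time = NULL,
                            n_particles = NULL) {
  sc <- resolve_scenario(scenario)
  cfg <- sc$sim
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(total_time)) cfg$total_time <- total_time
  if (!is.null(n_particles)) cfg$N <- as.integer(n_particles)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- run_simulation(cfg, sc$particle, sc$environment)
  files <- c(xyz = file.path(out_dir, "trajectory.xyz"),
             csv = file.path(out_dir, "trajectory.csv"),
             stats = file.path(out_dir, "statistics.csv"))
  write_xyz(sim$trajectory, files["xyz"])
  write_trajectory_csv(sim$trajectory, files["csv"])
  write_statistics_csv(sim$statistics, files["stats"])
  write_run_manifest("simulate-chains", sc$name, cfg$seed, out_dir)
  attr(sim, "files") <- files
  invisible(sim)
}

#' Predict the chain/random loss report and write it
#'
#' Wraps [compare_configurations()]: evaluates the Stoner-Wohlfarth loss
#' model for the scenario's particle/field and writes `loss_report.csv`
#' (columns label, alpha, Hc_Am, A_v_Jm3, A_m_Jkg, f_Hz, SLP_Wg plus the
#' chain/random `slp_ratio`) and a manifest.
#'
#' @inheritParams simulate_chains
#' @param Ms_chain,Ms_random Minor-loop magnetizations in A m^2/kg.
#' @param hc_mode Passed to [compare_configurations()].
#' @return The report data frame, invisibly, with attribute `files`.
#' @export
predict_slp_report <- function(scenario, out_dir, Ms_chain = 18,
                               Ms_random = 8, hc_mode = "shared") {
  sc <- resolve_scenario(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- compare_configurations(sc$particle, sc$environment, sc$field,
                                Ms_chain = Ms_chain, Ms_random = Ms_random,
                                hc_mode = hc_mode)
  out <- rep
  out$slp_ratio <- attr(rep, "slp_ratio")
  path <- file.path(out_dir, "loss_report.csv")
  write_loss_report(out, path)
  write_run_manifest("predict-slp", sc$name, NA_integer_, out_dir)
  attr(rep, "files") <- c(report = path)
  invisible(rep)
}

#' Fit SLP from trace files listed in a metadata table
#'
#' Reads each trace CSV named in the metadata, runs [slp_batch()] and
#' writes `slp_results.csv` and `slp_ratios.csv`.
#'
#' @param metadata_csv Path to a metadata CSV with columns `trace_path`,
#'   `configuration`, `concentration_mg_ml`, `frequency_kHz`, `c_J_kgK`,
#'   `m_f_kg`, `m_MNPs_kg`.
#' @param out_dir Output directory.
#' @param window Fit window in s.
#' @return The `slp_batch` result, invisibly, with attribute `files`.
#' @export
fit_slp_files <- function(metadata_csv, out_dir, window = 30) {
  md <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  if (nrow(md) > 0L && !"trace_path" %in% names(md))
    stop("metadata must have a trace_path column")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traces <- list()
  if (nrow(md) > 0L) {
    for (tp in unique(md$trace_path)) {
      traces[[tp]] <- tryCatch(suppressWarnings(read_heating_curve(tp)),
                               error = function(e) NULL)
    }
    traces <- Filter(Negate(is.null), traces)
    md$trace <- md$trace_path
  } else {
    md$trace <- character(0)
  }
  batch <- slp_batch(traces, md, window = window)
  files <- c(results = file.path(out_dir, "slp_results.csv"),
             ratios = file.path(out_dir, "slp_ratios.csv"))
  utils::write.csv(batch$results, files["results"], row.names = FALSE)
  utils::write.csv(batch$ratios, files["ratios"], row.names = FALSE)
  write_run_manifest("fit-slp", metadata_csv, NA_integer_, out_dir)
  attr(batch, "files") <- files
  invisible(batch)
}

#' Simulate heating cycles for a scenario and write them
#'
#' Full forward path: loss model -> heat sources -> lumped chain and random
#' heating/cooling traces written as CSV.
#'
#' @inheritParams simulate_chains
#' @param t_heat,t_cool Phase durations in s.
#' @return Named list of curves, invisibly, with attribute `files`.
#' @export
simulate_heating <- function(scenario, out_dir, t_heat = 120, t_cool = 120) {
  sc <- resolve_scenario(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- compare_configurations(sc$particle, sc$environment, sc$field)
  curves <- synthesize_cycle(rep, sc$thermal, sc$field, sc$particle,
                             concentration = sc$concentration_mg_ml,
                             t_heat = t_heat, t_cool = t_cool)
  files <- vapply(names(curves), function(nm) {
    path <- file.path(out_dir, paste0("curve_", nm, ".csv"))
    write_heating_curve(curves[[nm]], path)
    path
  }, character(1))
  write_run_manifest("simulate-heating", sc$name, NA_integer_, out_dir)
  attr(curves, "files") <- files
  invisible(curves)
}
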