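# Scenario configuration: YAML files with defaults, validation, presets and
# a runner that executes the timeseries / bifurcation / sweep / threshold
# commands and writes their outputs.

default_config <- function() {
  list(
    scenario = "default",
    strategy = "lytic",
    params = list(x = 0.0206, y1 = 7.5, y2 = 4, N_H = 1, i_norm = 5.23,
                  c = 3.14e-4, n = 0.02, s_max = 0.33, d = 0.0866,
                  D = 1 / 24, N0 = 2, SH = 4, r = 0.5, H = 1,
                  s_switch = 0.0033, a = 0, T = 720, shunt_enabled = TRUE),
    initial_state = list(B1 = 0.83, B2 = 0.83, I1 = 0.17, I2 = 0.17,
                         P1 = 3.1e-4, P2 = 3.1e-4, N = NA_real_),
    simulation = list(t_end = 43800, output_step = 1,
                      transient_fraction = 0.8,
                      rel_tol = 1e-8, abs_tol = 1e-8),
    analysis = list(
      extinction_threshold = 1e-6,
      N0_grid = list(from = 0.6, to = 30, length = 60L, log = FALSE),
      fluctuating = FALSE, bif_a = 0.5, bif_T_h = 168,
      sweep_axis = "amplitude",
      axis_grid = list(from = 0, to = 0.99, length = 25L, log = FALSE),
      fixed_T_h = 720, fixed_a = 0.9,
      component = "B1", bracket = c(5, 30), tolerance = 0.05)
  )
}

GRID_RANGES <- list(N0 = c(0.6, 30), amplitude = c(0, 0.99),
                    period = c(24, 8760))

#' Expand a grid specification into a numeric vector
#'
#' Grids in scenario configs are written as
#' \code{list(from, to, length, log)}; \code{log = TRUE} spaces the points
#' logarithmically (used for the period axis).
#'
#' @param g Grid specification list.
#' @return Numeric vector of grid points.
#' @examples
#' expand_grid_spec(list(from = 1, to = 100, length = 3, log = TRUE))
#' @export
expand_grid_spec <- function(g) {
  stopifnot(is.list(g), all(c("from", "to", "length") %in% names(g)))
  if (isTRUE(g$log)) exp(seq(log(g$from), log(g$to), length.out = g$length))
  else seq(g$from, g$to, length.out = g$length)
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    if (!key %in% names(base))
      stop("unknown config key: ", paste0(path, key), call. = FALSE)
    if (is.list(base[[key]]) && !is.null(names(base[[key]])) &&
        key != "bracket")
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  paste0(path, key, "."))
    else
      base[[key]] <- override[[key]]
  }
  base
}

coerce_config_types <- function(cfg) {
  num <- function(v) if (is.null(v)) v else as.numeric(v)
  cfg$params <- c(lapply(cfg$params[setdiff(names(cfg$params),
                                            "shunt_enabled")], num),
                  list(shunt_enabled = isTRUE(cfg$params$shunt_enabled)))
  cfg$initial_state <- lapply(cfg$initial_state, num)
  cfg$simulation <- lapply(cfg$simulation, num)
  for (g in c("N0_grid", "axis_grid")) {
    cfg$analysis[[g]]$from <- num(cfg$analysis[[g]]$from)
    cfg$analysis[[g]]$to <- num(cfg$analysis[[g]]$to)
    cfg$analysis[[g]]$length <- as.integer(cfg$analysis[[g]]$length)
    cfg$analysis[[g]]$log <- isTRUE(cfg$analysis[[g]]$log)
  }
  for (f in c("extinction_threshold", "bif_a", "bif_T_h", "fixed_T_h",
              "fixed_a", "tolerance"))
    cfg$analysis[[f]] <- num(cfg$analysis[[f]])
  cfg$analysis$bracket <- num(cfg$analysis$bracket)
  cfg$analysis$fluctuating <- isTRUE(cfg$analysis$fluctuating)
  cfg
}

#' Load a scenario configuration
#'
#' Reads a YAML file of overrides, merges it over the full default
#' configuration (reference parameters, initial state, simulation and
#' analysis settings) and validates the result. Unknown keys are rejected
#' with the offending key path; parameter constraints (amplitude below 1,
#' positive rates, switch rate below the maximum lysis rate) are enforced,
#' and grids must stay inside the reference ranges — supply in [0.6, 30],
#' amplitude in [0, 0.99], period in [24, 8760] h — unless
#' \code{allow_extrapolation} is set. An unset initial nutrient density
#' resolves to the supply concentration \code{N0}.
#'
#' @param path Path to a YAML override file (an empty file yields the
#'   defaults).
#' @param allow_extrapolation Permit grids outside the reference ranges.
#' @return An object of class \code{scenario_config} (a nested list).
#' @examples
#' cfg <- load_config(preset_path("fig3_ptl"))
#' cfg$strategy
#' @export
load_config <- function(path, allow_extrapolation = FALSE) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  override <- yaml::read_yaml(path)
  if (is.null(override)) override <- list()
  cfg <- coerce_config_types(merge_config(default_config(), override))
  validate_config(cfg, allow_extrapolation)
  structure(cfg, class = "scenario_config")
}

validate_config <- function(cfg, allow_extrapolation = FALSE) {
  cfg$strategy <- match.arg(cfg$strategy, PHAGE_STRATEGIES)
  do.call(phage_params, cfg$params)  # runs all parameter invariants
  init <- cfg$initial_state
  if (is.na(init$N)) init$N <- cfg$params$N0
  do.call(phage_state, init)
  sim <- cfg$simulation
  if (sim$t_end <= 0 || sim$output_step <= 0 ||
      sim$transient_fraction < 0 || sim$transient_fraction >= 1 ||
      sim$rel_tol <= 0 || sim$abs_tol <= 0)
    stop("invalid simulation settings", call. = FALSE)
  an <- cfg$analysis
  if (!an$sweep_axis %in% c("amplitude", "period"))
    stop("analysis.sweep_axis must be 'amplitude' or 'period'",
         call. = FALSE)
  if (!allow_extrapolation) {
    # epsilon slack: log-spaced grid endpoints reproduce the range bounds
    # only to floating-point accuracy
    check_range <- function(v, range, what)
      if (min(v) < range[1] - 1e-9 * max(1, abs(range[1])) ||
          max(v) > range[2] + 1e-9 * abs(range[2]))
        stop(what, " grid outside the reference range [", range[1], ", ",
             range[2], "]; use allow_extrapolation to override",
             call. = FALSE)
    check_range(expand_grid_spec(an$N0_grid), GRID_RANGES$N0,
                "analysis.N0_grid")
    check_range(expand_grid_spec(an$axis_grid), GRID_RANGES[[an$sweep_axis]],
                paste0("analysis.axis_grid (", an$sweep_axis, ")"))
  }
  invisible(cfg)
}

#' Save a scenario configuration
#'
#' Writes the fully resolved configuration as YAML; loading the written file
#' reproduces the configuration exactly (round trip).
#'
#' @param cfg A \code{scenario_config}.
#' @param path Output YAML path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  # doubles are emitted verbatim at 17 significant digits so that
  # load -> save -> load is an exact identity
  num_handler <- function(x) {
    s <- vapply(x, function(v)
      if (is.na(v)) ".na.real" else format(v, digits = 17, trim = TRUE),
      character(1))
    if (length(s) == 1L) structure(s, class = "verbatim")
    else lapply(s, structure, class = "verbatim")
  }
  yaml::write_yaml(unclass(cfg), path,
                   handlers = list(logical = yaml::verbatim_logical,
                                   numeric = num_handler))
  invisible(path)
}

#' Bundled scenario presets
#'
#' The package ships preset configurations for its reference scenarios:
#' the four \code{fig3_*} time-series runs at N0 = 2, the \code{fig4_*}
#' constant and fluctuating (a = 0.5, T = 7 d) bifurcation scans, the
#' \code{fig5_*} amplitude and period sweeps, the \code{fig6_*} low/high
#' growth-rate period sweeps, the \code{s3_}/\code{s4_} switching-point and
#' \code{s5_}/\code{s6_} lysis-law sensitivity scans, and the
#' \code{s7_shunt_*} viral-shunt comparison.
#'
#' @return \code{list_presets}: character vector of preset names.
#' @examples
#' list_presets()
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "phagestrat")
  sort(tools::file_path_sans_ext(list.files(dir, pattern = "\\.yml$")))
}

#' @rdname list_presets
#' @param name Preset name (one of \code{list_presets()}).
#' @return \code{preset_path}: path to the bundled YAML file.
#' @export
preset_path <- function(name) {
  p <- system.file("extdata", "presets", paste0(name, ".yml"),
                   package = "phagestrat")
  if (p == "")
    stop("unknown preset: ", name, " (see list_presets())", call. = FALSE)
  p
}

config_to_spec <- function(cfg) {
  params <- do.call(phage_params, cfg$params)
  init <- cfg$initial_state
  if (is.na(init$N)) init$N <- params$N0
  sim <- cfg$simulation
  simulation_spec(cfg$strategy, params,
                  initial_state = do.call(phage_state, init),
                  t_end = sim$t_end, output_step = sim$output_step,
                  transient_fraction = sim$transient_fraction,
                  rel_tol = sim$rel_tol, abs_tol = sim$abs_tol)
}

#' Execute a scenario command and write its outputs
#'
#' Runs one of the four analysis commands for a scenario configuration and
#' writes the results plus a \code{manifest.json} run record (resolved
#' configuration, command, wall time, per-point integration failures) into
#' the output directory. Outputs are deterministic: repeated invocations
#' produce byte-identical files.
#'
#' \describe{
#'   \item{timeseries}{\code{trajectory.csv} (normalized) and
#'     \code{trajectory_particles_per_ml.csv}.}
#'   \item{bifurcation}{\code{bifurcation.csv} (long-format extrema) and
#'     \code{bifurcation_codes.csv} (N0, persistence code, survival flags).}
#'   \item{sweep}{\code{sweep.tsv} (code matrix) and
#'     \code{sweep_flags.csv}.}
#'   \item{threshold}{\code{threshold.json} with the bisected critical N0.}
#' }
#'
#' @param cfg A \code{scenario_config} (see \code{\link{load_config}}).
#' @param command One of \code{"timeseries"}, \code{"bifurcation"},
#'   \code{"sweep"}, \code{"threshold"}.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Named list of the result objects, invisibly.
#' @export
run_scenario <- function(cfg, command = c("timeseries", "bifurcation",
                                          "sweep", "threshold"),
                         out_dir = ".", quiet = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[phagestrat] ", ...)
  t0 <- proc.time()[3]
  say("scenario '", cfg$scenario, "' (", cfg$strategy, "), command: ",
      command)

  params <- do.call(phage_params, cfg$params)
  an <- cfg$analysis
  sim <- cfg$simulation
  out <- list()

  if (command == "timeseries") {
    traj <- run_simulation(config_to_spec(cfg))
    write_trajectory(traj, file.path(out_dir, "trajectory.csv"),
                     denormalized = TRUE)
    out$trajectory <- traj
    out$persistence <- classify_persistence(traj, an$extinction_threshold)
    say("persistence code ", out$persistence$code)
  } else if (command == "bifurcation") {
    bd <- bifurcation_scan(cfg$strategy, params,
                           N0_grid = expand_grid_spec(an$N0_grid),
                           fluctuating = an$fluctuating,
                           a = an$bif_a, T_h = an$bif_T_h,
                           extinction_threshold = an$extinction_threshold,
                           t_end = sim$t_end, output_step = sim$output_step,
                           transient_fraction = sim$transient_fraction,
                           rel_tol = sim$rel_tol, abs_tol = sim$abs_tol)
    write_bifurcation(bd, file.path(out_dir, "bifurcation.csv"))
    codes <- data.frame(N0 = bd$N0, code = bd$codes, bd$survived,
                        error = bd$errors)
    utils::write.csv(codes, file.path(out_dir, "bifurcation_codes.csv"),
                     row.names = FALSE)
    nfail <- sum(nzchar(bd$errors))
    if (nfail) say(nfail, " grid point(s) failed to integrate")
    out$bifurcation <- bd
  } else if (command == "sweep") {
    sw <- sweep_2d(cfg$strategy, params, axis = an$sweep_axis,
                   axis_grid = expand_grid_spec(an$axis_grid),
                   N0_grid = expand_grid_spec(an$N0_grid),
                   fixed_T_h = an$fixed_T_h, fixed_a = an$fixed_a,
                   extinction_threshold = an$extinction_threshold,
                   t_end = sim$t_end, output_step = sim$output_step,
                   transient_fraction = sim$transient_fraction,
                   rel_tol = sim$rel_tol, abs_tol = sim$abs_tol)
    write_sweep(sw, file.path(out_dir, "sweep.tsv"))
    nfail <- sum(nzchar(sw$errors))
    if (nfail) say(nfail, " sweep cell(s) failed to integrate")
    out$sweep <- sw
  } else {
    crit <- find_critical_N0(cfg$strategy, params,
                             component = an$component,
                             bracket = an$bracket,
                             tolerance = an$tolerance,
                             extinction_threshold = an$extinction_threshold,
                             t_end = sim$t_end,
                             output_step = sim$output_step,
                             transient_fraction = sim$transient_fraction,
                             rel_tol = sim$rel_tol, abs_tol = sim$abs_tol)
    jsonlite::write_json(list(component = an$component, critical_N0 = crit,
                              bracket = an$bracket,
                              tolerance = an$tolerance),
                         file.path(out_dir, "threshold.json"),
                         auto_unbox = TRUE, digits = NA)
    say("critical N0 for ", an$component, ": ", signif(crit, 6))
    out$critical_N0 <- crit
  }

  manifest <- list(scenario = cfg$scenario, command = command,
                   config = unclass(cfg),
                   wall_time_s = round(proc.time()[3] - t0, 3))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in ", manifest$wall_time_s, " s; outputs in ", out_dir)
  invisible(out)
}
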