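#' Default run configuration
#'
#' The full set of overridable settings: every [kinetic_params()] field
#' plus the solver settings (`grid_nodes`, `grid_spacing`, `dt`, `theta`,
#' `record_every_s`, `well_volume_ul`). Writing this list out (see
#' [write_default_config()]) documents the exact defaults a run used.
#'
#' @return a named list.
#' @export
default_config <- function() {
  c(unclass(kinetic_params()),
    list(grid_nodes = 300, grid_spacing = "log", dt = 1, theta = 1,
         record_every_s = 60, well_volume_ul = 150))
}

#' Load and validate a run configuration
#'
#' Reads a flat JSON object of configuration overrides, rejects unknown
#' keys, fills in defaults, and validates the result (constraint
#' violations name the offending field). Returns the fully resolved
#' configuration together with the constructed [kinetic_params()].
#'
#' @param path path to a JSON configuration file.
#' @return a list with elements `config` (the resolved flat list) and
#'   `params` (the validated `kinetic_params`).
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('{"km_sucrose": 11, "grid_nodes": 150}', f)
#' cfg <- load_config(f)
#' cfg$params$km_sucrose
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(user) && is.null(names(user)))
    stop("config must be a JSON object of key: value pairs", call. = FALSE)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(user)) {
    if (is.character(defaults[[k]]) != is.character(user[[k]]))
      stop(sprintf("type mismatch for %s", k), call. = FALSE)
    if (is.numeric(defaults[[k]]) &&
        (!is.numeric(user[[k]]) || length(user[[k]]) != 1))
      stop(sprintf("type mismatch for %s: expected a single number", k),
           call. = FALSE)
  }
  cfg <- modifyList(defaults, user)
  kp_fields <- names(unclass(kinetic_params()))
  params <- do.call(kinetic_params, cfg[kp_fields])
  if (cfg$grid_nodes < 10) stop("grid_nodes must be >= 10", call. = FALSE)
  if (cfg$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (cfg$theta < 0.5 || cfg$theta > 1)
    stop("theta must lie in [0.5, 1]", call. = FALSE)
  if (cfg$well_volume_ul <= 0)
    stop("well_volume_ul must be positive", call. = FALSE)
  list(config = cfg, params = params)
}

#' Write the default configuration to a JSON file
#'
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_default_config <- function(path) {
  jsonlite::write_json(default_config(), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce an output file: the command
#' name, the full parameter set, the seed, a timestamp and the package
#' version.
#'
#' @param path output path for the JSON manifest.
#' @param command short name of the operation that produced the output.
#' @param settings named list of all parameters of the run.
#' @param seed the seed used (or `NA` for deterministic runs).
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, command, settings, seed = NA) {
  manifest <- list(command = command, settings = settings, seed = seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   package = "clumpshare",
                   version = as.character(packageVersion("clumpshare")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read back a run manifest
#' @param path path to a manifest written by [write_run_manifest()].
#' @return the manifest list.
#' @export
read_run_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a simulation result to CSV files with a manifest
#'
#' Writes the recorded timeseries (`time_s`, `intake_molecules_per_s`,
#' `wall_sucrose_mM`, `wall_glucose_mM`, `induction`), the final radial
#' profiles (`radius_um`, `sucrose_mM`, `glucose_mM`) and a JSON sidecar
#' manifest holding every parameter of the run.
#'
#' @param result a [run_simulation()] result.
#' @param prefix output path prefix; files `<prefix>_timeseries.csv`,
#'   `<prefix>_profile.csv` and `<prefix>_manifest.json` are written.
#' @return the three paths, invisibly.
#' @export
save_run_result <- function(result, prefix) {
  stopifnot(inherits(result, "run_result"))
  paths <- paste0(prefix, c("_timeseries.csv", "_profile.csv",
                            "_manifest.json"))
  write.csv(result$timeseries, paths[1], row.names = FALSE)
  write.csv(result$final_profiles, paths[2], row.names = FALSE)
  geom <- result$geometry
  settings <- c(unclass(result$params),
                list(scenario = geom$scenario, n_cells = geom$n_cells,
                     well_volume_ul = geom$well_volume_ul,
                     grid_nodes = geom$grid_nodes,
                     grid_spacing = geom$grid_spacing,
                     sucrose_mM = result$sucrose_mM,
                     duration_h = result$duration_h, dt = result$dt,
                     theta = result$theta, mode = result$mode,
                     induction0 = result$induction0,
                     decay = result$decay))
  write_run_manifest(paths[3], "simulate", settings)
  invisible(paths)
}
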