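#' Default run configuration
#'
#' Every tunable of a run in one structured list: plate format, tube and
#' flow specs, transition timing, carryover model, generator presets and
#' the seed. All defaults are the documented working values of the
#' delivery system.
#'
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    plate_format = "96-medium",
    tube = list(length_cm = 22, inner_diameter_um = 250),
    flow = list(flowrate_ul_s = 2, diffusivity_m2_s = 4.25e-10),
    timing = unclass(timing_profile()),
    carryover = list(f = 0.0032, r = 0.1, f_sd = 4.7e-4),
    backpressure = list(reservoir_height_cm = 2, capillary_setpoint_pa = 200,
                        tolerance_pa = 20, fluid_density_kg_m3 = 1000),
    switch_threshold = 0.999,
    seed = 0,
    output_dir = "."
  ), class = "run_config")
}

#' Load and validate a run configuration from JSON
#'
#' Unknown keys (at top level or inside a known block) are rejected;
#' omitted keys take their documented defaults.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(bad) > 0) {
        stop("unknown config key(s) in '", k, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  plate_spec(cfg$plate_format)  # errors on unknown format
  stopifnot(cfg$tube$length_cm > 0, cfg$tube$inner_diameter_um > 0,
            cfg$flow$flowrate_ul_s >= 0, cfg$flow$diffusivity_m2_s > 0,
            cfg$carryover$f >= 0, cfg$carryover$f < 1,
            cfg$carryover$r > 0, cfg$carryover$r <= 1,
            cfg$switch_threshold > 0.5, cfg$switch_threshold < 1,
            is.numeric(cfg$seed))
  structure(cfg, class = "run_config")
}

#' Write a run configuration as JSON
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_objects <- function(cfg) {
  list(plate = plate_spec(cfg$plate_format),
       tube = tube_spec(cfg$tube$length_cm, cfg$tube$inner_diameter_um),
       flow = flow_spec(cfg$flow$flowrate_ul_s, cfg$flow$diffusivity_m2_s),
       profile = do.call(timing_profile, cfg$timing),
       carryover = carryover_model(cfg$carryover$f, cfg$carryover$r,
                                   cfg$carryover$f_sd),
       backpressure = do.call(backpressure_config, cfg$backpressure))
}

# polynomial rolling digest of the serialised config, for run logs
config_digest <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                      digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
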