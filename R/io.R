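# Delimited-text I/O for process traces, results and reports. One dialect
# everywhere: comma-separated, "." decimal, UTF-8, mandatory header. Files
# speak degrees C and L/min; everything in memory is SI.

#' Read / write a process trace file
#'
#' Trace files carry a header row and columns `time_s, t_gas_C, flow_L_min`
#' and optionally `t_wall_C`, sampled on a uniform grid. Units are converted
#' at this boundary (degrees C to K, L/min to m^3/s); writing then reading a
#' trace reproduces it.
#'
#' @param path File path.
#' @param spacing_tol Relative tolerance on grid irregularity (see
#'   [process_trace()]).
#' @return `read_trace()` returns a [process_trace()]; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path, spacing_tol = 0.02) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "t_gas_C", "flow_L_min")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(
      "trace file ", path, " is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    stop(
      "trace file ", path, ": time not strictly increasing at line ",
      bad[1] + 2L, # header + 1-based offset
      call. = FALSE
    )
  }
  process_trace(
    time = df$time_s,
    gas_temperature = celsius_to_kelvin(df$t_gas_C),
    flow_rate = lmin_to_m3s(df$flow_L_min),
    wall_temperature = if ("t_wall_C" %in% names(df)) celsius_to_kelvin(df$t_wall_C) else NULL,
    spacing_tol = spacing_tol
  )
}

#' @rdname read_trace
#' @param trace A [process_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "process_trace"))
  df <- data.frame(
    time_s = trace$time,
    t_gas_C = kelvin_to_celsius(trace$gas_temperature),
    flow_L_min = m3s_to_lmin(trace$flow_rate)
  )
  if (!is.null(trace$wall_temperature)) {
    df$t_wall_C <- kelvin_to_celsius(trace$wall_temperature)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation result as delimited text (plus a JSON sidecar)
#'
#' @param result A `simulation_result`.
#' @param path Output CSV path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_simulation_result <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  df <- data.frame(
    time_s = result$time,
    phase = result$phase,
    t_outer_C = kelvin_to_celsius(result$t_outer),
    t_inner_C = kelvin_to_celsius(result$t_inner),
    ice_mass_kg = result$ice_mass,
    ice_thickness_m = result$ice_thickness,
    q_watt = result$q,
    h_wm2k = result$h,
    flow_L_min = m3s_to_lmin(result$flow)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  nuc <- attr(result, "nucleation")
  side <- list(
    tcryst_s = attr(result, "tcryst"),
    chi_nuc = nuc$chi_nuc,
    rsc_m = nuc$nucleation_radius,
    nucleation_time_s = unname(attr(result, "phase_bounds")["nucleation"]),
    growth_end_time_s = unname(attr(result, "phase_bounds")["growth_end"]),
    completed = attr(result, "completed"),
    tool = "spinfreeze",
    version = as.character(utils::packageVersion("spinfreeze"))
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a flow schedule as delimited text
#'
#' The output is directly consumable by [read_trace()] when combined with a
#' gas temperature column, and by [simulate_schedule()] round trips.
#'
#' @param schedule A `flow_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "flow_schedule"))
  df <- data.frame(
    time_s = schedule$time,
    phase = schedule$phase,
    t_target_C = kelvin_to_celsius(schedule$t_target),
    q_watt = schedule$q,
    h_wm2k = schedule$h_required,
    flow_L_min = m3s_to_lmin(schedule$flow),
    clamped = schedule$clamped,
    extrapolated = schedule$extrapolated
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flow schedule written by [write_schedule()]
#'
#' @param path CSV path.
#' @param profile The [profile_spec()] the schedule was built for (stored
#'   schedules carry no profile metadata; supply the one used, or accept the
#'   defaults).
#' @return A `flow_schedule`.
#' @export
read_schedule <- function(path, profile = profile_spec()) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "phase", "t_target_C", "q_watt", "h_wm2k", "flow_L_min")
  if (!all(need %in% names(df))) {
    stop("schedule file missing required columns", call. = FALSE)
  }
  structure(
    data.frame(
      time = df$time_s, phase = df$phase,
      t_target = celsius_to_kelvin(df$t_target_C),
      q = df$q_watt, h_required = df$h_wm2k,
      flow = lmin_to_m3s(df$flow_L_min),
      clamped = if ("clamped" %in% names(df)) df$clamped else FALSE,
      extrapolated = if ("extrapolated" %in% names(df)) df$extrapolated else FALSE,
      stringsAsFactors = FALSE
    ),
    class = c("flow_schedule", "data.frame"),
    profile = profile,
    tcryst_target = profile$crystallization_duration
  )
}

# ---- flat INI-style configuration files -------------------------------------
# No YAML/INI reader ships with the pre-installed stack, so the (tiny) format
# is parsed by hand: "[section]" headers, "key = value" lines, "#" comments.

parse_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "global"
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      out[[section]][[key]] <- if (!is.na(num)) num else val
    } else {
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    }
  }
  out
}

ini_line <- function(key, val) {
  sprintf("%s = %s", key, if (is.numeric(val)) format(val, digits = 17) else as.character(val))
}

#' Read / write a spinfreeze configuration file
#'
#' A flat key-value file with sections `[vial]`, `[fill]`, `[constants]`,
#' `[settings]`, `[uncertainty]`, and optionally `[calibration]`,
#' `[thermocouple]`, `[profile]` and `[process]`. Keys are named exactly like
#' the corresponding constructor fields. Units per key: lengths m, masses kg,
#' energies SI, temperatures degrees C (converted to K at this boundary),
#' process flow rates L/min, cooling rates degrees C/min. A commented template
#' ships at `system.file("extdata", "config_template.ini", package =
#' "spinfreeze")`. Writing a configuration and reading it back reproduces it
#' field-for-field.
#'
#' @param path File path.
#' @return `read_config()` returns a list with elements `system`
#'   ([vial_system()]), `settings` ([simulation_settings()]), `uncertainty`
#'   ([uncertainty_spec()]) and, when the file carries the sections,
#'   `calibration`, `thermocouple`, `profile` and `process`
#'   (`list(gas_temperature, flow)`, SI).
#' @export
read_config <- function(path) {
  ini <- parse_ini(path)
  gets <- function(section, key, default = NULL) {
    v <- ini[[section]][[key]]
    if (is.null(v)) default else v
  }
  sys_args <- list()
  for (key in c(
    "outer_diameter", "wall_height", "inner_radius", "outer_radius",
    "vial_mass", "glass_specific_heat", "glass_conductivity"
  )) {
    v <- gets("vial", key)
    if (!is.null(v)) sys_args[[key]] <- v
  }
  v <- gets("fill", "water_mass")
  if (!is.null(v)) sys_args$water_mass <- v
  for (key in c(
    "water_specific_heat", "ice_specific_heat", "ice_conductivity",
    "latent_heat_fusion", "water_density", "ice_density"
  )) {
    v <- gets("constants", key)
    if (!is.null(v)) sys_args[[key]] <- v
  }
  v <- gets("constants", "equilibrium_temperature_C")
  if (!is.null(v)) sys_args$equilibrium_temperature <- celsius_to_kelvin(v)
  system <- do.call(vial_system, sys_args)

  set_args <- list()
  v <- gets("settings", "dt")
  if (!is.null(v)) set_args$dt <- v
  for (key in c(
    "initial_wall_temperature", "nucleation_temperature", "final_temperature"
  )) {
    v <- gets("settings", paste0(key, "_C"))
    if (!is.null(v)) set_args[[key]] <- celsius_to_kelvin(v)
  }
  v <- gets("settings", "max_steps")
  if (!is.null(v)) set_args$max_steps <- v
  v <- gets("settings", "nucleation_reference")
  if (!is.null(v)) set_args$nucleation_reference <- v
  settings <- do.call(simulation_settings, set_args)

  unc_args <- list()
  for (key in c(
    "h", "outer_diameter", "vial_mass", "water_mass", "flow_rate",
    "equilibrium_temperature", "gas_temperature", "sample_count", "distribution"
  )) {
    v <- gets("uncertainty", key)
    if (!is.null(v)) unc_args[[key]] <- v
  }
  uncertainty <- do.call(uncertainty_spec, unc_args)

  out <- list(system = system, settings = settings, uncertainty = uncertainty)
  if (!is.null(ini$calibration)) {
    out$calibration <- calibration_model(
      slope = gets("calibration", "slope"),
      intercept = gets("calibration", "intercept"),
      rmse = gets("calibration", "rmse", NA_real_),
      rmsecv = gets("calibration", "rmsecv", NA_real_),
      n_experiments = gets("calibration", "n_experiments", NA_integer_)
    )
  }
  if (!is.null(ini$thermocouple)) {
    out$thermocouple <- thermocouple_spec(
      nt_a = gets("thermocouple", "nt_a", 0.5),
      nt_b = gets("thermocouple", "nt_b", 0),
      air_velocity = gets("thermocouple", "air_velocity", 5)
    )
  }
  if (!is.null(ini$profile)) {
    out$profile <- profile_spec(
      liquid_cooling_rate = gets("profile", "liquid_cooling_rate_C_min", 20),
      crystallization_duration = gets("profile", "crystallization_duration_s", 150),
      solid_cooling_rate = gets("profile", "solid_cooling_rate_C_min", 20),
      start_temperature = celsius_to_kelvin(gets("profile", "start_temperature_C", 20)),
      nucleation_temperature = celsius_to_kelvin(gets("profile", "nucleation_temperature_C", -1)),
      final_temperature = celsius_to_kelvin(gets("profile", "final_temperature_C", -50))
    )
  }
  if (!is.null(ini$process)) {
    out$process <- list(
      gas_temperature = celsius_to_kelvin(gets("process", "gas_temperature_C", -60)),
      flow = lmin_to_m3s(gets("process", "flow_L_min", 50))
    )
  }
  out
}

#' @rdname read_config
#' @param config A configuration list as returned by [read_config()] (any of
#'   the optional elements may be absent).
#' @export
write_config <- function(config, path) {
  vs <- config$system
  st <- config$settings
  us <- config$uncertainty
  lines <- c(
    "# spinfreeze configuration (units: m, kg, SI energies, degC, L/min)",
    "[vial]",
    ini_line("outer_diameter", vs$outer_diameter),
    ini_line("wall_height", vs$wall_height),
    ini_line("inner_radius", vs$inner_radius),
    ini_line("outer_radius", vs$outer_radius),
    ini_line("vial_mass", vs$vial_mass),
    ini_line("glass_specific_heat", vs$glass_specific_heat),
    ini_line("glass_conductivity", vs$glass_conductivity),
    "[fill]",
    ini_line("water_mass", vs$water_mass),
    "[constants]",
    ini_line("water_specific_heat", vs$water_specific_heat),
    ini_line("ice_specific_heat", vs$ice_specific_heat),
    ini_line("ice_conductivity", vs$ice_conductivity),
    ini_line("latent_heat_fusion", vs$latent_heat_fusion),
    ini_line("water_density", vs$water_density),
    ini_line("ice_density", vs$ice_density),
    ini_line("equilibrium_temperature_C", kelvin_to_celsius(vs$equilibrium_temperature)),
    "[settings]",
    ini_line("dt", st$dt),
    ini_line("initial_wall_temperature_C", kelvin_to_celsius(st$initial_wall_temperature)),
    ini_line("nucleation_temperature_C", kelvin_to_celsius(st$nucleation_temperature)),
    ini_line("final_temperature_C", kelvin_to_celsius(st$final_temperature)),
    ini_line("max_steps", st$max_steps),
    ini_line("nucleation_reference", st$nucleation_reference),
    "[uncertainty]",
    ini_line("h", unname(us$half_width["h"])),
    ini_line("outer_diameter", unname(us$half_width["outer_diameter"])),
    ini_line("vial_mass", unname(us$half_width["vial_mass"])),
    ini_line("water_mass", unname(us$half_width["water_mass"])),
    ini_line("flow_rate", unname(us$half_width["flow_rate"])),
    ini_line("equilibrium_temperature", unname(us$half_width["equilibrium_temperature"])),
    ini_line("gas_temperature", unname(us$half_width["gas_temperature"])),
    ini_line("sample_count", us$sample_count),
    ini_line("distribution", us$distribution)
  )
  if (!is.null(config$calibration)) {
    cm <- config$calibration
    lines <- c(
      lines, "[calibration]",
      ini_line("slope", cm$slope), ini_line("intercept", cm$intercept),
      ini_line("rmse", cm$rmse), ini_line("rmsecv", cm$rmsecv),
      ini_line("n_experiments", cm$n_experiments)
    )
  }
  if (!is.null(config$thermocouple)) {
    tc <- config$thermocouple
    lines <- c(
      lines, "[thermocouple]",
      ini_line("nt_a", tc$nt_a), ini_line("nt_b", tc$nt_b),
      ini_line("air_velocity", tc$air_velocity)
    )
  }
  if (!is.null(config$profile)) {
    pf <- config$profile
    lines <- c(
      lines, "[profile]",
      ini_line("liquid_cooling_rate_C_min", pf$liquid_cooling_rate),
      ini_line("crystallization_duration_s", pf$crystallization_duration),
      ini_line("solid_cooling_rate_C_min", pf$solid_cooling_rate),
      ini_line("start_temperature_C", kelvin_to_celsius(pf$start_temperature)),
      ini_line("nucleation_temperature_C", kelvin_to_celsius(pf$nucleation_temperature)),
      ini_line("final_temperature_C", kelvin_to_celsius(pf$final_temperature))
    )
  }
  if (!is.null(config$process)) {
    pr <- config$process
    lines <- c(
      lines, "[process]",
      ini_line("gas_temperature_C", kelvin_to_celsius(pr$gas_temperature)),
      ini_line("flow_L_min", m3s_to_lmin(pr$flow))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Packaged verification-run summary table
#'
#' Summary statistics of ten constant-flow verification experiments on the
#' reference rig (flow rate; fitted liquid- and solid-phase cooling rates;
#' crystal-growth duration; nucleation temperatures measured at the outer
#' wall and inferred at the inner wall). Shipped as a plain-text fixture for
#' ordering/containment checks: the rig's gas temperature depends on the flow
#' rate and is not part of the table, so these values are not reproducible
#' from the simulator alone.
#'
#' @return data.frame with one row per verification run.
#' @export
verification_runs <- function() {
  utils::read.csv(
    system.file("extdata", "verification_runs.csv", package = "spinfreeze"),
    check.names = FALSE
  )
}
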