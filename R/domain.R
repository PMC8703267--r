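#' Physical description of a spin-frozen vial and its aqueous fill
#'
#' Bundles the geometry, masses and thermal constants of a rotating glass vial
#' filled with an aqueous product. During spin freezing the liquid spreads as
#' a thin annulus on the inner wall while cold gas removes heat from the
#' curved outer surface, so the exchange area is the cylindrical shell
#' `pi * outer_diameter * wall_height`. All quantities are SI (m, kg, K,
#' J, W); unit conversion happens only at the I/O boundary.
#'
#' Defaults describe a 10 mL type-I tubular glass vial filled with 3.0 mL of
#' demineralised water, together with handbook constants for borosilicate
#' glass, liquid water and ice. The nominal vial constants are a documented
#' profile (actual vials vary); every value can be overridden.
#'
#' @param outer_diameter Vial outer diameter (m). Must equal `2 * outer_radius`.
#' @param wall_height Liquid-covered (heat-exchange) height of the wall (m).
#' @param inner_radius,outer_radius Inner/outer radius of the glass wall (m).
#' @param vial_mass Mass of the empty vial (kg).
#' @param glass_specific_heat Specific heat of the glass (J/(kg K)).
#' @param glass_conductivity Thermal conductivity of the glass (W/(m K)).
#' @param water_mass Mass of the aqueous fill (kg).
#' @param water_specific_heat,ice_specific_heat Specific heats (J/(kg K)).
#' @param ice_conductivity Thermal conductivity of ice (W/(m K)), taken as a
#'   single constant (its value at 0 degrees C).
#' @param latent_heat_fusion Latent heat of fusion of water (J/kg).
#' @param water_density,ice_density Densities (kg/m^3).
#' @param equilibrium_temperature Equilibrium freezing temperature Teq (K);
#'   273.15 K for pure water.
#' @return An object of class `vial_system`.
#' @export
#' @examples
#' vs <- vial_system()
#' total_heat_capacity(vs, "liquid")
vial_system <- function(outer_diameter = 0.024,
                        wall_height = 0.060,
                        inner_radius = 0.0112,
                        outer_radius = 0.0120,
                        vial_mass = 0.0125,
                        glass_specific_heat = 830,
                        glass_conductivity = 1.1,
                        water_mass = 0.003,
                        water_specific_heat = 4186,
                        ice_specific_heat = 2108,
                        ice_conductivity = 2.22,
                        latent_heat_fusion = 3.34e5,
                        water_density = 1000,
                        ice_density = 917,
                        equilibrium_temperature = 273.15) {
  vs <- structure(
    list(
      outer_diameter = outer_diameter,
      wall_height = wall_height,
      inner_radius = inner_radius,
      outer_radius = outer_radius,
      vial_mass = vial_mass,
      glass_specific_heat = glass_specific_heat,
      glass_conductivity = glass_conductivity,
      water_mass = water_mass,
      water_specific_heat = water_specific_heat,
      ice_specific_heat = ice_specific_heat,
      ice_conductivity = ice_conductivity,
      latent_heat_fusion = latent_heat_fusion,
      water_density = water_density,
      ice_density = ice_density,
      equilibrium_temperature = equilibrium_temperature
    ),
    class = "vial_system"
  )
  validate_vial_system(vs)
}

validate_vial_system <- function(vs) {
  stopifnot(inherits(vs, "vial_system"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in names(vs)) {
    if (!num1(vs[[f]])) stop("vial_system field '", f, "' must be a finite scalar", call. = FALSE)
  }
  pos <- c(
    "outer_diameter", "wall_height", "inner_radius", "outer_radius",
    "vial_mass", "glass_specific_heat", "glass_conductivity",
    "water_specific_heat", "ice_specific_heat", "ice_conductivity",
    "latent_heat_fusion", "water_density", "ice_density",
    "equilibrium_temperature"
  )
  for (f in pos) {
    if (vs[[f]] <= 0) stop("vial_system field '", f, "' must be strictly positive", call. = FALSE)
  }
  if (vs$water_mass <= 0) {
    stop("water_mass must be strictly positive: an empty vial has no product to freeze", call. = FALSE)
  }
  if (vs$inner_radius >= vs$outer_radius) {
    stop("geometry violation: inner_radius must be smaller than outer_radius", call. = FALSE)
  }
  if (abs(vs$outer_diameter - 2 * vs$outer_radius) > 1e-12 * vs$outer_diameter) {
    stop("dimension inconsistency: outer_diameter must equal 2 * outer_radius", call. = FALSE)
  }
  if (vs$ice_density >= vs$water_density) {
    stop("ice_density must be below water_density (ice floats)", call. = FALSE)
  }
  annulus_volume <- pi * vs$inner_radius^2 * vs$wall_height
  if (vs$water_mass / vs$water_density >= annulus_volume) {
    stop(
      "fill volume (", format(vs$water_mass / vs$water_density), " m^3) does not fit in the ",
      "rotating annulus (", format(annulus_volume), " m^3): reduce water_mass or fill height",
      call. = FALSE
    )
  }
  vs
}

#' @export
print.vial_system <- function(x, ...) {
  cat("<vial_system>\n")
  cat(sprintf(
    "  glass: OD %.1f mm, wall %.2f -> %.2f mm radius, exchange height %.1f mm, %.2f g\n",
    1000 * x$outer_diameter, 1000 * x$inner_radius, 1000 * x$outer_radius,
    1000 * x$wall_height, 1000 * x$vial_mass
  ))
  cat(sprintf(
    "  fill : %.2f g water (%.2f mL), Teq %.2f K\n",
    1000 * x$water_mass, 1e6 * x$water_mass / x$water_density, x$equilibrium_temperature
  ))
  invisible(x)
}

#' Time stepping and phase-trigger settings for the freezing simulator
#'
#' @param dt Time step (s). Default 0.5 s, the logging interval of the rig the
#'   model was built for.
#' @param initial_wall_temperature Outer-wall temperature at t = 0 (K).
#'   Ambient (20 degrees C) by default.
#' @param nucleation_temperature Inner-wall temperature at which primary ice
#'   nucleation is triggered (K). Nucleation is stochastic and is an input to
#'   the model, not a prediction; the default of -1 degree C sits mid-range of
#'   the inner-wall nucleation temperatures observed on the reference rig
#'   (-2 to 0 degrees C).
#' @param final_temperature Outer-wall temperature at which solid cooling, and
#'   the simulation, ends (K). Default 223.15 K (-50 degrees C).
#' @param max_steps Hard cap on the number of Euler steps.
#' @param nucleation_reference Whether the nucleation trigger compares
#'   `nucleation_temperature` against the inner wall (default; the physically
#'   meaningful product-side temperature) or the outer wall (useful when
#'   replaying data reported as outer-wall nucleation temperatures).
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(dt = 0.5,
                                initial_wall_temperature = 293.15,
                                nucleation_temperature = 272.15,
                                final_temperature = 223.15,
                                max_steps = 100000L,
                                nucleation_reference = c("inner", "outer")) {
  nucleation_reference <- match.arg(nucleation_reference)
  st <- structure(
    list(
      dt = dt,
      initial_wall_temperature = initial_wall_temperature,
      nucleation_temperature = nucleation_temperature,
      final_temperature = final_temperature,
      max_steps = as.integer(max_steps),
      nucleation_reference = nucleation_reference
    ),
    class = "simulation_settings"
  )
  if (!is.finite(st$dt) || st$dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (st$max_steps < 1L) stop("max_steps must be >= 1", call. = FALSE)
  st
}

#' Thermocouple time-constant specification
#'
#' A bare-wire thermocouple reading a changing gas temperature lags the true
#' value; the lag error is `-Nt * dTgas/dt`, with the time constant `Nt`
#' obtained from an empirical regression in the air velocity `w`:
#' `Nt = 1 / (nt_a + nt_b * sqrt(w))`. The regression constants depend on the
#' thermocouple type and gauge. The defaults below are placeholders that give
#' `Nt = 2 s`, representative of a fine-gauge type-K couple; the constants for
#' a specific sensor must be supplied from its own characterisation.
#'
#' @param nt_a Regression constant (1/s).
#' @param nt_b Regression constant (m^-1/2 s^-1/2).
#' @param air_velocity Gas velocity at the sensor (m/s).
#' @return An object of class `thermocouple_spec`.
#' @export
thermocouple_spec <- function(nt_a = 0.5, nt_b = 0, air_velocity = 5) {
  spec <- structure(
    list(nt_a = nt_a, nt_b = nt_b, air_velocity = air_velocity),
    class = "thermocouple_spec"
  )
  denom <- spec$nt_a + spec$nt_b * sqrt(spec$air_velocity)
  if (!is.finite(denom) || denom <= 0) {
    stop("thermocouple configuration error: nt_a + nt_b*sqrt(w) must be positive and finite",
      call. = FALSE
    )
  }
  spec
}

#' Affine map from gas flow rate to heat transfer coefficient
#'
#' `h = slope * flow + intercept`, with flow in m^3/s. The packaged default
#' (`default_calibration()`) carries the regression obtained on the reference
#' spin-freezing rig: slope 71.11e3 J/(m^5 K), intercept 32.05 W/(m^2 K),
#' RMSE 4.3058 and leave-one-out RMSECV 5.6293 W/(m^2 K) over eight
#' constant-flow experiments.
#'
#' @param slope Regression slope ha (J/(m^5 K)).
#' @param intercept Regression intercept hb (W/(m^2 K)).
#' @param rmse Root-mean-square error of the fit (W/(m^2 K)).
#' @param rmsecv Leave-one-out cross-validated RMSE (W/(m^2 K)).
#' @param n_experiments Number of calibration runs behind the fit.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(slope, intercept, rmse = NA_real_,
                              rmsecv = NA_real_, n_experiments = NA_integer_) {
  cm <- structure(
    list(
      slope = slope, intercept = intercept, rmse = rmse, rmsecv = rmsecv,
      n_experiments = n_experiments
    ),
    class = "calibration_model"
  )
  if (!is.finite(cm$slope) || !is.finite(cm$intercept)) {
    stop("calibration_model slope and intercept must be finite", call. = FALSE)
  }
  if (is.finite(cm$rmse) && cm$rmse < 0) stop("rmse must be >= 0", call. = FALSE)
  if (is.finite(cm$rmsecv) && cm$rmsecv < 0) stop("rmsecv must be >= 0", call. = FALSE)
  cm
}

#' @rdname calibration_model
#' @export
default_calibration <- function() {
  calibration_model(
    slope = 71.11e3, intercept = 32.05,
    rmse = 4.3058, rmsecv = 5.6293, n_experiments = 8L
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> h = %.4g * flow + %.4g  [RMSE %.3g, RMSECV %.3g, n = %s]\n",
    x$slope, x$intercept, x$rmse, x$rmsecv, format(x$n_experiments)
  ))
  invisible(x)
}

#' Uncertainty specification for the seven uncertain model inputs
#'
#' Half-widths of uniform uncertainty ranges, one per uncertain input, in the
#' input's own SI units. The defaults reproduce the uncertainty budget of the
#' reference rig: the heat-transfer-coefficient uncertainty is the RMSE of its
#' calibration regression (applied as an additive offset to the calibration
#' prediction), vial diameter and mass come from manufacturer tolerances, fill
#' mass from pipetting accuracy, flow rate from the mass-flow-controller
#' accuracy, and both temperature half-widths (2 K) from the accuracy of the
#' infrared camera (Teq) and the gas thermocouple (Tgas).
#'
#' The default vial-mass half-width is 5e-5 kg (0.05 g, a weighing-scale
#' tolerance). A value of 5e-4 kg is sometimes quoted as a glass-vial
#' manufacturing spread, but at that level the vial mass alone would
#' contribute more than 5% of the liquid-cooling prediction variance at high
#' gas flows — incompatible with the observed dominance of h, Tgas and Teq on
#' the reference rig (see the methods vignette); it can of course still be
#' configured.
#'
#' @param h Half-width on the heat transfer coefficient (W/(m^2 K)).
#' @param outer_diameter Half-width on the vial diameter (m).
#' @param vial_mass Half-width on the vial mass (kg).
#' @param water_mass Half-width on the fill mass (kg).
#' @param flow_rate Half-width on the volumetric gas flow rate (m^3/s).
#' @param equilibrium_temperature Half-width on Teq (K).
#' @param gas_temperature Half-width on Tgas (K).
#' @param sample_count Default Monte-Carlo sample count for uncertainty
#'   propagation.
#' @param distribution Input distribution: `"uniform"` on nominal +/-
#'   half-width (default), or `"normal"` with sd = half-width / 2.
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(h = 4.3058,
                             outer_diameter = 1e-4,
                             vial_mass = 5e-5,
                             water_mass = 3e-5,
                             flow_rate = 6.67e-6,
                             equilibrium_temperature = 2,
                             gas_temperature = 2,
                             sample_count = 10000L,
                             distribution = c("uniform", "normal")) {
  distribution <- match.arg(distribution)
  us <- structure(
    list(
      half_width = c(
        h = h, outer_diameter = outer_diameter, vial_mass = vial_mass,
        water_mass = water_mass, flow_rate = flow_rate,
        equilibrium_temperature = equilibrium_temperature,
        gas_temperature = gas_temperature
      ),
      sample_count = as.integer(sample_count),
      distribution = distribution
    ),
    class = "uncertainty_spec"
  )
  if (any(!is.finite(us$half_width)) || any(us$half_width < 0)) {
    stop("all uncertainty half-widths must be finite and >= 0", call. = FALSE)
  }
  if (us$sample_count < 100L) stop("sample_count must be >= 100", call. = FALSE)
  us
}

#' Names of the seven uncertain inputs, in canonical order
#' @return Character vector of length 7.
#' @export
uncertain_parameters <- function() {
  c(
    "h", "outer_diameter", "vial_mass", "water_mass", "flow_rate",
    "equilibrium_temperature", "gas_temperature"
  )
}

#' Uniformly sampled process trace
#'
#' Container for logged (or synthesised) process time series: gas temperature,
#' volumetric gas flow rate and, optionally, the measured outer-vial-wall
#' temperature. The time grid must be strictly increasing with (near-)constant
#' spacing; series are stored in SI units (s, K, m^3/s).
#'
#' @param time Time grid (s).
#' @param gas_temperature Gas temperature per sample (K).
#' @param flow_rate Volumetric flow rate per sample (m^3/s), all >= 0.
#' @param wall_temperature Optional measured outer-wall temperature (K).
#' @param spacing_tol Relative tolerance on grid irregularity (default 2%);
#'   spacing deviations within tolerance are accepted with a warning.
#' @return An object of class `process_trace` (also a data.frame).
#' @export
process_trace <- function(time, gas_temperature, flow_rate,
                          wall_temperature = NULL, spacing_tol = 0.02) {
  n <- length(time)
  if (n < 2L) stop("process_trace needs at least 2 samples", call. = FALSE)
  if (length(gas_temperature) != n || length(flow_rate) != n) {
    stop("all process_trace series must have equal length", call. = FALSE)
  }
  if (!is.null(wall_temperature) && length(wall_temperature) != n) {
    stop("wall_temperature must match the time grid length", call. = FALSE)
  }
  dts <- diff(time)
  if (any(dts <= 0)) stop("time must be strictly increasing", call. = FALSE)
  dt <- stats::median(dts)
  rel <- abs(dts - dt) / dt
  if (any(rel > spacing_tol)) {
    stop(
      "irregular time grid: spacing deviates by more than ", 100 * spacing_tol,
      "% at sample ", which(rel > spacing_tol)[1] + 1L,
      call. = FALSE
    )
  }
  if (any(rel > 1e-9)) {
    warning("time grid has small spacing irregularities (within tolerance)", call. = FALSE)
  }
  if (any(flow_rate < 0)) stop("flow_rate must be >= 0", call. = FALSE)
  df <- data.frame(
    time = time, gas_temperature = gas_temperature, flow_rate = flow_rate
  )
  if (!is.null(wall_temperature)) df$wall_temperature <- wall_temperature
  structure(df, class = c("process_trace", "data.frame"), dt = dt)
}

#' Time step of a process trace (s)
#' @param trace A `process_trace`.
#' @return Median sample spacing (s).
#' @export
trace_dt <- function(trace) {
  attr(trace, "dt") %||% stats::median(diff(trace$time))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a (system, settings) configuration for simulation
#'
#' Re-runs all type invariants and the cross-checks tying the settings to the
#' physical system: the final temperature must lie below the equilibrium
#' temperature and the nucleation temperature must not exceed it.
#'
#' @param system A `vial_system`.
#' @param settings A `simulation_settings`.
#' @return The validated configuration, invisibly, as
#'   `list(system = system, settings = settings)`.
#' @export
validate_configuration <- function(system, settings) {
  validate_vial_system(system)
  if (!inherits(settings, "simulation_settings")) {
    stop("settings must be a simulation_settings object", call. = FALSE)
  }
  if (settings$final_temperature >= system$equilibrium_temperature) {
    stop("final_temperature must lie below the equilibrium temperature", call. = FALSE)
  }
  if (settings$nucleation_temperature > system$equilibrium_temperature) {
    stop("nucleation_temperature cannot exceed the equilibrium temperature", call. = FALSE)
  }
  invisible(list(system = system, settings = settings))
}

# Unit conversions: applied only at the I/O boundary.

#' Unit conversions used at the I/O boundary
#'
#' Internally everything is SI (K, m^3/s); files and the CLI speak degrees C
#' and L/min.
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' @rdname celsius_to_kelvin
#' @export
lmin_to_m3s <- function(x) x / 60000

#' @rdname celsius_to_kelvin
#' @export
m3s_to_lmin <- function(x) x * 60000
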