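# Shared machinery for uncertainty propagation and sensitivity analysis: map
# unit-hypercube rows to perturbed model inputs and run the simulator.

# Map an n x 7 matrix of unit-hypercube points to perturbed parameter values
# around the nominal configuration. Columns follow uncertain_parameters():
# h (additive offset on the calibration prediction), outer_diameter,
# vial_mass, water_mass, flow_rate, equilibrium_temperature (Teq),
# gas_temperature (additive offset on the gas series).
scale_to_ranges <- function(u, spec, nominal) {
  stopifnot(ncol(u) == 7L)
  hw <- spec$half_width
  centers <- c(
    0, nominal$system$outer_diameter, nominal$system$vial_mass,
    nominal$system$water_mass, nominal$flow,
    nominal$system$equilibrium_temperature, 0
  )
  out <- matrix(NA_real_, nrow(u), 7L, dimnames = list(NULL, uncertain_parameters()))
  for (j in seq_len(7L)) {
    if (spec$distribution == "uniform") {
      out[, j] <- centers[j] + (2 * u[, j] - 1) * hw[j]
    } else {
      out[, j] <- centers[j] + stats::qnorm(u[, j]) * hw[j] / 2
    }
  }
  out
}

#' Sample perturbed model inputs for uncertainty propagation
#'
#' Builds an `n x 7` matrix of perturbed inputs using Sobol low-discrepancy
#' sampling, one column per uncertain parameter (in the order of
#' [uncertain_parameters()]). The heat transfer coefficient and the gas
#' temperature are sampled as additive offsets (applied to the calibration
#' prediction and to the gas-temperature series respectively); the other five
#' columns are sampled around their nominal values. Ranges are nominal +/-
#' half-width under the default uniform distribution.
#'
#' @param spec An [uncertainty_spec()].
#' @param system Nominal [vial_system()].
#' @param flow Nominal volumetric flow rate (m^3/s).
#' @param n Number of samples (default `spec$sample_count`).
#' @param seed Optional integer seed for the Sobol digital shift.
#' @return `n x 7` numeric matrix with named columns.
#' @export
sample_uncertain_inputs <- function(spec, system, flow, n = spec$sample_count,
                                    seed = NULL) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  u <- sobol_points(n, 7L, seed = seed)
  scale_to_ranges(u, spec, list(system = system, flow = flow))
}

# Apply one row of perturbed inputs: returns the arguments for
# simulate_freezing. Teq perturbations shift the nucleation trigger with them
# (the configured supercooling degree, Teq - Tnuc, is preserved) so that the
# trigger stays physical for every sampled Teq.
perturbed_run_args <- function(row, system, settings, calibration, gas_temperature) {
  sys2 <- system
  sys2$outer_diameter <- row[["outer_diameter"]]
  sys2$outer_radius <- row[["outer_diameter"]] / 2
  sys2$vial_mass <- row[["vial_mass"]]
  sys2$water_mass <- row[["water_mass"]]
  supercooling <- system$equilibrium_temperature - settings$nucleation_temperature
  sys2$equilibrium_temperature <- row[["equilibrium_temperature"]]
  set2 <- settings
  set2$nucleation_temperature <- row[["equilibrium_temperature"]] - supercooling
  dtg <- row[["gas_temperature"]]
  gt <- if (is.numeric(gas_temperature) && length(gas_temperature) == 1L) {
    gas_temperature + dtg
  } else if (is.function(gas_temperature)) {
    function(t) gas_temperature(t) + dtg
  } else if (inherits(gas_temperature, "process_trace")) {
    g2 <- gas_temperature
    g2$gas_temperature <- g2$gas_temperature + dtg
    g2
  } else {
    stop("unsupported gas_temperature driver", call. = FALSE)
  }
  list(
    system = sys2, settings = set2, calibration = calibration,
    gas_temperature = gt, flow = row[["flow_rate"]], h_offset = row[["h"]]
  )
}

#' Propagate input uncertainty to a 95% prediction interval
#'
#' Runs one simulation per sampled input row, aligns all predicted outer-wall
#' temperature profiles on the nominal run's time grid (runs that finish early
#' are padded with their final temperature), and takes the pointwise
#' `ceiling(0.025 n)`-th and `floor(0.975 n)`-th order statistics as the lower
#' and upper prediction limits (samples 250 and 9750 at n = 10000).
#'
#' @param samples Matrix from [sample_uncertain_inputs()].
#' @param system,settings,calibration Nominal configuration.
#' @param gas_temperature Nominal gas-temperature driver (constant K,
#'   function, or [process_trace()]).
#' @param flow Nominal flow (m^3/s); only used for the nominal run (each
#'   sampled run carries its own flow column).
#' @param max_failures Maximum tolerated fraction of failed sampled runs.
#' @return An object of class `prediction_interval`: data.frame with columns
#'   `time`, `lower`, `nominal`, `upper` (K); attributes `sample_count`,
#'   `excluded` (failed runs) and `order_indices`.
#' @export
propagate_uncertainty <- function(samples, system, settings,
                                  calibration = default_calibration(),
                                  gas_temperature = 213.15,
                                  flow = lmin_to_m3s(50),
                                  max_failures = 0.01) {
  nominal <- simulate_freezing(system, settings, calibration,
    gas_temperature = gas_temperature, flow = flow
  )
  grid <- nominal$time
  ngrid <- length(grid)
  n <- nrow(samples)
  prof <- matrix(NA_real_, nrow = n, ncol = ngrid)
  failed <- integer(0)
  for (i in seq_len(n)) {
    args <- perturbed_run_args(samples[i, ], system, settings, calibration, gas_temperature)
    r <- tryCatch(
      do.call(simulate_freezing, c(args, list(max_time = grid[ngrid] + settings$dt))),
      error = function(e) NULL
    )
    if (is.null(r)) {
      failed <- c(failed, i)
      next
    }
    k <- min(nrow(r), ngrid)
    prof[i, seq_len(k)] <- r$t_outer[seq_len(k)]
    if (k < ngrid) prof[i, (k + 1L):ngrid] <- r$t_outer[nrow(r)]
  }
  if (length(failed) > max_failures * n) {
    stop(
      length(failed), " of ", n, " sampled runs failed (> ",
      100 * max_failures, "% tolerated)",
      call. = FALSE
    )
  }
  if (length(failed)) prof <- prof[-failed, , drop = FALSE]
  m <- nrow(prof)
  lo_i <- max(1L, ceiling(0.025 * m))
  hi_i <- min(m, floor(0.975 * m))
  lims <- apply(prof, 2L, function(col) {
    s <- sort.int(col, method = "quick")
    c(s[lo_i], s[hi_i])
  })
  structure(
    data.frame(
      time = grid, lower = lims[1, ], nominal = nominal$t_outer, upper = lims[2, ]
    ),
    class = c("prediction_interval", "data.frame"),
    sample_count = m,
    excluded = length(failed),
    order_indices = c(lower = lo_i, upper = hi_i)
  )
}

#' Fraction of a measured trace lying inside a prediction interval
#'
#' @param interval A `prediction_interval`.
#' @param measured A [process_trace()] with a `wall_temperature` column, or a
#'   data.frame with `time` and `wall_temperature`. If the grids differ the
#'   measurement is linearly resampled onto the interval grid (with a
#'   warning).
#' @return List with `coverage` (fraction in `[0, 1]`) and `excursions`
#'   (times at which the measurement leaves the interval).
#' @export
interval_coverage <- function(interval, measured) {
  stopifnot(inherits(interval, "prediction_interval"))
  tt <- measured$time
  y <- measured$wall_temperature
  if (is.null(y)) stop("measured trace must carry a wall_temperature series", call. = FALSE)
  keep_t <- interval$time[interval$time >= min(tt) & interval$time <= max(tt)]
  if (length(keep_t) == 0L) stop("measurement does not overlap the interval grid", call. = FALSE)
  if (length(tt) != length(keep_t) || any(abs(tt[seq_along(keep_t)] - keep_t) > 1e-9)) {
    warning("grids misaligned: resampling measurement onto the interval grid", call. = FALSE)
  }
  ym <- stats::approx(tt, y, xout = keep_t, rule = 2)$y
  sub <- interval[interval$time %in% keep_t, ]
  inside <- ym >= sub$lower & ym <= sub$upper
  list(coverage = mean(inside), excursions = keep_t[!inside])
}
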