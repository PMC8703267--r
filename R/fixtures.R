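# Synthetic fixture generation: simulator-generated process traces with
# seeded additive measurement noise, emulating the two experiment families
# run on the reference rig (constant-flow calibration runs and imposed
# cooling-profile runs). Fixtures carry a truth echo for recovery tests.

#' Fixture generation specification
#'
#' @param scenario `"constant_flow"` (one trace per flow rate) or
#'   `"imposed_profile"` (one trace following an inverted flow schedule).
#' @param flows Constant flow rates (m^3/s); defaults to the eight calibration
#'   flows of the reference rig, 20 to 69 L/min in steps of 7.
#' @param profile A [profile_spec()] (imposed-profile scenario).
#' @param gas_model `list(type = "constant", cold = <K>)` or
#'   `list(type = "warmup", cold = <K>, warm = <K>, tau = <s>)`: an
#'   exponential warm-up from `warm` to `cold` with time constant `tau`,
#'   mirroring the initially warm gas of a real run.
#' @param noise_wall,noise_gas Gaussian noise standard deviations (K) added to
#'   the simulated wall temperature and the gas temperature channel.
#' @param noise_flow_rel Relative Gaussian noise on the recorded flow channel.
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(scenario = c("constant_flow", "imposed_profile"),
                         flows = lmin_to_m3s(seq(20, 69, by = 7)),
                         profile = profile_spec(),
                         gas_model = list(type = "constant", cold = 213.15),
                         noise_wall = 2, noise_gas = 2, noise_flow_rel = 0.01,
                         seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(noise_wall >= 0, noise_gas >= 0, noise_flow_rel >= 0)
  structure(
    list(
      scenario = scenario, flows = flows, profile = profile,
      gas_model = gas_model, noise_wall = noise_wall, noise_gas = noise_gas,
      noise_flow_rel = noise_flow_rel, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

gas_driver <- function(gas_model) {
  if (gas_model$type == "constant") {
    gas_model$cold
  } else if (gas_model$type == "warmup") {
    cold <- gas_model$cold
    warm <- gas_model$warm
    tau <- gas_model$tau
    function(t) cold + (warm - cold) * exp(-t / tau)
  } else {
    stop("unknown gas model type '", gas_model$type, "'", call. = FALSE)
  }
}

#' Generate synthetic process-trace fixtures
#'
#' Runs the forward simulator under the scenario described by `spec` and emits
#' one [process_trace()] per run, with seeded additive Gaussian noise on the
#' wall-temperature, gas-temperature and flow channels. The generating
#' parameters (calibration truth, per-run crystallization duration and phase
#' boundary times) are echoed in `truth` for recovery tests.
#'
#' @param spec A [fixture_spec()].
#' @param system A [vial_system()].
#' @param settings A [simulation_settings()].
#' @param calibration The generating ("truth") [calibration_model()].
#' @return List with `traces` (list of `process_trace`), `truth` (list: `slope`,
#'   `intercept`, per-run `tcryst`, `nucleation_time`, `growth_end_time`,
#'   `flow`), and `spec`.
#' @export
generate_fixtures <- function(spec, system = vial_system(),
                              settings = simulation_settings(),
                              calibration = default_calibration()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  gm <- gas_driver(spec$gas_model)

  make_trace <- function(sim, gas_fun) {
    n <- nrow(sim)
    tgas_true <- if (is.function(gas_fun)) gas_fun(sim$time) else rep(gas_fun, n)
    process_trace(
      time = sim$time,
      gas_temperature = tgas_true + stats::rnorm(n, 0, spec$noise_gas),
      flow_rate = pmax(0, sim$flow * (1 + stats::rnorm(n, 0, spec$noise_flow_rel))),
      wall_temperature = sim$t_outer + stats::rnorm(n, 0, spec$noise_wall)
    )
  }

  if (spec$scenario == "constant_flow") {
    runs <- lapply(spec$flows, function(fl) {
      sim <- simulate_freezing(system, settings, calibration,
        gas_temperature = gm, flow = fl
      )
      list(trace = make_trace(sim, gm), sim = sim)
    })
  } else {
    sch <- flow_schedule(spec$profile, system, calibration,
      gas_temperature = gm, dt = settings$dt
    )
    sim <- simulate_schedule(sch, system, calibration, gas_temperature = gm)
    runs <- list(list(trace = make_trace(sim, gm), sim = sim))
  }

  truth <- list(
    slope = calibration$slope,
    intercept = calibration$intercept,
    seed = spec$seed,
    flow = vapply(runs, function(r) r$sim$flow[1], numeric(1)),
    tcryst = vapply(runs, function(r) attr(r$sim, "tcryst"), numeric(1)),
    nucleation_time = vapply(
      runs,
      function(r) unname(attr(r$sim, "phase_bounds")["nucleation"]), numeric(1)
    ),
    growth_end_time = vapply(
      runs,
      function(r) unname(attr(r$sim, "phase_bounds")["growth_end"]), numeric(1)
    )
  )
  list(traces = lapply(runs, `[[`, "trace"), truth = truth, spec = spec)
}

#' Write generated fixtures to a directory
#'
#' One trace CSV per run (`run_01.csv`, ...) plus `truth.json` echoing the
#' generating parameters and the seed.
#'
#' @param fixtures Output of [generate_fixtures()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(fixtures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(fixtures$traces)) {
    write_trace(fixtures$traces[[i]], file.path(dir, sprintf("run_%02d.csv", i)))
  }
  jsonlite::write_json(
    fixtures$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
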