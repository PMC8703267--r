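#' Total heat capacity of the vial-plus-contents system
#'
#' `C = cp_glass * m_vial + cp_contents * m_contents` with the contents taken
#' as all water (liquid phase) or all ice (solid phase).
#'
#' @param system A [vial_system()].
#' @param phase `"liquid"` or `"solid"`.
#' @return Heat capacity (J/K).
#' @export
total_heat_capacity <- function(system, phase = c("liquid", "solid")) {
  phase <- match.arg(phase)
  glass <- system$glass_specific_heat * system$vial_mass
  if (phase == "liquid") {
    glass + system$water_specific_heat * system$water_mass
  } else {
    glass + system$ice_specific_heat * system$water_mass
  }
}

#' One explicit-Euler cooling step
#'
#' `T_new = T_prev - Q_prev * dt / C_tot`: the sensible-cooling update used in
#' both the liquid and the solid cooling phase, with the heat flow evaluated
#' at the previous step.
#'
#' @param t_prev Temperature at the previous step (K).
#' @param q_prev Heat flow at the previous step (W).
#' @param c_tot Total heat capacity (J/K), > 0.
#' @param dt Time step (s), > 0.
#' @return Temperature after the step (K). Vectorised.
#' @export
cooling_step <- function(t_prev, q_prev, c_tot, dt) {
  stopifnot(all(c_tot > 0), all(dt > 0))
  t_prev - q_prev * dt / c_tot
}

# ln(r_out/r_in) / (2 pi k H): thermal resistance of a cylindrical shell (K/W)
shell_resistance <- function(r_in, r_out, k, height) {
  log(r_out / r_in) / (2 * pi * k * height)
}

#' Inner-wall temperature from the outer wall across the glass shell
#'
#' Fourier conduction through a hollow cylinder: with heat flowing outward at
#' rate `Q`, the inner wall is warmer than the outer wall by
#' `Q * ln(r_out/r_in) / (2 pi k_glass H)`.
#'
#' @param system A [vial_system()].
#' @param t_outer Outer-wall temperature (K).
#' @param q Heat flow (W).
#' @return Inner-wall temperature (K). Vectorised over `t_outer`, `q`.
#' @export
inner_wall_from_outer <- function(system, t_outer, q) {
  t_outer + q * shell_resistance(
    system$inner_radius, system$outer_radius,
    system$glass_conductivity, system$wall_height
  )
}

#' Geometry of the instantaneously nucleated zone
#'
#' At high heat flux the radial temperature gradient in the liquid annulus can
#' leave the inner part of the liquid above the equilibrium temperature when
#' nucleation fires at the wall. Nucleation is then confined to the annular
#' zone outside the radius
#' `rsc = r_in * exp(-2 pi k_ice H (Teq - T_inner) / Q)`.
#' Because the spinning fill is a hollow annulus, `rsc` is clamped below by
#' the liquid core radius and the nucleated volume is capped at the liquid
#' volume.
#'
#' @param system A [vial_system()].
#' @param t_inner Inner-wall temperature at nucleation (K), <= Teq.
#' @param q Heat flow at nucleation (W), > 0.
#' @return List with `nucleation_radius` (m), `nucleated_volume` (m^3),
#'   `core_radius` (m) and `inner_wall_temperature_at_nucleation` (K).
#' @export
nucleation_geometry <- function(system, t_inner, q) {
  if (q <= 0) {
    stop("nucleation geometry undefined: heat flow must be positive at nucleation", call. = FALSE)
  }
  if (t_inner > system$equilibrium_temperature) {
    stop("nucleation geometry undefined: inner wall must be at or below Teq", call. = FALSE)
  }
  r_in <- system$inner_radius
  rsc <- r_in * exp(
    -2 * pi * system$ice_conductivity * system$wall_height *
      (system$equilibrium_temperature - t_inner) / q
  )
  liquid_volume <- system$water_mass / system$water_density
  core_radius <- sqrt(r_in^2 - liquid_volume / (pi * system$wall_height))
  rsc <- max(rsc, core_radius)
  vnucl <- pi * system$wall_height * (r_in^2 - rsc^2)
  vnucl <- min(vnucl, liquid_volume)
  list(
    nucleation_radius = rsc,
    nucleated_volume = vnucl,
    core_radius = core_radius,
    inner_wall_temperature_at_nucleation = t_inner
  )
}

#' Mass fraction of the nucleated zone frozen instantaneously at nucleation
#'
#' The sensible heat released in warming the supercooled system back to the
#' equilibrium temperature freezes part of the nucleated zone at once:
#' `chi_nuc = C_tot_w * (Teq - Tnuc) / (dHf * V_nucl * rho_water)`.
#'
#' @param system A [vial_system()].
#' @param ctot_w Liquid-phase total heat capacity (J/K).
#' @param t_nuc Nucleation temperature (K), <= Teq.
#' @param nucleated_mass Water mass in the nucleated zone (kg), > 0.
#' @return Dimensionless fraction in [0, 1).
#' @export
nucleation_fraction <- function(system, ctot_w, t_nuc, nucleated_mass) {
  if (nucleated_mass <= 0) stop("nucleated mass must be positive", call. = FALSE)
  if (t_nuc > system$equilibrium_temperature) stop("t_nuc must be <= Teq", call. = FALSE)
  chi <- ctot_w * (system$equilibrium_temperature - t_nuc) /
    (system$latent_heat_fusion * nucleated_mass)
  if (chi >= 1) {
    stop(
      "nucleation fraction >= 1 (", format(chi), "): the nucleated zone cannot absorb ",
      "the released sensible heat; deepen the heat flux or enlarge the nucleated volume",
      call. = FALSE
    )
  }
  chi
}

#' One crystal-growth step of the ice-mass ledger
#'
#' The latent heat removed over a step converts water to ice:
#' `m_new = m_prev + Q_prev * f * dt / dHf`, with `f = 1 + chi_nuc` while the
#' freezing front lies in the nucleated zone (where a fraction `chi_nuc` of
#' the mass froze instantaneously at nucleation and is swept up by the front)
#' and `f = 1` inside the nucleation radius. The mass is capped at the fill
#' mass.
#'
#' @param system A [vial_system()].
#' @param ice_mass_prev Ice mass at the previous step (kg).
#' @param q_prev Heat flow at the previous step (W).
#' @param chi_nuc Nucleation fraction.
#' @param dt Time step (s).
#' @param within_nucleated_zone Logical: is the freezing front still outside
#'   the nucleation radius?
#' @return Updated ice mass (kg).
#' @export
growth_step <- function(system, ice_mass_prev, q_prev, chi_nuc, dt,
                        within_nucleated_zone = TRUE) {
  f <- if (within_nucleated_zone) 1 + chi_nuc else 1
  min(system$water_mass, ice_mass_prev + q_prev * f * dt / system$latent_heat_fusion)
}

#' Ice layer thickness from ice mass
#'
#' The ice forms an annulus on the inner wall; its thickness measured inward
#' is `th = r_in - sqrt((pi r_in^2 H - V_ice) / (pi H))` with
#' `V_ice = m_ice / rho_ice`.
#'
#' @param system A [vial_system()].
#' @param ice_mass Ice mass (kg), >= 0. Vectorised.
#' @return Thickness (m).
#' @export
ice_thickness <- function(system, ice_mass) {
  stopifnot(all(ice_mass >= 0))
  v <- ice_mass / system$ice_density
  cyl <- pi * system$inner_radius^2 * system$wall_height
  if (any(v > cyl * (1 + 1e-12))) {
    stop("geometry error: ice volume exceeds the inner cylinder volume", call. = FALSE)
  }
  v <- pmin(v, cyl)
  system$inner_radius - sqrt((cyl - v) / (pi * system$wall_height))
}

#' Wall temperatures during crystal growth
#'
#' During growth the liquid sits at the equilibrium temperature; the inner
#' wall lies below it by the conduction gradient across the growing ice
#' annulus, `T_inner = Teq - Q ln(r_in / (r_in - th)) / (2 pi k_ice H)`, and
#' the outer wall below that by the glass-shell gradient.
#'
#' @param system A [vial_system()].
#' @param q Heat flow (W).
#' @param thice Ice layer thickness (m), in `[0, r_in)`.
#' @return List with `t_inner` and `t_outer` (K).
#' @export
outer_wall_during_growth <- function(system, q, thice) {
  r_in <- system$inner_radius
  if (thice < 0 || thice >= r_in) {
    stop("ice thickness must lie in [0, inner_radius): conduction gradient diverges", call. = FALSE)
  }
  grad_ice <- q * log(r_in / (r_in - thice)) /
    (2 * pi * system$ice_conductivity * system$wall_height)
  t_inner <- system$equilibrium_temperature - grad_ice
  t_outer <- t_inner - q * shell_resistance(
    r_in, system$outer_radius, system$glass_conductivity, system$wall_height
  )
  list(t_inner = t_inner, t_outer = t_outer)
}

# Resolve gas temperature / flow inputs onto the simulation grid. Accepts a
# scalar (held constant), a function of time, or a process_trace (linearly
# interpolated, constant-extrapolated beyond its end).
resolve_driver <- function(x, what = "gas_temperature") {
  if (inherits(x, "process_trace")) {
    tt <- x$time
    yy <- x[[what]]
    force(tt)
    force(yy)
    function(t) stats::approx(tt, yy, xout = t, rule = 2)$y
  } else if (is.function(x)) {
    x
  } else if (is.numeric(x) && length(x) == 1L) {
    NULL # signals a constant; caller uses the scalar fast path
  } else {
    stop("driver inputs must be a scalar, a function of time, or a process_trace", call. = FALSE)
  }
}

#' Simulate the four phases of spin freezing
#'
#' Explicit forward-Euler simulation of the outer/inner vial-wall temperature
#' through liquid cooling, the nucleation event, crystal growth and solid
#' cooling, with the heat flow always evaluated at the previous step. Gas
#' temperature and flow rate may each be a constant, a function of time (s ->
#' K or m^3/s), or a [process_trace()] (interpolated onto the simulation
#' grid). The heat transfer coefficient comes from the affine calibration
#' plus an optional additive offset `h_offset` (used to propagate the
#' calibration RMSE as an uncertainty).
#'
#' Instead of flow-driven heat flow, a prescribed per-phase heat flow
#' `q_phase = c(liquid =, growth =, solid =)` (W) may be supplied; this is the
#' mode used to construct open-loop target trajectories, and it shares every
#' other equation with the flow-driven mode.
#'
#' @param system A [vial_system()].
#' @param settings A [simulation_settings()].
#' @param calibration A [calibration_model()]; ignored in prescribed-Q mode.
#' @param gas_temperature Constant (K), function, or `process_trace`.
#' @param flow Constant (m^3/s), function, or `process_trace` (its
#'   `flow_rate` column). Ignored in prescribed-Q mode.
#' @param h_offset Additive offset on the heat transfer coefficient
#'   (W/(m^2 K)).
#' @param q_phase Optional named numeric `c(liquid, growth, solid)` of
#'   prescribed heat flows (W); switches the engine to prescribed-Q mode.
#' @param max_time Optional stop time (s); the run ends at this time even if
#'   the final temperature has not been reached (reported in `completed`).
#' @return An object of class `simulation_result`: a data.frame with columns
#'   `time`, `phase` (`liquid_cooling`, `crystal_growth`, `solid_cooling`),
#'   `t_outer`, `t_inner` (K), `ice_mass` (kg), `ice_thickness` (m), `q`
#'   (W, evaluated at the row's state), `h` (W/(m^2 K)) and `flow` (m^3/s),
#'   plus attributes `nucleation` (the nucleation state, incl. `chi_nuc`,
#'   `rsc`, `t_event`), `tcryst` (s), `phase_bounds`, and `completed`.
#' @export
simulate_freezing <- function(system, settings, calibration = default_calibration(),
                              gas_temperature = 213.15, flow = lmin_to_m3s(50),
                              h_offset = 0, q_phase = NULL, max_time = Inf) {
  validate_configuration(system, settings)
  prescribed <- !is.null(q_phase)
  if (prescribed) {
    stopifnot(all(c("liquid", "growth", "solid") %in% names(q_phase)))
  }

  dt <- settings$dt
  teq <- system$equilibrium_temperature
  tnuc <- settings$nucleation_temperature
  tfin <- settings$final_temperature
  dhf <- system$latent_heat_fusion
  mwater <- system$water_mass
  area <- pi * system$outer_diameter * system$wall_height
  gg <- shell_resistance(
    system$inner_radius, system$outer_radius,
    system$glass_conductivity, system$wall_height
  )
  ki2ph <- 2 * pi * system$ice_conductivity * system$wall_height
  r_in <- system$inner_radius
  cyl <- pi * r_in^2 * system$wall_height
  rho_ice <- system$ice_density
  cw <- total_heat_capacity(system, "liquid")
  ci <- total_heat_capacity(system, "solid")
  inner_trigger <- settings$nucleation_reference == "inner"

  tg_fun <- resolve_driver(gas_temperature, "gas_temperature")
  tg_const <- is.null(tg_fun)
  if (tg_const) tg0 <- as.numeric(gas_temperature)
  fl_fun <- if (prescribed) NULL else resolve_driver(flow, "flow_rate")
  fl_const <- is.null(fl_fun)
  if (!prescribed && fl_const) {
    h0 <- calibration$slope * as.numeric(flow) + calibration$intercept + h_offset
    if (h0 < 0) stop("heat transfer coefficient below zero at the supplied flow", call. = FALSE)
  }

  # feasibility: with flow-driven flux the wall asymptotes to the gas
  # temperature, so nucleation is unreachable if the gas never falls below the
  # trigger (a prescribed heat flow has no such limit)
  horizon <- min(max_time, settings$max_steps * dt)
  probe_t <- seq(0, min(horizon, 86400), length.out = 257)
  tg_min <- if (tg_const) tg0 else min(tg_fun(probe_t))
  if (!prescribed && tg_min >= tnuc) {
    stop(
      sprintf(
        "nucleation temperature %.2f K unreachable: gas temperature never falls below it (min Tgas = %.2f K)",
        tnuc, tg_min
      ),
      call. = FALSE
    )
  }

  nmax <- settings$max_steps + 1L
  cap <- min(nmax, 2048L)
  t_o <- numeric(cap)
  t_i <- numeric(cap)
  mi <- numeric(cap)
  th <- numeric(cap)
  qv <- numeric(cap)
  hv <- numeric(cap)
  fv <- numeric(cap)
  ph <- integer(cap)

  grow_to <- function(newcap) {
    length(t_o) <<- newcap
    length(t_i) <<- newcap
    length(mi) <<- newcap
    length(th) <<- newcap
    length(qv) <<- newcap
    length(hv) <<- newcap
    length(fv) <<- newcap
    length(ph) <<- newcap
  }

  phase <- 1L # 1 liquid, 2 growth, 3 solid
  nuc <- NULL
  chi <- 0
  rsc <- r_in
  i_event <- NA_integer_
  i_growth_end <- NA_integer_
  completed <- FALSE

  # state at step 0
  i <- 1L
  tm <- 0
  To <- settings$initial_wall_temperature
  tg <- if (tg_const) tg0 else tg_fun(0)
  if (prescribed) {
    Q <- q_phase[["liquid"]]
    h <- NA_real_
    fl <- NA_real_
  } else {
    fl <- if (fl_const) as.numeric(flow) else fl_fun(0)
    h <- if (fl_const) h0 else calibration$slope * fl + calibration$intercept + h_offset
    Q <- area * h * (To - tg)
  }
  Ti <- To + Q * gg
  t_o[1] <- To
  t_i[1] <- Ti
  qv[1] <- Q
  hv[1] <- h
  fv[1] <- fl
  ph[1] <- 1L
  mi[1] <- 0
  th[1] <- 0

  # immediate-trigger guard: start already below the nucleation temperature
  if ((if (inner_trigger) Ti else To) <= tnuc) {
    stop("initial wall temperature is already at or below the nucleation trigger", call. = FALSE)
  }

  while (i < nmax && tm < max_time - 1e-9) {
    i <- i + 1L
    if (i > cap) {
      cap <- min(nmax, cap * 2L)
      grow_to(cap)
    }
    tm <- tm + dt
    tg <- if (tg_const) tg0 else tg_fun(tm)
    Qprev <- Q

    if (phase == 1L) {
      To <- To - Qprev * dt / cw
      if (prescribed) {
        Q <- q_phase[["liquid"]]
      } else {
        if (!fl_const) {
          fl <- fl_fun(tm)
          h <- calibration$slope * fl + calibration$intercept + h_offset
        }
        Q <- area * h * (To - tg)
      }
      Ti <- To + Q * gg
      trigger <- if (inner_trigger) Ti <= tnuc else To <= tnuc
      if (trigger) {
        # nucleation event: geometry from the state at the trigger, liquid
        # snaps to Teq, outer wall recomputed through the glass alone
        geom <- nucleation_geometry(system, min(Ti, teq), max(Q, 1e-12))
        m_nuc <- geom$nucleated_volume * system$water_density
        chi <- nucleation_fraction(system, cw, tnuc, m_nuc)
        rsc <- geom$nucleation_radius
        nuc <- c(geom, list(
          chi_nuc = chi, nucleated_mass = m_nuc, t_event = tm,
          q_at_event = Q
        ))
        i_event <- i
        mice <- chi * m_nuc
        thice <- r_in - sqrt((cyl - mice / rho_ice) / (pi * system$wall_height))
        Ti <- teq
        To <- teq - Q * gg
        if (prescribed) {
          Q <- q_phase[["growth"]]
        } else {
          Q <- area * h * (To - tg)
        }
        phase <- 2L
        mi[i] <- mice
        th[i] <- thice
      } else {
        mi[i] <- 0
        th[i] <- 0
      }
    } else if (phase == 2L) {
      outside <- (r_in - thice) >= rsc
      f <- if (outside) 1 + chi else 1
      mice <- mice + Qprev * f * dt / dhf
      if (mice >= mwater) {
        mice <- mwater
      }
      thice <- r_in - sqrt((cyl - mice / rho_ice) / (pi * system$wall_height))
      Ti <- teq - Qprev * log(r_in / (r_in - thice)) / ki2ph
      To <- Ti - Qprev * gg
      if (prescribed) {
        Q <- if (mice >= mwater) q_phase[["solid"]] else q_phase[["growth"]]
      } else {
        if (!fl_const) {
          fl <- fl_fun(tm)
          h <- calibration$slope * fl + calibration$intercept + h_offset
        }
        Q <- area * h * (To - tg)
      }
      if (mice >= mwater) {
        i_growth_end <- i
        phase <- 3L
        ph[i] <- 2L # the completing step still belongs to crystal growth
        mi[i] <- mice
        th[i] <- thice
        t_o[i] <- To
        t_i[i] <- Ti
        qv[i] <- Q
        hv[i] <- h
        fv[i] <- fl
        if (To <= tfin) {
          completed <- TRUE
          break
        }
        next
      }
      mi[i] <- mice
      th[i] <- thice
    } else {
      To <- To - Qprev * dt / ci
      if (prescribed) {
        Q <- q_phase[["solid"]]
      } else {
        if (!fl_const) {
          fl <- fl_fun(tm)
          h <- calibration$slope * fl + calibration$intercept + h_offset
        }
        Q <- area * h * (To - tg)
      }
      Ti <- To + Q * gg
      mi[i] <- mwater
      th[i] <- thice
      if (To <= tfin) {
        t_o[i] <- To
        t_i[i] <- Ti
        qv[i] <- Q
        hv[i] <- h
        fv[i] <- fl
        ph[i] <- 3L
        completed <- TRUE
        break
      }
    }

    t_o[i] <- To
    t_i[i] <- Ti
    qv[i] <- Q
    hv[i] <- h
    fv[i] <- fl
    ph[i] <- phase
  }

  n <- i
  res <- data.frame(
    time = seq(0, by = dt, length.out = n),
    phase = c("liquid_cooling", "crystal_growth", "solid_cooling")[ph[1:n]],
    t_outer = t_o[1:n],
    t_inner = t_i[1:n],
    ice_mass = mi[1:n],
    ice_thickness = th[1:n],
    q = qv[1:n],
    h = hv[1:n],
    flow = fv[1:n],
    stringsAsFactors = FALSE
  )
  if (is.na(i_event)) {
    stop(
      "nucleation not reached within ", n - 1L, " steps; the gas may be too warm ",
      "or max_steps/max_time too small",
      call. = FALSE
    )
  }
  tcryst <- if (!is.na(i_growth_end)) (i_growth_end - i_event) * dt else NA_real_
  structure(
    res,
    class = c("simulation_result", "data.frame"),
    nucleation = nuc,
    tcryst = tcryst,
    phase_bounds = c(
      nucleation = (i_event - 1L) * dt,
      growth_end = if (!is.na(i_growth_end)) (i_growth_end - 1L) * dt else NA_real_
    ),
    completed = completed,
    dt = dt
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  pb <- attr(x, "phase_bounds")
  nuc <- attr(x, "nucleation")
  cat(sprintf(
    "<simulation_result> %d samples, dt = %.3g s, %s\n",
    nrow(x), attr(x, "dt"),
    if (isTRUE(attr(x, "completed"))) "reached final temperature" else "stopped early"
  ))
  cat(sprintf(
    "  nucleation at %.1f s (chi_nuc = %.4f, rsc = %.3f mm), tcryst = %.1f s\n",
    pb[["nucleation"]], nuc$chi_nuc, 1000 * nuc$nucleation_radius, attr(x, "tcryst")
  ))
  cat(sprintf(
    "  t_outer: %.2f -> %.2f degC\n",
    kelvin_to_celsius(x$t_outer[1]), kelvin_to_celsius(x$t_outer[nrow(x)])
  ))
  invisible(x)
}

#' Phase midpoint times of a simulation
#'
#' @param result A `simulation_result`.
#' @return Named numeric: time (s) at the midpoint of each phase.
#' @export
phase_midpoints <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  out <- c(liquid_cooling = NA_real_, crystal_growth = NA_real_, solid_cooling = NA_real_)
  for (p in names(out)) {
    tt <- result$time[result$phase == p]
    if (length(tt)) out[p] <- tt[1] + (tt[length(tt)] - tt[1]) / 2
  }
  out
}

#' Linear cooling rate over a phase of a simulated profile
#'
#' Ordinary least-squares slope of the outer-wall temperature over all samples
#' of the requested phase, reported as a positive cooling rate.
#'
#' @param result A `simulation_result`.
#' @param phase One of `"liquid_cooling"`, `"solid_cooling"`.
#' @param units `"K_per_s"` or `"C_per_min"`.
#' @return Cooling rate (positive for a falling temperature).
#' @export
fit_cooling_rate <- function(result, phase = c("liquid_cooling", "solid_cooling"),
                             units = c("C_per_min", "K_per_s")) {
  phase <- match.arg(phase)
  units <- match.arg(units)
  sel <- result$phase == phase
  if (sum(sel) < 3L) stop("not enough samples in phase '", phase, "' to fit a slope", call. = FALSE)
  slope <- -unname(stats::coef(stats::lm(result$t_outer[sel] ~ result$time[sel]))[2])
  if (units == "C_per_min") slope * 60 else slope
}
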