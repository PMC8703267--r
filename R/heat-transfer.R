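#' Thermocouple time constant
#'
#' `Nt = 1 / (nt_a + nt_b * sqrt(w))`, the empirical regression for the lag
#' time constant of a thermocouple in a gas stream of velocity `w`.
#'
#' @param spec A [thermocouple_spec()].
#' @return Time constant Nt (s).
#' @export
sensor_time_constant <- function(spec) {
  stopifnot(inherits(spec, "thermocouple_spec"))
  denom <- spec$nt_a + spec$nt_b * sqrt(spec$air_velocity)
  if (!is.finite(denom) || denom <= 0) {
    stop("thermocouple configuration error: nt_a + nt_b*sqrt(w) must be positive", call. = FALSE)
  }
  1 / denom
}

# Finite-difference derivative on a uniform grid: central differences in the
# interior, one-sided second-order at both ends.
fd_derivative <- function(y, dt) {
  n <- length(y)
  if (n < 2L) stop("cannot differentiate fewer than 2 samples", call. = FALSE)
  if (n == 2L) {
    return(rep((y[2] - y[1]) / dt, 2L))
  }
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * dt)
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * dt)
  d
}

#' Correct a gas-temperature series for thermocouple measurement lag
#'
#' The lag error is `Te_lag = -Nt * dTgas/dt`; the corrected reading is the
#' measured value minus the lag error. By default the derivative is estimated
#' by finite differences on the trace grid (central in the interior,
#' one-sided second-order at the ends). For noisy gas channels the two-point
#' stencil multiplies the channel noise by `sqrt(2) Nt / (2 dt)` into the
#' corrected series; setting `derivative_window > 1` replaces it with a
#' rolling local-linear slope of that width (odd number of samples), which is
#' still exact for linear ramps but strongly attenuates noise.
#'
#' @param trace A [process_trace()].
#' @param spec A [thermocouple_spec()].
#' @param derivative_window 1 (default) for plain central differences, or an
#'   odd width (samples) for the local-linear derivative.
#' @return The trace with its `gas_temperature` column corrected (K).
#' @export
correct_gas_temperature <- function(trace, spec, derivative_window = 1L) {
  stopifnot(inherits(trace, "process_trace"))
  nt <- sensor_time_constant(spec)
  dt <- trace_dt(trace)
  deriv <- if (derivative_window <= 1L) {
    fd_derivative(trace$gas_temperature, dt)
  } else {
    d <- rolling_slope(trace$gas_temperature, dt, derivative_window)
    # fall back to finite differences where the rolling window runs off the ends
    fd <- fd_derivative(trace$gas_temperature, dt)
    ifelse(is.na(d), fd, d)
  }
  lag_error <- -nt * deriv
  trace$gas_temperature <- trace$gas_temperature - lag_error
  trace
}

#' Convective heat flow from vial wall to cooling gas
#'
#' Newton's law of cooling over the cylindrical exchange surface:
#' `Q = pi * h * D * H * (T_wall - T_gas)`. Positive when the wall is warmer
#' than the gas (heat leaving the system); the sign carries meaning.
#'
#' @param system A [vial_system()].
#' @param h Heat transfer coefficient (W/(m^2 K)), >= 0.
#' @param t_wall Outer-wall temperature (K).
#' @param t_gas Gas temperature (K).
#' @return Heat flow (W). Vectorised over `h`, `t_wall`, `t_gas`.
#' @export
heat_rate <- function(system, h, t_wall, t_gas) {
  stopifnot(all(h >= 0))
  pi * h * system$outer_diameter * system$wall_height * (t_wall - t_gas)
}

#' Heat transfer coefficient from gas flow rate
#'
#' Evaluates the affine calibration `h = slope * flow + intercept`. A
#' non-positive result is flagged: the affine map is only trusted over the
#' calibrated flow range, and a coefficient <= 0 is unphysical.
#'
#' @param model A [calibration_model()].
#' @param flow Volumetric flow rate (m^3/s), >= 0. Vectorised.
#' @return Heat transfer coefficient (W/(m^2 K)).
#' @export
h_from_flow <- function(model, flow) {
  stopifnot(inherits(model, "calibration_model"), all(flow >= 0))
  h <- model$slope * flow + model$intercept
  if (any(h <= 0)) {
    warning("predicted h <= 0: flow outside the calibrated regime", call. = FALSE)
  }
  h
}

#' Latent heat released by full crystallization of the fill
#'
#' @param system A [vial_system()].
#' @return `water_mass * latent_heat_fusion` (J).
#' @export
crystallization_heat <- function(system) {
  system$water_mass * system$latent_heat_fusion
}

# Rolling local-linear slope estimate (Savitzky-Golay order-1 derivative).
# Returns NA within half a window of either end.
rolling_slope <- function(y, dt, width) {
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  k <- seq(-half, half)
  wts <- k / sum(k^2) / dt
  as.numeric(stats::filter(y, rev(wts), sides = 2))
}

# Two-piece-linear changepoint refinement on raw data: within idx_lo..idx_hi,
# choose the split s (last index of the left segment) minimising the summed
# RSS of independent line fits left and right. Returns the split index with
# the residual standard deviation of the best fit as attribute "sd".
refine_changepoint <- function(time, y, idx_lo, idx_hi, min_seg = 3L) {
  idx_lo <- max(idx_lo, 1L)
  idx_hi <- min(idx_hi, length(y))
  rng <- idx_lo:idx_hi
  tt <- time[rng]
  yy <- y[rng]
  n <- length(rng)
  if (n < 2L * min_seg + 1L) {
    return(structure(rng[ceiling(n / 2)], sd = NA_real_))
  }
  rss_line <- function(t, v) {
    m <- length(v)
    if (m < 2L) {
      return(0)
    }
    tc <- t - mean(t)
    vc <- v - mean(v)
    stt <- sum(tc^2)
    if (stt == 0) {
      return(sum(vc^2))
    }
    sum(vc^2) - sum(tc * vc)^2 / stt
  }
  best_s <- min_seg
  best_rss <- Inf
  for (s in min_seg:(n - min_seg)) {
    r <- rss_line(tt[1:s], yy[1:s]) + rss_line(tt[(s + 1):n], yy[(s + 1):n])
    if (r < best_rss) {
      best_rss <- r
      best_s <- s
    }
  }
  structure(rng[best_s], sd = sqrt(best_rss / max(1L, n - 4L)))
}

# Joint three-piece-linear changepoint fit: given candidate windows for the
# two breakpoints (descent -> plateau -> drop), choose the pair (s1, s2)
# minimising the summed RSS of three independent line fits. Sharing the
# plateau segment between both breakpoints roughly halves the endpoint
# variance relative to two independent two-piece fits. O(1) segment RSS via
# prefix sums.
refine_three_piece <- function(time, y, s1_lo, s1_hi, s2_lo, s2_hi, min_seg = 3L) {
  n <- length(y)
  lo <- max(1L, s1_lo - min_seg)
  hi <- min(n, s2_hi + min_seg)
  tt <- time[lo:hi]
  yy <- y[lo:hi]
  m <- length(tt)
  c1 <- cumsum(tt)
  c2 <- cumsum(tt^2)
  c3 <- cumsum(yy)
  c4 <- cumsum(yy^2)
  c5 <- cumsum(tt * yy)
  seg_rss <- function(i, j) { # local indices, inclusive
    k <- j - i + 1L
    if (k < 2L) {
      return(0)
    }
    st <- c1[j] - if (i > 1L) c1[i - 1L] else 0
    stt <- c2[j] - if (i > 1L) c2[i - 1L] else 0
    sy <- c3[j] - if (i > 1L) c3[i - 1L] else 0
    syy <- c4[j] - if (i > 1L) c4[i - 1L] else 0
    sty <- c5[j] - if (i > 1L) c5[i - 1L] else 0
    sxx <- stt - st^2 / k
    sxy <- sty - st * sy / k
    syy_c <- syy - sy^2 / k
    if (sxx <= 0) {
      return(syy_c)
    }
    max(0, syy_c - sxy^2 / sxx)
  }
  s1_cand <- max(lo + min_seg - 1L, s1_lo):min(s1_hi, hi - 2L * min_seg)
  s2_cand <- max(s2_lo, lo + 2L * min_seg):min(s2_hi, hi - min_seg)
  best <- c(NA_integer_, NA_integer_)
  best_rss <- Inf
  for (s1 in s1_cand) {
    i1 <- s1 - lo + 1L
    r_left <- seg_rss(1L, i1)
    for (s2 in s2_cand) {
      if (s2 < s1 + min_seg) next
      i2 <- s2 - lo + 1L
      r <- r_left + seg_rss(i1 + 1L, i2) + seg_rss(i2 + 1L, m)
      if (r < best_rss) {
        best_rss <- r
        best <- c(s1, s2)
      }
    }
  }
  dof <- max(1L, m - 6L)
  list(s1 = best[1], s2 = best[2], sd = sqrt(best_rss / dof))
}

# first index in `idx` at which `cond[idx]` holds and keeps holding for a
# majority of the following `persist` samples (guards threshold crossings
# against isolated noise excursions)
first_persistent <- function(cond, idx, persist) {
  n <- length(cond)
  for (i in idx) {
    if (!isTRUE(cond[i])) next
    ahead <- cond[i:min(n, i + persist)]
    ahead <- ahead[!is.na(ahead)]
    if (length(ahead) && mean(ahead) >= 0.6) {
      return(i)
    }
  }
  NA_integer_
}

#' Locate the crystal-growth window in a measured wall-temperature trace
#'
#' During spin freezing the measured outer-wall temperature falls steadily
#' (liquid cooling), rises abruptly at ice nucleation, declines slowly along
#' the crystal-growth plateau, and finally drops sharply once all water is
#' frozen. This detector finds the plateau: it estimates the local temperature
#' slope with a rolling linear fit (robust to measurement noise of a few K),
#' finds the first persistent crossing from a cooling slope to a plateau slope
#' (nucleation) and the first persistent return to a steep cooling slope (end
#' of growth), then refines both instants against the raw series with a
#' two-piece-linear changepoint fit.
#'
#' @param trace A [process_trace()] with a `wall_temperature` column spanning
#'   nucleation through solid cooling.
#' @param smooth_window Width (samples) of the rolling slope estimate.
#' @param rise_slope Slope threshold (K/s) separating the liquid-cooling
#'   descent from the crystal-growth plateau; the onset is the first
#'   persistent crossing above it.
#' @param drop_slope Slope threshold (K/s) marking the sharp post-plateau
#'   drop into solid cooling (first persistent crossing below it).
#' @param min_plateau Minimum plateau length (s) between onset and drop.
#' @return `list(t_start, t_end, i_start, i_end)`: window endpoints on the
#'   trace grid (s) and their sample indices.
#' @export
detect_crystallization_window <- function(trace, smooth_window = 21L,
                                          rise_slope = -0.4, drop_slope = -0.4,
                                          min_plateau = 5) {
  stopifnot(inherits(trace, "process_trace"))
  if (is.null(trace$wall_temperature)) {
    stop("detection failure: trace has no measured wall_temperature series", call. = FALSE)
  }
  y <- trace$wall_temperature
  tm <- trace$time
  dt <- trace_dt(trace)
  sl <- rolling_slope(y, dt, smooth_window)
  ok <- which(!is.na(sl))
  if (length(ok) < 10L) stop("detection failure: trace too short for the slope window", call. = FALSE)
  half <- (as.integer(smooth_window) %/% 2L) + 1L
  persist <- half

  # nucleation onset: the trace must first be descending (liquid cooling),
  # then cross persistently above rise_slope (the jump and plateau)
  descending <- first_persistent(sl < rise_slope, ok, persist)
  if (is.na(descending)) {
    stop("detection failure: no liquid-cooling descent found before a plateau", call. = FALSE)
  }
  after <- ok[ok > descending]
  i_rise <- first_persistent(sl > rise_slope, after, persist)
  if (is.na(i_rise)) {
    stop("detection failure: no nucleation-associated rise/plateau found", call. = FALSE)
  }
  # end of growth: first persistent steep drop after the plateau
  gap <- max(1L, ceiling(min_plateau / dt))
  cand <- ok[ok >= i_rise + gap]
  i_drop <- first_persistent(sl < drop_slope, cand, persist)
  if (is.na(i_drop)) {
    stop("detection failure: no post-plateau sharp drop found", call. = FALSE)
  }

  # joint three-piece refinement (descent | plateau | drop) on the raw series
  jr <- refine_three_piece(
    tm, y,
    i_rise - 3L * half, min(i_rise + 3L * half, i_drop - 2L),
    max(i_drop - 3L * half, i_rise + 2L), i_drop + 3L * half
  )
  s1 <- jr$s1
  s2 <- jr$s2
  if (is.na(s1) || is.na(s2)) stop("detection failure: degenerate window", call. = FALSE)
  # narrow second pass on effectively noiseless data: the wide windows give
  # the curvature of the surrounding phases leverage over the splits, while
  # under real measurement noise the wide joint fit is the lower-variance
  # estimator
  if (is.finite(jr$sd) && jr$sd < 0.35) {
    s1 <- as.integer(refine_changepoint(tm, y, s1 - 6L, s1 + 6L, min_seg = 3L))
    s2 <- as.integer(refine_changepoint(tm, y, s2 - 6L, s2 + 6L, min_seg = 3L))
  }
  i_start <- s1 + 1L # first sample after the nucleation jump
  i_end <- s2
  if (i_end <= i_start) stop("detection failure: degenerate window", call. = FALSE)
  list(
    t_start = tm[i_start], t_end = tm[i_end],
    i_start = i_start, i_end = i_end
  )
}

#' Calibrate the flow-rate to heat-transfer-coefficient regression
#'
#' Implements the constant-flow calibration procedure. For each run the
#' crystal-growth window is located on the measured wall temperature
#' ([detect_crystallization_window()]); the mean heat flow over the window is
#' `Qbar = water_mass * latent_heat_fusion / tcryst` (all latent heat is
#' removed at the mean rate; the slight sensible cooling of the ice layer
#' during growth is neglected); a per-timepoint heat transfer coefficient
#' `h = Qbar / (pi * D * H * (T_wall - T_gas))` is averaged over the window;
#' and ordinary least squares of the per-run mean `h` on the per-run mean flow
#' gives the affine calibration. RMSE is computed over the runs and RMSECV by
#' leave-one-out refits.
#'
#' @param traces List of [process_trace()] objects, one constant-flow run
#'   each, every one carrying a measured `wall_temperature`. At least 3 runs
#'   at distinct flows are required.
#' @param system A [vial_system()].
#' @param tc Optional [thermocouple_spec()]; when supplied, each run's gas
#'   temperature is lag-corrected before use (with a 5-sample local-linear
#'   derivative, see [correct_gas_temperature()], so channel noise does not
#'   leak into the per-timepoint coefficients).
#' @param edge_guard Samples excluded at each end of the detected window when
#'   averaging the per-timepoint h (the window endpoints carry the detector's
#'   uncertainty and would otherwise contaminate the average with
#'   neighbouring-phase samples); the window length used for the mean heat
#'   rate is not affected.
#' @param ... Passed to [detect_crystallization_window()].
#' @return A [calibration_model()] with an attached `runs` data.frame
#'   (per-run flow, window, mean heat rate and mean h).
#' @export
calibrate_heat_transfer <- function(traces, system, tc = NULL, edge_guard = 5L, ...) {
  stopifnot(is.list(traces))
  if (length(traces) < 3L) {
    stop("calibration needs at least 3 constant-flow runs", call. = FALSE)
  }
  qc <- crystallization_heat(system)
  area <- pi * system$outer_diameter * system$wall_height
  rows <- lapply(traces, function(tr) {
    stopifnot(inherits(tr, "process_trace"))
    if (!is.null(tc)) tr <- correct_gas_temperature(tr, tc, derivative_window = 5L)
    win <- detect_crystallization_window(tr, ...)
    tcryst <- win$t_end - win$t_start
    qbar <- qc / tcryst
    guard <- min(as.integer(edge_guard), (win$i_end - win$i_start - 1L) %/% 3L)
    idx <- (win$i_start + guard):(win$i_end - guard)
    dT <- tr$wall_temperature[idx] - tr$gas_temperature[idx]
    bad <- dT <= 0
    if (any(bad)) {
      warning(sum(bad), " timepoint(s) with wall not warmer than gas excluded from Eq-based h",
        call. = FALSE
      )
      dT <- dT[!bad]
    }
    if (length(dT) == 0L) {
      stop("calibration run invalid: wall never warmer than gas inside the window", call. = FALSE)
    }
    h_t <- qbar / (area * dT)
    data.frame(
      flow = mean(tr$flow_rate[idx]),
      t_start = win$t_start, t_end = win$t_end,
      mean_heat_rate = qbar, mean_h = mean(h_t)
    )
  })
  runs <- do.call(rbind, rows)
  if (length(unique(signif(runs$flow, 10))) < 2L) {
    stop("calibration is rank-deficient: need at least two distinct flow rates", call. = FALSE)
  }
  fit <- stats::lm(mean_h ~ flow, data = runs)
  coefs <- stats::coef(fit)
  n <- nrow(runs)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  # leave-one-out cross-validation
  cv_err <- vapply(seq_len(n), function(i) {
    sub <- runs[-i, , drop = FALSE]
    if (length(unique(signif(sub$flow, 10))) < 2L) {
      return(NA_real_)
    }
    f <- stats::lm(mean_h ~ flow, data = sub)
    runs$mean_h[i] - unname(stats::predict(f, newdata = runs[i, , drop = FALSE]))
  }, numeric(1))
  rmsecv <- sqrt(mean(cv_err^2, na.rm = TRUE))
  model <- calibration_model(
    slope = unname(coefs["flow"]), intercept = unname(coefs["(Intercept)"]),
    rmse = rmse, rmsecv = rmsecv, n_experiments = n
  )
  attr(model, "runs") <- runs
  model
}
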