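#' Saltelli sampling design for total-order sensitivity indices
#'
#' Builds the base matrices `A` and `B` from a `2k`-dimensional Sobol sequence
#' (A = first k columns, B = last k columns) plus the k cross matrices
#' `AB_i`, each equal to `A` with column `i` replaced from `B`. Evaluating the
#' model on all `(k + 2) N` rows supports the Jansen total-order estimator.
#'
#' @param k Number of parameters.
#' @param n Base sample count (>= 128 recommended for reports).
#' @param seed Optional integer seed for the Sobol digital shift.
#' @return List with matrices `A`, `B` (each `n x k`, unit hypercube) and list
#'   `AB` of k matrices.
#' @export
saltelli_design <- function(k, n, seed = NULL) {
  stopifnot(k >= 1L, 2L * k <= 16L, n >= 2L)
  u <- sobol_points(n, 2L * k, seed = seed)
  a <- u[, seq_len(k), drop = FALSE]
  b <- u[, k + seq_len(k), drop = FALSE]
  ab <- lapply(seq_len(k), function(i) {
    m <- a
    m[, i] <- b[, i]
    m
  })
  list(A = a, B = b, AB = ab)
}

#' Jansen total-order sensitivity indices
#'
#' `ST_i = mean((fA - fAB_i)^2) / (2 Var(f))`, the Jansen formulation of the
#' total-order effect: the fraction of output variance attributable to
#' parameter `i` including all of its interactions. The total variance is
#' estimated from the pooled `fA` and `fB` evaluations. Small negative
#' estimates (sampling noise) are clipped to zero before the normalised
#' shares are formed; the raw values are retained.
#'
#' @param f_a Model outputs on the rows of `A` (length n).
#' @param f_ab `n x k` matrix of outputs on the rows of each `AB_i`.
#' @param f_b Optional outputs on `B`, pooled into the variance estimate.
#' @return List with `st` (clipped indices), `st_raw`, `share` (percent,
#'   summing to 100) and `variance`.
#' @export
total_order_index <- function(f_a, f_ab, f_b = NULL) {
  f_ab <- as.matrix(f_ab)
  n <- length(f_a)
  stopifnot(nrow(f_ab) == n)
  if (any(!is.finite(f_a)) || any(!is.finite(f_ab))) {
    stop("model outputs must be finite", call. = FALSE)
  }
  pool <- c(f_a, f_b)
  v <- mean(pool^2) - mean(pool)^2
  if (v <= 0) {
    stop("output variance is zero: sensitivity indices are undefined", call. = FALSE)
  }
  st_raw <- colMeans((f_a - f_ab)^2) / (2 * v)
  st <- pmax(st_raw, 0)
  share <- if (sum(st) > 0) 100 * st / sum(st) else rep(0, length(st))
  list(st = st, st_raw = st_raw, share = share, variance = v)
}

#' Global sensitivity analysis of the freezing model, per phase and flow rate
#'
#' For each gas flow rate, a Saltelli design over the seven uncertain inputs
#' is propagated through the simulator; the output analysed is the predicted
#' outer-wall temperature at one representative timepoint per spin-freezing
#' phase (default: the phase midpoints of the nominal run at that flow; a
#' sampled run whose phase at that time differs from the intended phase is
#' evaluated at its own phase midpoint instead). Jansen total-order indices
#' and normalised percentage shares are reported per (flow, phase, parameter).
#'
#' @param system,settings,calibration Nominal configuration.
#' @param spec An [uncertainty_spec()].
#' @param flows Flow rates to analyse (m^3/s).
#' @param n Base sample count per flow (the design evaluates `(k+2) n` runs).
#' @param gas_temperature Gas-temperature driver shared by all runs.
#' @param seed Optional integer seed for the Sobol digital shift.
#' @param timepoints Optional named numeric vector of representative times (s)
#'   per phase (names `liquid_cooling`, `crystal_growth`, `solid_cooling`);
#'   defaults to the nominal run's phase midpoints.
#' @return An object of class `sensitivity_report`: data.frame with columns
#'   `flow`, `phase`, `parameter`, `st`, `st_raw`, `share`; attributes `n`,
#'   `seed`, `timepoints`.
#' @export
gsa_profile <- function(system, settings, calibration = default_calibration(),
                        spec = uncertainty_spec(),
                        flows = lmin_to_m3s(c(20, 50, 80)),
                        n = 1024L,
                        gas_temperature = 213.15,
                        seed = NULL,
                        timepoints = NULL) {
  phases <- c("liquid_cooling", "crystal_growth", "solid_cooling")
  k <- 7L
  out <- list()
  tp_used <- list()
  for (fl in flows) {
    design <- saltelli_design(k, n, seed = seed)
    nominal <- simulate_freezing(system, settings, calibration,
      gas_temperature = gas_temperature, flow = fl
    )
    tp <- if (is.null(timepoints)) phase_midpoints(nominal) else timepoints
    if (any(!is.finite(tp[phases]))) {
      stop("nominal run at flow ", m3s_to_lmin(fl), " L/min lacks one of the three phases",
        call. = FALSE
      )
    }
    tp_used[[as.character(fl)]] <- tp

    eval_rows <- function(u) {
      rows <- scale_to_ranges(u, spec, list(system = system, flow = fl))
      res <- matrix(NA_real_, nrow(rows), 3L, dimnames = list(NULL, phases))
      for (i in seq_len(nrow(rows))) {
        args <- perturbed_run_args(rows[i, ], system, settings, calibration, gas_temperature)
        r <- do.call(simulate_freezing, args)
        mid <- phase_midpoints(r)
        for (p in phases) {
          # use the intended timepoint when the run is in the intended phase
          # there; otherwise fall back to the run's own phase midpoint
          idx <- which.min(abs(r$time - tp[[p]]))
          if (r$phase[idx] == p) {
            res[i, p] <- r$t_outer[idx]
          } else {
            j <- which.min(abs(r$time - mid[[p]]))
            res[i, p] <- r$t_outer[j]
          }
        }
      }
      res
    }

    f_a <- eval_rows(design$A)
    f_b <- eval_rows(design$B)
    f_ab <- lapply(design$AB, eval_rows)
    for (p in phases) {
      fab_p <- vapply(f_ab, function(m) m[, p], numeric(n))
      idx <- total_order_index(f_a[, p], fab_p, f_b[, p])
      out[[length(out) + 1L]] <- data.frame(
        flow = fl, phase = p, parameter = uncertain_parameters(),
        st = idx$st, st_raw = idx$st_raw, share = idx$share,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    do.call(rbind, out),
    class = c("sensitivity_report", "data.frame"),
    n = n, seed = seed, timepoints = tp_used
  )
}

#' Combined normalised share of a set of parameters, per (flow, phase) cell
#'
#' Convenience summary of a [gsa_profile()] report: the summed percentage
#' share of the given parameters in every (flow, phase) cell.
#'
#' @param report A `sensitivity_report`.
#' @param parameters Parameter names to pool (default: the three that
#'   dominate the prediction uncertainty on the reference rig).
#' @return data.frame with columns `flow`, `phase`, `combined_share`.
#' @export
combined_share <- function(report,
                           parameters = c("h", "gas_temperature", "equilibrium_temperature")) {
  stopifnot(inherits(report, "sensitivity_report"))
  agg <- stats::aggregate(
    share ~ flow + phase,
    data = report[report$parameter %in% parameters, ],
    FUN = sum
  )
  names(agg)[names(agg) == "share"] <- "combined_share"
  agg
}
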