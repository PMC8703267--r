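test_that("zero uncertainty gives a zero-width interval on the nominal profile", {
  spec0 <- uncertainty_spec(
    h = 0, outer_diameter = 0, vial_mass = 0, water_mass = 0,
    flow_rate = 0, equilibrium_temperature = 0, gas_temperature = 0,
    sample_count = 100L
  )
  flow <- lmin_to_m3s(50)
  s <- sample_uncertain_inputs(spec0, default_vs, flow, n = 100L)
  pi_ <- propagate_uncertainty(s, default_vs, default_st, default_cal,
    gas_temperature = gas_m60, flow = flow
  )
  expect_equal(pi_$lower, pi_$nominal, tolerance = 1e-12)
  expect_equal(pi_$upper, pi_$nominal, tolerance = 1e-12)
})

test_that("the nominal trajectory lies inside the interval at every timepoint", {
  flow <- lmin_to_m3s(50)
  s <- sample_uncertain_inputs(uncertainty_spec(), default_vs, flow, n = 128L, seed = 3)
  pi_ <- propagate_uncertainty(s, default_vs, default_st, default_cal,
    gas_temperature = gas_m60, flow = flow
  )
  expect_true(all(pi_$lower <= pi_$nominal + 1e-9))
  expect_true(all(pi_$upper >= pi_$nominal - 1e-9))
  expect_equal(attr(pi_, "excluded"), 0)
})

test_that("order-statistic indices match direct index arithmetic", {
  flow <- lmin_to_m3s(50)
  s <- sample_uncertain_inputs(uncertainty_spec(), default_vs, flow, n = 200L, seed = 3)
  pi_ <- propagate_uncertainty(s, default_vs, default_st, default_cal,
    gas_temperature = gas_m60, flow = flow
  )
  oi <- attr(pi_, "order_indices")
  expect_equal(unname(oi), c(ceiling(0.025 * 200), floor(0.975 * 200)))
  # at n = 10000 the same arithmetic lands on samples 250 and 9750
  expect_equal(ceiling(0.025 * 10000), 250)
  expect_equal(floor(0.975 * 10000), 9750)
})

test_that("interval width is monotone in each dominant half-width", {
  flow <- lmin_to_m3s(50)
  width_for <- function(spec) {
    s <- sample_uncertain_inputs(spec, default_vs, flow, n = 96L)
    pi_ <- propagate_uncertainty(s, default_vs, default_st, default_cal,
      gas_temperature = gas_m60, flow = flow
    )
    pi_$upper - pi_$lower
  }
  zero <- list(
    h = 0, outer_diameter = 0, vial_mass = 0, water_mass = 0,
    flow_rate = 0, equilibrium_temperature = 0, gas_temperature = 0
  )
  for (par in c("h", "gas_temperature", "equilibrium_temperature")) {
    base <- c(h = 4.3058, gas_temperature = 2, equilibrium_temperature = 2)[[par]]
    args1 <- zero
    args1[[par]] <- base
    args2 <- zero
    args2[[par]] <- 2 * base
    w1 <- width_for(do.call(uncertainty_spec, c(args1, sample_count = 100L)))
    w2 <- width_for(do.call(uncertainty_spec, c(args2, sample_count = 100L)))
    expect_true(all(w2 >= w1 - 1e-9), info = par)
  }
})

test_that("with only gas-temperature uncertainty the late solid interval is ~2u", {
  u <- 2
  spec <- uncertainty_spec(
    h = 0, outer_diameter = 0, vial_mass = 0, water_mass = 0,
    flow_rate = 0, equilibrium_temperature = 0, gas_temperature = u,
    sample_count = 100L
  )
  # final temperature below the gas asymptote: the run ends at max_time with
  # the wall tracking the (offset) gas temperature
  st_deep <- simulation_settings(final_temperature = celsius_to_kelvin(-70), max_steps = 2000L)
  flow <- lmin_to_m3s(50)
  s <- sample_uncertain_inputs(spec, default_vs, flow, n = 200L)
  pi_ <- propagate_uncertainty(s, default_vs, st_deep, default_cal,
    gas_temperature = gas_m60, flow = flow
  )
  late <- pi_[pi_$time > 0.9 * max(pi_$time), ]
  # uniform +/- u: the 2.5%..97.5% band converges to 0.95 * 2u
  expect_equal(mean(late$upper - late$lower), 0.95 * 2 * u, tolerance = 0.08)
})

test_that("coverage counts the timepoints inside the interval", {
  flow <- lmin_to_m3s(50)
  s <- sample_uncertain_inputs(uncertainty_spec(), default_vs, flow, n = 96L, seed = 5)
  pi_ <- propagate_uncertainty(s, default_vs, default_st, default_cal,
    gas_temperature = gas_m60, flow = flow
  )
  # measured identical to nominal: full coverage
  meas <- data.frame(time = pi_$time, wall_temperature = pi_$nominal)
  expect_equal(interval_coverage(pi_, meas)$coverage, 1.0)
  # measured above the upper limit everywhere: zero coverage
  meas_hi <- data.frame(time = pi_$time, wall_temperature = pi_$upper + 1)
  cov_hi <- interval_coverage(pi_, meas_hi)
  expect_equal(cov_hi$coverage, 0.0)
  expect_equal(length(cov_hi$excursions), nrow(pi_))
  # synthetic measurement: nominal plus bounded noise at half the local width
  set.seed(42)
  half_w <- (pi_$upper - pi_$lower) / 2
  mid <- (pi_$upper + pi_$lower) / 2
  meas_in <- data.frame(
    time = pi_$time,
    wall_temperature = mid + runif(nrow(pi_), -0.45, 0.45) * 2 * half_w
  )
  expect_equal(interval_coverage(pi_, meas_in)$coverage, 1.0)
})
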