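# Shared fixtures: the documented default vial/fill profile and reference
# calibration, plus a cold-gas constant used throughout.

default_vs <- vial_system()
default_st <- simulation_settings()
default_cal <- default_calibration()
gas_m60 <- celsius_to_kelvin(-60)

# quick forward run used by several property tests
quick_sim <- function(flow_lmin = 50, gas = gas_m60, vs = default_vs,
                      st = default_st, cal = default_cal, ...) {
  simulate_freezing(vs, st, cal,
    gas_temperature = gas,
    flow = lmin_to_m3s(flow_lmin), ...
  )
}
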