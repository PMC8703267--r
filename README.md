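# spinfreeze

Mechanistic cooling and freezing model for spin-frozen pharmaceutical vials.

In continuous freeze-drying, each vial is spun rapidly around its long axis so
that the aqueous formulation spreads as a thin annulus on the inner wall, while
a jet of cold gas cools the outside. `spinfreeze` simulates the outer- and
inner-vial-wall temperature through the four phases of this process — liquid
cooling, ice nucleation, crystal growth, solid cooling — and builds the
surrounding workflow a process engineer needs: calibration of the gas-flow →
heat-transfer-coefficient map, uncertainty propagation to 95% prediction
intervals, variance-based global sensitivity analysis, and open-loop inversion
of the model to compute the gas-flow schedule that imposes a target cooling
profile.

## The model

Heat leaves the vial by Newton cooling over the wetted cylindrical shell,

    Q = pi * h * D * H * (T_v,o - T_gas),     h = ha * V + hb,

where `V` is the volumetric gas flow rate and `(ha, hb)` come from a linear
calibration against constant-flow experiments. The wall temperature is stepped
by explicit Euler with the heat flow evaluated at the previous step:

* **liquid cooling** `T(i) = T(i-1) - Q(i-1) dt / C_w`, with
  `C_w = cp_vial m_vial + cp_water m_water`, until the inner wall (obtained
  from the outer wall by hollow-cylinder conduction,
  `T_v,i = T_v,o + Q ln(r_o/r_i) / (2 pi k_glass H)`) reaches the nucleation
  temperature `T_nuc` — a stochastic event treated as a model *input*;
* **nucleation** warms the product instantly to the equilibrium temperature
  `T_eq`; when the heat flux is high enough that only the annulus outside
  `r_sc = r_i exp(-2 pi k_ice H (T_eq - T_v,i)/Q)` is subcooled, a mass
  fraction `chi_nuc = C_w (T_eq - T_nuc) / (dHf V_nucl rho_water)` of that
  zone freezes at once;
* **crystal growth** converts latent heat to ice,
  `m_ice(i) = m_ice(i-1) + Q(i-1) (1 + chi_nuc) dt / dHf` (the factor applies
  while the centripetally travelling front is inside the pre-nucleated zone),
  with the wall temperature set by conduction through the growing ice annulus
  and the glass;
* **solid cooling** repeats the Euler cooling with the frozen heat capacity
  `C_i` down to the final temperature (default −50 °C).

Inverting the same equations (`Q = Cr * C_tot` for a target cooling rate `Cr`;
`Q = m_water dHf / t_cryst` for a target crystallization duration) gives the
flow schedule that imposes a chosen temperature profile.

## Worked example

```r
library(spinfreeze)

vs  <- vial_system()            # 10 mL type-I vial, 3.0 mL water fill
st  <- simulation_settings()    # dt 0.5 s, T_nuc -1 degC (inner wall), end -50 degC
run <- simulate_freezing(vs, st, default_calibration(),
                         gas_temperature = celsius_to_kelvin(-60),
                         flow = lmin_to_m3s(50))
print(run)
#> <simulation_result> 264 samples, dt = 0.5 s, reached final temperature
#>   nucleation at 21.0 s (chi_nuc = 0.0271, rsc = 10.583 mm), tcryst = 42.5 s
#>   t_outer: 20.00 -> -50.01 degC
fit_cooling_rate(run, "liquid_cooling")
#> [1] 72.4   # degC/min at 50 L/min of -60 degC gas
```

The vial cools from ambient for 21 s until the inner wall reaches −1 °C; ice
nucleation snaps the product to 0 °C, instantaneously freezing 2.7% of the
nucleated zone; the remaining water crystallizes in 42.5 s; the frozen system
then cools to −50 °C. (The reference rig measures longer crystallization times
at this flow because its gas is warmer than −60 °C at low flows.)

Other entry points: `calibrate_heat_transfer()` (constant-flow runs →
`h = ha V + hb` with RMSE and leave-one-out RMSECV),
`propagate_uncertainty()` (Sobol-sampled 95% prediction interval),
`gsa_profile()` (Saltelli/Jansen total-order sensitivity shares per flow and
phase), `flow_schedule()` / `simulate_schedule()` (open-loop inversion and its
round trip), and `generate_fixtures()` (seeded synthetic process traces). A
command-line wrapper with subcommands `simulate / calibrate / ua / gsa /
invert / fixtures` lives at `inst/cli/spinfreeze`; worked configuration files
ship under `inst/extdata/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline quantities from scratch: the minimum
combined total-order sensitivity share of {h, T_gas, T_eq} over three flow
rates and three phases (Saltelli base N = 1024); the liquid-phase cooling
rate, crystallization duration and solid-phase cooling rate recovered by
forward-simulating the inverted 20 °C/min / 150 s / 20 °C/min profile; and the
median calibration slope and intercept recovered from 50 seeded noisy
synthetic calibration studies. It writes them as a JSON object to `--out`
(about 1 minute on one CPU).
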