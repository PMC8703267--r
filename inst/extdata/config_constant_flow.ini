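# Worked example: constant-flow verification run (simulate / calibrate / ua / gsa)
# Units are fixed per key: lengths m, masses kg, specific heats J/(kg K),
# conductivities W/(m K), latent heat J/kg, densities kg/m^3, time s,
# temperatures in degrees C (suffix _C; converted to kelvin internally),
# process flow rates in L/min, cooling rates in degrees C/min.

[vial]                              # 10 mL type-I tubular glass vial (documented default profile)
outer_diameter = 0.024              # vial outer diameter (= 2 * outer_radius)
wall_height = 0.060                 # liquid-covered heat-exchange height
inner_radius = 0.0112
outer_radius = 0.0120
vial_mass = 0.0125
glass_specific_heat = 830
glass_conductivity = 1.1

[fill]
water_mass = 0.003                  # 3.0 mL of demineralized water

[constants]                         # water / ice handbook constants
water_specific_heat = 4186
ice_specific_heat = 2108
ice_conductivity = 2.22             # at 0 degC, used as a single constant
latent_heat_fusion = 334000
water_density = 1000
ice_density = 917
equilibrium_temperature_C = 0

[settings]
dt = 0.5                            # logger interval of the reference rig
initial_wall_temperature_C = 20     # ambient
nucleation_temperature_C = -1       # inner-wall trigger; a model input, not a prediction
final_temperature_C = -50           # end of solid cooling
max_steps = 100000
nucleation_reference = inner        # inner | outer

[uncertainty]                       # half-widths, in each parameter's own SI units
h = 4.3058                          # RMSE of the calibration regression, W/(m2 K)
outer_diameter = 1e-4               # vial manufacturer tolerance, m
vial_mass = 5e-5                    # weighing tolerance, kg
water_mass = 3e-5                   # pipetting accuracy, kg
flow_rate = 6.67e-6                 # mass flow controller accuracy, m3/s
equilibrium_temperature = 2         # IR camera accuracy, K
gas_temperature = 2                 # thermocouple accuracy, K
sample_count = 10000
distribution = uniform              # uniform | normal

[calibration]                       # affine flow -> h map of the reference rig
slope = 71110                       # J/(m5 K)
intercept = 32.05                   # W/(m2 K)
rmse = 4.3058
rmsecv = 5.6293
n_experiments = 8

[thermocouple]                      # placeholder constants giving Nt = 2 s
nt_a = 0.5                          # 1/s
nt_b = 0                            # m^-1/2 s^-1/2
air_velocity = 5                    # m/s

[process]                           # nominal process conditions
gas_temperature_C = -60
flow_L_min = 50                     # constant-flow verification run
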