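flow_L_min,cooling_rate_liquid_C_min,cooling_rate_solid_C_min,crystallization_duration_s,t_nuc_outer_C,t_nuc_inner_C
20,18.5,14.3,161,-10.6,-1.8
26,24.6,25.7,134,-10.8,-0.4
32,25.0,28.6,123,-9.0,-0.6
38,27.4,26.3,115,-9.6,-0.3
44,25.8,26.7,116,-8.7,-0.9
50,33.6,54.5,87,-11.4,-2.0
56,38.7,67.1,80,-12.1,-0.5
62,53.8,79.3,65,-14.4,-0.9
68,47.0,91.3,66,-13.7,-0.5
80,46.5,82.9,60,-13.2,-0.9
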